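# Member ranking, per-tissue top calls and switch detection.

switch_fixture <- function(vals, expressed = TRUE,
                           tissues = c("T1", "T2")) {
  ids <- rownames(vals)
  rec <- toy_records(length(ids), ids = ids)
  list(rec = rec,
       means = toy_means(ids, tissues, vals),
       st = toy_statuses(ids, expressed))
}

test_that("members rank by total abundance with id tie-breaks", {
  fx <- switch_fixture(rbind(A = c(50, 50), B = c(5, 5)))
  expect_equal(rank_members(fx$rec, fx$means, fx$st, "RF0001"), c("A", "B"))

  tie <- switch_fixture(rbind(b = c(5, 5), a = c(5, 5)))
  expect_equal(rank_members(tie$rec, tie$means, tie$st, "RF0001"),
               c("a", "b"))

  # random families agree with an independent sort oracle
  withr::local_seed(61)
  for (i in 1:8) {
    n <- sample(2:7, 1)
    vals <- matrix(runif(n * 3, 0, 20), n, 3,
                   dimnames = list(sprintf("m%02d", sample(n)), NULL))
    fx <- switch_fixture(vals, tissues = c("T1", "T2", "T3"))
    got <- rank_members(fx$rec, fx$means, fx$st, "RF0001")
    oracle <- rownames(vals)[order(-rowSums(vals), rownames(vals))]
    expect_equal(got, oracle)
  }
})

test_that("per-tissue top calls pick the maximal expressed member", {
  fx <- switch_fixture(rbind(A = c(10, 1), B = c(1, 10)))
  st <- switch_table(fx$rec, fx$means, fx$st)
  expect_equal(unname(st$top_members[[1]]), c("A", "B"))
  expect_true(st$switch)
  expect_equal(st$n_top_members, 2L)

  fx2 <- switch_fixture(rbind(A = c(10, 5), B = c(1, 2)))
  st2 <- switch_table(fx2$rec, fx2$means, fx2$st)
  expect_equal(unname(st2$top_members[[1]]), c("A", "A"))
  expect_false(st2$switch)

  # all-zero tissue is degenerate and contributes no switch evidence
  fx3 <- switch_fixture(rbind(A = c(0, 0), B = c(0, 3)))
  st3 <- switch_table(fx3$rec, fx3$means, fx3$st)
  expect_true(is.na(st3$top_members[[1]][["T1"]]))
  expect_equal(st3$top_members[[1]][["T2"]], "B")
  expect_false(st3$switch)

  # exact per-tissue ties resolve to the better overall rank
  fx4 <- switch_fixture(rbind(A = c(10, 5), B = c(10, 1)))
  st4 <- switch_table(fx4$rec, fx4$means, fx4$st)
  expect_equal(st4$top_members[[1]][["T1"]], "A")
  expect_false(st4$switch)
})

test_that("families with fewer than two expressed members never switch", {
  fx <- switch_fixture(rbind(A = c(10, 1), B = c(1, 10)),
                       expressed = c(TRUE, FALSE))
  st <- switch_table(fx$rec, fx$means, fx$st)
  expect_false(st$eligible)
  expect_false(st$switch)
  expect_equal(st$member_rank[[1]], "A")
})

test_that("scaling and tissue order leave switch calls invariant", {
  withr::local_seed(67)
  tissues <- paste0("T", 1:5)
  for (i in 1:6) {
    n <- sample(2:5, 1)
    vals <- matrix(runif(n * 5, 0, 30), n, 5,
                   dimnames = list(sprintf("m%02d", 1:n), NULL))
    fx <- switch_fixture(vals, tissues = tissues)
    st <- switch_table(fx$rec, fx$means, fx$st)

    scaled <- switch_fixture(vals * 7.3, tissues = tissues)
    st_s <- switch_table(scaled$rec, scaled$means, scaled$st)
    expect_equal(st_s$switch, st$switch)
    expect_equal(st_s$member_rank, st$member_rank)
    expect_equal(st_s$top_members, st$top_members)

    perm <- sample(5)
    shuffled <- switch_fixture(vals[, perm, drop = FALSE],
                               tissues = tissues[perm])
    st_p <- switch_table(shuffled$rec, shuffled$means, shuffled$st)
    expect_equal(st_p$switch, st$switch)
    expect_equal(st_p$n_top_members, st$n_top_members)
  }
})

test_that("the overall top member tops at least one non-degenerate tissue", {
  withr::local_seed(71)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    vals <- matrix(runif(n * 4, 0, 10), n, 4,
                   dimnames = list(sprintf("m%02d", 1:n), NULL))
    fx <- switch_fixture(vals, tissues = paste0("T", 1:4))
    st <- switch_table(fx$rec, fx$means, fx$st)
    tops <- st$top_members[[1]]
    expect_true(st$member_rank[[1]][1] %in% tops[!is.na(tops)])
  }
})

test_that("top-member matrix stores overall rank indices per tissue", {
  fx <- switch_fixture(rbind(A = c(10, 4), B = c(1, 8)))
  st <- switch_table(fx$rec, fx$means, fx$st)
  heat <- top_member_matrix(st)
  # A has the higher total (rank 1), B ranks 2 and tops T2
  expect_equal(heat$T1, 1L)
  expect_equal(heat$T2, 2L)
})

test_that("same-top-tissue counting uses expressed members per family", {
  rec <- dplyr::bind_rows(
    toy_records(3, family_id = "F1", ids = paste0("a", 1:3)),
    toy_records(2, family_id = "F2", ids = paste0("b", 1:2)),
    toy_records(2, family_id = "F3", ids = paste0("c", 1:2)))
  st <- tibble::tibble(
    snorna_id = rec$snorna_id,
    expressed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    top_tissue = c("ovary", "ovary", "ovary",   # coherent
                   "ovary", "testis",           # not coherent
                   "brain", "none"))            # single expressed member
  out <- same_tissue_top_fraction(rec, st)
  expect_equal(out$n, 2)  # F3 has one expressed member only
  expect_equal(out$k, 1)
  expect_equal(out$fraction, 0.5)

  # a fully coherent cohort has k = n
  st2 <- st
  st2$top_tissue <- "ovary"
  st2$expressed <- TRUE
  out2 <- same_tissue_top_fraction(rec, st2)
  expect_equal(out2$k, out2$n)
})
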