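# Coefficient-of-variation statistics, diagonal distances, the class
# comparison and the size-abundance correlation.

test_that("CV closed forms hold for both sd conventions", {
  expect_equal(cv_percent(rep(2, 7)), 0)
  expect_equal(cv_percent(c(1, 3)), 100 * sqrt(2) / 2)  # 70.7107
  expect_equal(round(cv_percent(c(1, 3)), 4), 70.7107)
  expect_equal(cv_percent(c(1, 3), ddof = 0), 50)
  expect_true(is.na(cv_percent(c(0, 0))))
  expect_error(cv_percent(3), "at least 2")
})

test_that("CV is invariant under positive scaling", {
  withr::local_seed(41)
  for (i in 1:10) {
    x <- runif(7, 0.1, 100)
    c1 <- runif(1, 0.01, 50)
    expect_equal(cv_percent(c1 * x), cv_percent(x))
    expect_equal(cv_percent(c1 * x, ddof = 0), cv_percent(x, ddof = 0))
  }
})

test_that("family variability reduces expressed members correctly", {
  tissues <- c("t1", "t2", "t3", "t4")
  # single expressed member: family CV equals member CV, distance 0
  rec <- toy_records(2, ids = c("a1", "a2"))
  means <- toy_means(c("a1", "a2"), tissues,
                     rbind(c(1, 2, 3, 4), c(9, 9, 9, 9)))
  st <- toy_statuses(c("a1", "a2"), c(TRUE, FALSE))
  fv <- family_variability(rec, means, st)
  expect_equal(fv$family_cv, cv_percent(c(1, 2, 3, 4)))
  expect_equal(fv$diag_distance, 0)
  expect_equal(fv$n_expressed, 1L)

  # proportional profiles (B = 3A): CV scale invariance makes distance 0
  means2 <- toy_means(c("a1", "a2"), tissues,
                      rbind(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4)))
  st2 <- toy_statuses(c("a1", "a2"), TRUE)
  fv2 <- family_variability(rec, means2, st2)
  expect_equal(fv2$family_cv, fv2$mean_member_cv)
  expect_equal(fv2$diag_distance, 0)

  # mirror-image profiles summing to a constant: family CV 0, distance < 0
  means3 <- toy_means(c("a1", "a2"), tissues,
                      rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  fv3 <- family_variability(rec, means3, st2)
  expect_equal(fv3$family_cv, 0)
  expect_gt(fv3$mean_member_cv, 0)
  expect_lt(fv3$diag_distance, 0)
  expect_equal(fv3$diag_distance,
               (fv3$family_cv - fv3$mean_member_cv) / sqrt(2))

  # families with zero expressed members are skipped
  st0 <- toy_statuses(c("a1", "a2"), FALSE)
  expect_equal(nrow(family_variability(rec, means, st0)), 0)
})

test_that("family CV equals the CV of the summed member mean vectors", {
  withr::local_seed(43)
  tissues <- paste0("t", 1:7)
  for (i in 1:8) {
    n <- sample(2:6, 1)
    ids <- sprintf("m%02d", seq_len(n))
    vals <- matrix(runif(n * 7, 0.5, 50), n, 7)
    rec <- toy_records(n, ids = ids)
    fv <- family_variability(rec, toy_means(ids, tissues, vals),
                             toy_statuses(ids, TRUE))
    expect_equal(fv$family_cv, cv_percent(colSums(vals)))
    expect_equal(fv$mean_member_cv,
                 mean(apply(vals, 1, cv_percent)))
    # sign convention
    expect_equal(fv$diag_distance < 0, fv$mean_member_cv > fv$family_cv)
  }
})

test_that("Mann-Whitney U equals the brute-force pair count", {
  res <- compare_classes_diag(c(1, 2, 3), c(-3, -2, -1))
  expect_equal(res$statistic, 9)  # all 9 pairwise wins

  same <- compare_classes_diag(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)

  # exhaustive equality over random list pairs of every length <= 8,
  # including heavy ties from the small integer pool
  withr::local_seed(47)
  for (n1 in 1:8) for (n2 in 1:8) {
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(compare_classes_diag(x, y)$statistic, oracle_mwu_u(x, y))
  }
  expect_error(compare_classes_diag(numeric(), 1:3), "at least one")
})

test_that("the class-comparison p-value shrinks with the shift size", {
  withr::local_seed(53)
  base <- rnorm(30)
  other <- rnorm(30)
  ps <- vapply(c(0.1, 1, 3), function(shift) {
    compare_classes_diag(base, other + shift)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[3], 1e-6)
})

test_that("size-abundance correlation behaves on constructed cohorts", {
  tissues <- c("brain", "liver")
  panel <- toy_panel(tissues, reps = 1)
  build <- function(n_expressed_per_family, slope = 10) {
    recs <- list()
    mats <- list()
    for (f in seq_along(n_expressed_per_family)) {
      k <- n_expressed_per_family[f]
      ids <- sprintf("f%02d_m%02d", f, seq_len(k))
      recs[[f]] <- toy_records(k, family_id = sprintf("F%02d", f),
                               ids = ids)
      # total abundance exactly proportional to expressed-member count
      per <- slope * k / k
      mats[[f]] <- toy_abundance(ids, panel, matrix(per, k, 2))
    }
    list(rec = dplyr::bind_rows(recs), mat = dplyr::bind_rows(mats))
  }
  cohort <- build(c(1, 2, 3, 4, 5))
  st <- toy_statuses(cohort$rec$snorna_id, TRUE)
  res <- correlate_size_abundance(cohort$rec, cohort$mat, st)
  expect_equal(res$r, 1)

  # duplicating every family leaves the Pearson r unchanged
  dup <- build(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  st2 <- toy_statuses(dup$rec$snorna_id, TRUE)
  expect_equal(correlate_size_abundance(dup$rec, dup$mat, st2)$r, 1)

  # decoupled data: small r, large p
  withr::local_seed(59)
  recs <- list(); vals <- list()
  for (f in 1:40) {
    k <- sample(1:6, 1)
    ids <- sprintf("g%02d_m%02d", f, seq_len(k))
    recs[[f]] <- toy_records(k, family_id = sprintf("G%02d", f), ids = ids)
    vals[[f]] <- toy_abundance(ids, panel,
                               matrix(runif(k * 2, 1, 10) / k, k, 2))
  }
  rec <- dplyr::bind_rows(recs)
  st3 <- toy_statuses(rec$snorna_id, TRUE)
  res3 <- correlate_size_abundance(rec, dplyr::bind_rows(vals), st3)
  expect_lt(abs(res3$r), 0.35)
  expect_gt(res3$p_value, 0.05)

  # zero variance in size: undefined sentinel
  flat <- build(c(2, 2, 2))
  st4 <- toy_statuses(flat$rec$snorna_id, TRUE)
  expect_true(is.na(correlate_size_abundance(flat$rec, flat$mat, st4)$r))
})
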