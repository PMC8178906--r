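# Conservation averaging, SNP density, host-transcript assignment and
# genomic-context classification.

test_that("conservation score averages per nucleotide over the snoRNA span", {
  track <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                          score = 0.8)
  sno <- toy_records(1, start = 10, end = 20)
  expect_equal(conservation_score(sno, track)$conservation_score, 0.8)

  # 10 nt covered at 0.8, 10 nt uncovered -> 0.4 over the full span
  sno2 <- toy_records(1, start = 90, end = 110)
  expect_equal(conservation_score(sno2, track)$conservation_score, 0.4)
  # covered-only variant averages just the covered nucleotides
  expect_equal(
    conservation_score(sno2, track,
                       uncovered_zero = FALSE)$conservation_score, 0.8)

  empty <- track[0, ]
  expect_equal(conservation_score(sno, empty)$conservation_score, 0)
  expect_true(is.na(conservation_score(
    sno, empty, uncovered_zero = FALSE)$conservation_score))
})

test_that("conservation score is invariant to splitting track intervals", {
  withr::local_seed(29)
  for (i in 1:10) {
    s <- sample(0:50, 1)
    e <- s + sample(30:80, 1)
    score <- runif(1)
    sno <- toy_records(1, start = s + 5, end = e - 5)
    whole <- tibble::tibble(chrom = "chr1", start = as.integer(s),
                            end = as.integer(e), score = score)
    cut <- sample(seq(s + 1, e - 1), 1)
    split <- tibble::tibble(chrom = "chr1",
                            start = as.integer(c(s, cut)),
                            end = as.integer(c(cut, e)), score = score)
    expect_equal(conservation_score(sno, split)$conservation_score,
                 conservation_score(sno, whole)$conservation_score)
  }
})

test_that("SNP density is 1000 * count / length", {
  sno <- toy_records(1, start = 0, end = 100)
  none <- tibble::tibble(chrom = character(), pos = integer())
  expect_equal(snp_density(sno, none)$snp_per_nt_1000, 0)

  two <- tibble::tibble(chrom = "chr1", pos = c(10L, 50L))
  expect_equal(snp_density(sno, two)$snp_per_nt_1000, 20)

  sno80 <- toy_records(1, start = 0, end = 80)
  one <- tibble::tibble(chrom = "chr1", pos = 40L)
  expect_equal(snp_density(sno80, one)$snp_per_nt_1000, 12.5)

  # outside-span and other-chromosome sites do not count
  outside <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(500L, 10L))
  expect_equal(snp_density(sno, outside)$n_snps, 0L)
})

test_that("SNP density scales linearly in count and inversely in length", {
  withr::local_seed(37)
  for (i in 1:8) {
    len <- sample(50:200, 1)
    k <- sample(1:10, 1)
    sno <- toy_records(1, start = 0, end = len)
    snps <- tibble::tibble(chrom = "chr1",
                           pos = as.integer(sort(sample(0:(len - 1), k))))
    d <- snp_density(sno, snps)$snp_per_nt_1000
    expect_equal(d, 1000 * k / len)
    # doubling the length (same SNPs) halves the density
    sno2 <- toy_records(1, start = 0, end = 2 * len)
    expect_equal(snp_density(sno2, snps)$snp_per_nt_1000, d / 2)
  }
})

test_that("host assignment finds the first intron-containing transcript", {
  # plus strand: snoRNA 1000-1100 (0-based), downstream exon starts at 1170
  lines <- gtf_text(start = 1, end = 2000, transcripts = list(
    list(name = "t1", exons = list(c(1, 900), c(1171, 1250)))))
  host <- read_gtf(write_gtf_tmp(lines))
  sno <- toy_records(1, start = 1000, end = 1100)
  hit <- assign_host_transcript(sno, host)
  expect_true(hit$intronic)
  expect_equal(hit$distance_to_downstream_exon, 70)

  # minus strand mirror of the same geometry: exon ends at internal 830,
  # snoRNA starts at 900, gap 70 measured towards lower coordinates
  lines_m <- gtf_text(start = 1, end = 2000, strand = "-", transcripts = list(
    list(name = "t1", exons = list(c(751, 830), c(1101, 2000)))))
  host_m <- read_gtf(write_gtf_tmp(lines_m))
  sno_m <- toy_records(1, start = 900, end = 1000, strand = "-")
  hit_m <- assign_host_transcript(sno_m, host_m)
  expect_true(hit_m$intronic)
  expect_equal(hit_m$distance_to_downstream_exon, 70)
})

test_that("host assignment obeys the exon-count and name sort order", {
  # two qualifying transcripts with equal exon counts: name ascending wins
  lines <- gtf_text(start = 1, end = 2000, transcripts = list(
    list(name = "T_b", exons = list(c(1, 900), c(1171, 1250))),
    list(name = "T_a", exons = list(c(1, 900), c(1201, 1250)))))
  host <- read_gtf(write_gtf_tmp(lines))
  sno <- toy_records(1, start = 1000, end = 1100)
  hit <- assign_host_transcript(sno, host)
  expect_equal(hit$transcript_id, "HOST1.T_a")
  expect_equal(hit$distance_to_downstream_exon, 100)

  # most-exon transcript overlaps the snoRNA: iterate to the next one
  lines2 <- gtf_text(start = 1, end = 2000, transcripts = list(
    list(name = "t1", exons = list(c(1, 900), c(1001, 1020), c(1171, 1250))),
    list(name = "t2", exons = list(c(1, 900), c(1171, 1250)))))
  host2 <- read_gtf(write_gtf_tmp(lines2))
  hit2 <- assign_host_transcript(sno, host2)
  expect_equal(hit2$transcript_id, "HOST1.t2")
  expect_equal(hit2$distance_to_downstream_exon, 70)

  # snoRNA inside an exon of every transcript: not intronic, no distance
  lines3 <- gtf_text(start = 1, end = 2000, transcripts = list(
    list(name = "t1", exons = list(c(901, 1150), c(1171, 1250)))))
  host3 <- read_gtf(write_gtf_tmp(lines3))
  hit3 <- assign_host_transcript(sno, host3)
  expect_false(hit3$intronic)
  expect_true(is.na(hit3$distance_to_downstream_exon))
})

test_that("family context categories follow the all-share-or-mixed rule", {
  rec <- dplyr::bind_rows(
    toy_records(2, family_id = "F1", ids = c("a1", "a2"),
                host_biotype = "coding"),
    toy_records(2, family_id = "F2", ids = c("b1", "b2"),
                host_biotype = c("coding", "noncoding")),
    toy_records(2, family_id = "F3", ids = c("c1", "c2"),
                host_gene_id = NA, host_biotype = "intergenic"),
    toy_records(2, family_id = "F4", ids = c("d1", "d2"),
                host_gene_id = c("H1", NA),
                host_biotype = c("coding", "intergenic")))
  st <- toy_statuses(rec$snorna_id, TRUE)
  ctx <- classify_family_context(rec, st)
  expect_equal(ctx$category[match(c("F1", "F2", "F3", "F4"),
                                  ctx$family_id)],
               c("coding_only", "mixed", "intergenic_only", "mixed"))
})

test_that("expressed-only context and the same-host flag honor statuses", {
  rec <- dplyr::bind_rows(
    toy_records(3, family_id = "F1", ids = c("a1", "a2", "a3"),
                host_gene_id = c("H1", "H1", "H2"),
                host_biotype = c("coding", "coding", "noncoding")))
  st <- toy_statuses(rec$snorna_id, c(TRUE, TRUE, FALSE))
  all_members <- classify_family_context(rec, st, expressed_only = FALSE)
  expect_equal(all_members$category, "mixed")
  expressed <- classify_family_context(rec, st, expressed_only = TRUE)
  expect_equal(expressed$category, "coding_only")
  expect_true(expressed$same_host)

  # different hosts among expressed members
  st2 <- toy_statuses(rec$snorna_id, c(TRUE, FALSE, TRUE))
  expect_false(classify_family_context(rec, st2, TRUE)$same_host)
  # fewer than two expressed members: flag undefined
  st3 <- toy_statuses(rec$snorna_id, c(TRUE, FALSE, FALSE))
  expect_true(is.na(classify_family_context(rec, st3, TRUE)$same_host))
  # zero expressed members: category sentinel
  st4 <- toy_statuses(rec$snorna_id, FALSE)
  expect_equal(classify_family_context(rec, st4, TRUE)$category,
               "undefined")
})

test_that("context categories partition the families of a cohort", {
  sim <- simulate_cohort(small_config(99))
  st <- toy_statuses(sim$truth_sno$snorna_id, sim$truth_sno$expressed)
  for (eo in c(FALSE, TRUE)) {
    ctx <- classify_family_context(sim$records, st, expressed_only = eo)
    expect_equal(nrow(ctx), length(unique(sim$records$family_id)))
    expect_equal(sum(table(ctx$category)), nrow(ctx))
    expect_true(all(ctx$category %in% c("coding_only", "noncoding_only",
                                        "intergenic_only", "mixed",
                                        "undefined")))
  }
})
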