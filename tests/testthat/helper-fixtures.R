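# In-code fixture builders shared across test files.

toy_records <- function(n = 3, family_id = "RF0001", box_type = "CD",
                        ids = sprintf("sno%02d", seq_len(n)),
                        sequence = NULL, host_gene_id = "HOST1",
                        host_biotype = "coding", chrom = "chr1",
                        start = NULL, end = NULL, strand = "+") {
  if (is.null(sequence)) {
    sequence <- vapply(seq_len(n), function(i) random_seq(20), character(1))
  }
  if (is.null(start)) start <- seq(1000L, by = 1000L, length.out = n)
  if (is.null(end)) end <- start + nchar(sequence)
  tibble::tibble(
    snorna_id = ids, name = ids,
    box_type = rep_len(box_type, n), family_id = rep_len(family_id, n),
    sequence = sequence, chrom = rep_len(chrom, n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n),
    host_gene_id = rep_len(host_gene_id, n),
    host_biotype = rep_len(host_biotype, n)
  )
}

toy_panel <- function(tissues = c("brain", "liver"), reps = 2) {
  tibble::tibble(
    sample_id = paste0(rep(tissues, each = reps), "_",
                       rep(seq_len(reps), length(tissues))),
    tissue = rep(tissues, each = reps)
  )
}

toy_abundance <- function(ids, panel, values = NULL) {
  n <- length(ids)
  m <- nrow(panel)
  if (is.null(values)) values <- matrix(runif(n * m, 0, 10), n, m)
  out <- tibble::tibble(snorna_id = ids)
  for (j in seq_len(m)) out[[panel$sample_id[j]]] <- values[, j]
  out
}

# Means tibble straight from a member x tissue matrix.
toy_means <- function(ids, tissues, values) {
  out <- tibble::tibble(snorna_id = ids)
  for (j in seq_along(tissues)) out[[tissues[j]]] <- values[, j]
  out
}

toy_statuses <- function(ids, expressed = TRUE) {
  tibble::tibble(snorna_id = ids, expressed = rep_len(expressed,
                                                      length(ids)))
}

# Minimal GTF text for host-assignment fixtures: `transcripts` is a list of
# lists with name and exons (list of 1-based closed c(start, end)).
gtf_text <- function(gene_id = "HOST1", chrom = "chr1", start = 1,
                     end = 5000, strand = "+", biotype = "protein_coding",
                     transcripts = list()) {
  lines <- sprintf(
    '%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    chrom, start, end, strand, gene_id, biotype)
  for (tx in transcripts) {
    tid <- paste0(gene_id, ".", tx$name)
    lines <- c(lines, sprintf(
      '%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s"; gene_biotype "%s";',
      chrom, start, end, strand, gene_id, tid, tx$name, biotype))
    for (ex in tx$exons) {
      lines <- c(lines, sprintf(
        '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s"; gene_biotype "%s";',
        chrom, ex[1], ex[2], strand, gene_id, tid, tx$name, biotype))
    }
  }
  lines
}

write_gtf_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small cohort configuration for fast tests.
small_config <- function(seed, ...) {
  defaults <- list(
    seed = seed, n_cd_families = 25, n_haca_families = 15,
    p_expressed = c(CD = 0.5, HACA = 0.5),
    n_switch_families = c(CD = 2, HACA = 1),
    n_identical_pairs = c(CD = 1, HACA = 1),
    family_size = list(
      CD = list(p_singleton = 0.4, nb_mu = 3, nb_size = 1.5,
                p_large = 0, large_range = c(30, 40)),
      HACA = list(p_singleton = 0.3, nb_mu = 3, nb_size = 1.5,
                  p_large = 0, large_range = c(20, 30)))
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}
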