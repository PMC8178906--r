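# Genomic-context module: per-base conservation averaging, SNP density,
# host-transcript assignment with distance to the downstream exon, and
# family-level context classification.

records_granges <- function(records) {
  GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand
  )
}

#' Average per-nucleotide conservation score
#'
#' Mean conservation over the snoRNA span `[start, end)`. By default
#' nucleotides not covered by any track interval contribute 0 (the average is
#' taken over all nucleotides of the snoRNA); with `uncovered_zero = FALSE`
#' the mean is over covered nucleotides only (`NA` when nothing is covered).
#'
#' @param records Annotation tibble.
#' @param track Conservation tibble from [read_bedgraph()].
#' @param uncovered_zero Score uncovered nucleotides as 0 (default).
#' @return Tibble with `snorna_id` and `conservation_score` in \[0, 1\].
#' @export
conservation_score <- function(records, track, uncovered_zero = TRUE) {
  n <- nrow(records)
  total <- numeric(n)
  covered <- numeric(n)
  if (nrow(track) > 0 && n > 0) {
    sno <- records_granges(records)
    trk <- GenomicRanges::GRanges(
      seqnames = track$chrom,
      ranges = IRanges::IRanges(start = track$start + 1L, end = track$end)
    )
    hits <- GenomicRanges::findOverlaps(sno, trk, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(IRanges::pintersect(
        IRanges::ranges(sno)[qi], IRanges::ranges(trk)[si]))
      contrib <- w * track$score[si]
      total <- as.numeric(tapply(contrib, factor(qi, levels = seq_len(n)),
                                 sum, default = 0))
      covered <- as.numeric(tapply(w, factor(qi, levels = seq_len(n)),
                                   sum, default = 0))
      total[is.na(total)] <- 0
      covered[is.na(covered)] <- 0
    }
  }
  len <- records$end - records$start
  score <- if (uncovered_zero) total / len else
    ifelse(covered > 0, total / covered, NA_real_)
  tibble::tibble(snorna_id = records$snorna_id, conservation_score = score)
}

#' SNP density per snoRNA
#'
#' `1000 * (number of SNP sites within [start, end)) / length`.
#'
#' @param records Annotation tibble.
#' @param snps SNP tibble from [read_bed()].
#' @return Tibble with `snorna_id`, `n_snps` and `snp_per_nt_1000`.
#' @export
snp_density <- function(records, snps) {
  n_hits <- integer(nrow(records))
  if (nrow(snps) > 0 && nrow(records) > 0) {
    sno <- records_granges(records)
    sites <- GenomicRanges::GRanges(
      seqnames = snps$chrom,
      ranges = IRanges::IRanges(start = snps$pos + 1L, width = 1L)
    )
    n_hits <- GenomicRanges::countOverlaps(sno, sites, ignore.strand = TRUE)
  }
  tibble::tibble(
    snorna_id = records$snorna_id,
    n_snps = as.integer(n_hits),
    snp_per_nt_1000 = 1000 * n_hits / (records$end - records$start)
  )
}

#' Assign intronic snoRNAs to a host transcript
#'
#' For each snoRNA with a host gene present in the model, the host's
#' transcripts are sorted by exon count (descending) then transcript name
#' (ascending) and scanned until the first transcript whose span contains the
#' snoRNA and none of whose exons overlap it — i.e. the snoRNA is fully
#' intronic in it. The distance is the strand-aware gap in nucleotides from
#' the snoRNA's 3' end to the nearest exon downstream in transcript
#' orientation. When no transcript qualifies the snoRNA is called
#' non-intronic and the distance is undefined.
#'
#' @param records Annotation tibble.
#' @param host A `host_model` from [read_gtf()].
#' @return Tibble with `snorna_id`, `transcript_id`, `intronic` and
#'   `distance_to_downstream_exon`.
#' @export
assign_host_transcript <- function(records, host) {
  tx_by_gene <- split(host$transcripts, host$transcripts$gene_id)
  exons_by_tx <- split(host$exons, host$exons$transcript_id)

  one <- function(i) {
    gid <- records$host_gene_id[i]
    res <- list(transcript_id = NA_character_, intronic = FALSE,
                distance = NA_real_)
    if (is.na(gid) || is.null(tx_by_gene[[gid]])) return(res)
    txs <- tx_by_gene[[gid]]
    txs <- txs[order(-txs$exon_count, txs$name), ]
    s <- records$start[i]
    e <- records$end[i]
    for (k in seq_len(nrow(txs))) {
      if (s < txs$start[k] || e > txs$end[k]) next
      ex <- exons_by_tx[[txs$transcript_id[k]]]
      if (any(ex$start < e & ex$end > s)) next  # overlaps an exon
      if (txs$strand[k] == "+") {
        down <- ex$start[ex$start >= e]
        d <- if (length(down) > 0) min(down) - e else NA_real_
      } else {
        down <- ex$end[ex$end <= s]
        d <- if (length(down) > 0) s - max(down) else NA_real_
      }
      return(list(transcript_id = txs$transcript_id[k], intronic = TRUE,
                  distance = d))
    }
    res
  }

  hits <- lapply(seq_len(nrow(records)), one)
  tibble::tibble(
    snorna_id = records$snorna_id,
    transcript_id = vapply(hits, `[[`, character(1), "transcript_id"),
    intronic = vapply(hits, `[[`, logical(1), "intronic"),
    distance_to_downstream_exon = vapply(hits, `[[`, numeric(1), "distance")
  )
}

context_category <- function(contexts) {
  if (length(contexts) == 0) return("undefined")
  u <- unique(contexts)
  if (length(u) > 1) return("mixed")
  paste0(u, "_only")
}

#' Classify the genomic context of each family
#'
#' A family is `coding_only` / `noncoding_only` / `intergenic_only` when all
#' considered members share that context, `mixed` otherwise (combinations of
#' intergenic and intronic members are mixed). With `expressed_only = TRUE`
#' only expressed members are considered; a family whose considered set is
#' empty gets the `undefined` sentinel. The `same_host` flag — defined only
#' for families with at least two expressed members — is `TRUE` when all
#' expressed members share a single host gene.
#'
#' @param records Annotation tibble (uses `host_biotype`, `host_gene_id`).
#' @param statuses Tibble with `snorna_id` and `expressed`.
#' @param expressed_only Restrict the category to expressed members.
#' @return Tibble with `family_id`, `box_type`, `category` and `same_host`.
#' @export
classify_family_context <- function(records, statuses,
                                    expressed_only = FALSE) {
  joined <- dplyr::inner_join(
    records[, c("snorna_id", "family_id", "box_type", "host_gene_id",
                "host_biotype")],
    statuses[, c("snorna_id", "expressed")], by = "snorna_id")
  joined |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      category = context_category(
        if (expressed_only) .data$host_biotype[.data$expressed]
        else .data$host_biotype),
      same_host = {
        hosts <- .data$host_gene_id[.data$expressed]
        if (sum(.data$expressed) < 2) NA
        else !anyNA(hosts) && length(unique(hosts)) == 1
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family_id)
}
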