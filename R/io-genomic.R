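# Genomic-format ingest: GTF host-gene models, bedGraph conservation tracks
# and BED3 SNP sites. Parsing goes through rtracklayer; coordinates are
# converted to the package-internal 0-based half-open convention at the
# boundary (GTF is 1-based closed; BED/bedGraph are natively 0-based).

#' Read a host-gene model from GTF
#'
#' Builds the gene -> transcript -> exon model used for host-transcript
#' assignment. Requires `gene`, `transcript` and `exon` features carrying
#' `gene_id` / `transcript_id` attributes; `gene_biotype` and
#' `transcript_name` are used when present (`transcript_name` falls back to
#' `transcript_id`). Exons are sorted by coordinate within each transcript and
#' validated as non-overlapping; each transcript span must cover its exons.
#'
#' @param path Path to a GTF file (1-based closed coordinates).
#' @return A `host_model`: list of tibbles `genes` (gene_id, chrom, start,
#'   end, strand, biotype), `transcripts` (transcript_id, gene_id, name,
#'   chrom, start, end, strand, exon_count) and `exons` (transcript_id,
#'   start, end), all 0-based half-open.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble::tibble(
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = gtf_to_internal_start(GenomicRanges::start(gr)),
    end = gtf_to_internal_end(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = if (is.null(gr$transcript_id)) NA_character_ else
      as.character(gr$transcript_id),
    gene_biotype = if (is.null(gr$gene_biotype)) NA_character_ else
      as.character(gr$gene_biotype),
    transcript_name = if (is.null(gr$transcript_name)) NA_character_ else
      as.character(gr$transcript_name)
  )
  if (any(df$start >= df$end)) {
    stop("GTF feature with non-positive width after coordinate conversion",
         call. = FALSE)
  }

  genes <- df |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::transmute(
      gene_id = .data$gene_id, chrom = .data$chrom, start = .data$start,
      end = .data$end, strand = .data$strand,
      biotype = dplyr::case_when(
        .data$gene_biotype %in% c("protein_coding", "coding") ~ "coding",
        is.na(.data$gene_biotype) ~ NA_character_,
        TRUE ~ "noncoding"
      )
    )

  exons <- df |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::select("transcript_id", "start", "end") |>
    dplyr::arrange(.data$transcript_id, .data$start)

  # exons within a transcript must not overlap
  ov <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(bad = any(.data$start[-1] < head(.data$end, -1)),
                     .groups = "drop")
  if (any(ov$bad)) {
    stop("overlapping exons within transcript: ",
         paste(ov$transcript_id[ov$bad], collapse = ", "), call. = FALSE)
  }

  transcripts <- df |>
    dplyr::filter(.data$type == "transcript") |>
    dplyr::transmute(
      transcript_id = .data$transcript_id, gene_id = .data$gene_id,
      name = dplyr::coalesce(.data$transcript_name, .data$transcript_id),
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand
    ) |>
    dplyr::left_join(
      exons |>
        dplyr::group_by(.data$transcript_id) |>
        dplyr::summarise(exon_count = dplyr::n(),
                         exon_min = min(.data$start),
                         exon_max = max(.data$end), .groups = "drop"),
      by = "transcript_id"
    )
  if (anyNA(transcripts$exon_count)) {
    stop("transcript without exons: ",
         paste(transcripts$transcript_id[is.na(transcripts$exon_count)],
               collapse = ", "), call. = FALSE)
  }
  uncovered <- transcripts$exon_min < transcripts$start |
    transcripts$exon_max > transcripts$end
  if (any(uncovered)) {
    stop("transcript span does not cover its exons: ",
         paste(transcripts$transcript_id[uncovered], collapse = ", "),
         call. = FALSE)
  }
  transcripts$exon_min <- transcripts$exon_max <- NULL

  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "host_model")
}

#' @export
print.host_model <- function(x, ...) {
  cat(sprintf("<host_model> %d gene(s), %d transcript(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Read a conservation track from bedGraph
#'
#' Scored intervals, 0-based half-open. Scores must lie in \[0, 1\] and
#' intervals on one chromosome must not overlap.
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score)
  ) |> dplyr::arrange(.data$chrom, .data$start)
  if (any(track$score < 0 | track$score > 1)) {
    stop("bedGraph score outside [0, 1]", call. = FALSE)
  }
  ov <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = any(.data$start[-1] < head(.data$end, -1)),
                     .groups = "drop")
  if (any(ov$bad)) {
    stop("overlapping bedGraph intervals on chrom: ",
         paste(ov$chrom[ov$bad], collapse = ", "), call. = FALSE)
  }
  track
}

#' Read SNP sites from BED3
#'
#' Each row must describe a single-nucleotide site (width 1); duplicate sites
#' are rejected.
#'
#' @param path Path to a BED3 file.
#' @return Tibble with columns `chrom` and `pos` (0-based).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  snps <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    width = GenomicRanges::width(gr)
  )
  if (any(snps$width != 1)) {
    stop("BED SNP interval wider than one nucleotide", call. = FALSE)
  }
  snps$width <- NULL
  if (anyDuplicated(snps)) stop("duplicate SNP sites in BED", call. = FALSE)
  dplyr::arrange(snps, .data$chrom, .data$pos)
}

#' @rdname read_bedgraph
#' @param track Conservation tibble.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format(track$score, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' @rdname read_bed
#' @param snps SNP tibble.
#' @export
write_bed <- function(snps, path) {
  writeLines(sprintf("%s\t%d\t%d", snps$chrom, snps$pos, snps$pos + 1L), path)
  invisible(path)
}
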