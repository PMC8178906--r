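# Readers and writers for the package's frozen TSV dialects: snoRNA
# annotation, sample panel and TPM abundance matrix. All coordinates are
# 0-based half-open internally; absent host genes are written as ".".

ANNOTATION_COLS <- c("snorna_id", "name", "box_type", "family_id", "sequence",
                     "chrom", "start", "end", "strand", "host_gene_id",
                     "host_biotype")

#' Read a snoRNA annotation table
#'
#' Reads the tab-separated annotation dialect: one row per snoRNA with columns
#' `snorna_id`, `name`, `box_type` (CD or HACA), `family_id`, `sequence`,
#' `chrom`, `start`, `end` (0-based half-open), `strand`, `host_gene_id`
#' (`.` when intergenic) and `host_biotype` (coding, noncoding or intergenic).
#' Sequences are normalized (uppercase, U -> T) at ingest and all type
#' invariants are validated: unique ids, `start < end`, non-empty sequences
#' over A/C/G/T/U/N, a single box type per family, and consistency between
#' host id and intergenic biotype.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of validated snoRNA records.
#' @seealso [family_table()] to derive the per-family table.
#' @export
read_annotation <- function(path) {
  records <- readr::read_tsv(
    path,
    col_types = readr::cols(
      snorna_id = readr::col_character(),
      name = readr::col_character(),
      box_type = readr::col_character(),
      family_id = readr::col_character(),
      sequence = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      host_gene_id = readr::col_character(),
      host_biotype = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  assert_cols(records, ANNOTATION_COLS, "annotation TSV")
  records$host_gene_id[records$host_gene_id %in% c(".", "")] <- NA_character_
  records$sequence <- normalize_sequence(records$sequence)
  validate_annotation(records)
  tibble::as_tibble(records)
}

validate_annotation <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  dup <- records$snorna_id[duplicated(records$snorna_id)]
  if (length(dup) > 0) {
    stop("duplicate snorna_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- !records$box_type %in% c("CD", "HACA")
  if (any(bad_type)) {
    stop("box_type must be CD or HACA (offending snorna_id: ",
         paste(records$snorna_id[bad_type], collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!records$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  bad_coord <- !is.na(records$start) & !is.na(records$end) &
    records$start >= records$end
  if (any(bad_coord)) {
    stop("start must be < end (offending snorna_id: ",
         paste(records$snorna_id[bad_coord], collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(nchar(records$sequence) == 0)) {
    stop("empty sequence (offending snorna_id: ",
         paste(records$snorna_id[nchar(records$sequence) == 0],
               collapse = ", "), ")", call. = FALSE)
  }
  bad_alpha <- grepl("[^ACGTN]", records$sequence)
  if (any(bad_alpha)) {
    stop("sequence contains characters outside {A,C,G,T,U,N}: ",
         paste(records$snorna_id[bad_alpha], collapse = ", "), call. = FALSE)
  }
  intergenic <- records$host_biotype == "intergenic"
  if (any(intergenic & !is.na(records$host_gene_id))) {
    stop("intergenic snoRNAs must have no host_gene_id: ",
         paste(records$snorna_id[intergenic & !is.na(records$host_gene_id)],
               collapse = ", "), call. = FALSE)
  }
  if (any(!intergenic & is.na(records$host_gene_id))) {
    stop("snoRNAs with a missing host_gene_id must be intergenic: ",
         paste(records$snorna_id[!intergenic & is.na(records$host_gene_id)],
               collapse = ", "), call. = FALSE)
  }
  mixed <- tapply(records$box_type, records$family_id,
                  function(x) length(unique(x)) > 1)
  if (any(mixed)) {
    stop("mixed box_type within family: ",
         paste(names(mixed)[mixed], collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Write a snoRNA annotation table
#'
#' @param records Annotation tibble as returned by [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(records, path) {
  out <- records
  out$host_gene_id[is.na(out$host_gene_id)] <- "."
  readr::write_tsv(out[, ANNOTATION_COLS], path, progress = FALSE)
  invisible(path)
}

#' Derive the per-family table from annotation records
#'
#' Families are assembled by grouping on `family_id`. Families of size one are
#' singletons; size two or more are multi-member families.
#'
#' @param records Annotation tibble.
#' @return Tibble with `family_id`, `box_type`, `n_members` and a `member_ids`
#'   list-column.
#' @export
family_table <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(family_id = character(), box_type = character(),
                          n_members = integer(), member_ids = list()))
  }
  records |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(n_members = dplyr::n(),
                     member_ids = list(.data$snorna_id), .groups = "drop") |>
    dplyr::arrange(.data$family_id)
}

#' Read a sample panel (sample to tissue map)
#'
#' Two-column TSV `sample_id`, `tissue`. The canonical tissue order is the
#' order of first appearance in the file and is used to break top-tissue ties.
#'
#' @param path Path to the sample map TSV.
#' @return Tibble with columns `sample_id` and `tissue`.
#' @export
read_sample_panel <- function(path) {
  panel <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    tissue = readr::col_character()
  ), progress = FALSE)
  assert_cols(panel, c("sample_id", "tissue"), "sample panel TSV")
  validate_panel(panel)
  tibble::as_tibble(panel)
}

validate_panel <- function(panel) {
  dup <- panel$sample_id[duplicated(panel$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) == 0) stop("empty sample panel", call. = FALSE)
  invisible(panel)
}

#' @rdname read_sample_panel
#' @param panel Panel tibble.
#' @return `tissue_order()` returns the canonical tissue order.
#' @export
tissue_order <- function(panel) unique(panel$tissue)

#' @rdname read_sample_panel
#' @export
write_sample_panel <- function(panel, path) {
  readr::write_tsv(panel[, c("sample_id", "tissue")], path, progress = FALSE)
  invisible(path)
}

#' Read a TPM abundance matrix
#'
#' TSV with first column `snorna_id` and one column of non-negative TPM values
#' per sample. Every sample in the panel must be present and no extra sample
#' columns are allowed; negative values raise an error naming the cell.
#'
#' @param path Path to the abundance TSV.
#' @param panel Sample panel tibble (see [read_sample_panel()]).
#' @return Tibble keyed by `snorna_id` with one numeric column per sample, in
#'   panel order.
#' @export
read_abundance <- function(path, panel) {
  mat <- readr::read_tsv(path, col_types = readr::cols(
    snorna_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  assert_cols(mat, "snorna_id", "abundance TSV")
  validate_abundance(mat, panel)
  tibble::as_tibble(mat[, c("snorna_id", panel$sample_id)])
}

validate_abundance <- function(mat, panel) {
  samples <- sample_cols(mat)
  extra <- setdiff(samples, panel$sample_id)
  if (length(extra) > 0) {
    stop("abundance sample(s) absent from panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(panel$sample_id, samples)
  if (length(missing) > 0) {
    stop("panel sample(s) missing from abundance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- mat$snorna_id[duplicated(mat$snorna_id)]
  if (length(dup) > 0) {
    stop("duplicate snorna_id in abundance matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (s in samples) {
    v <- mat[[s]]
    if (anyNA(v)) {
      stop(sprintf("missing value in abundance cell (%s, %s)",
                   mat$snorna_id[which(is.na(v))[1]], s), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("negative TPM in abundance cell (%s, %s)",
                   mat$snorna_id[which(v < 0)[1]], s), call. = FALSE)
    }
  }
  invisible(mat)
}

#' @rdname read_abundance
#' @param mat Abundance tibble.
#' @export
write_abundance <- function(mat, path) {
  readr::write_tsv(mat, path, progress = FALSE)
  invisible(path)
}

#' Export snoRNA sequences as FASTA
#'
#' Convenience emitter: one record per snoRNA, 60-column wrapped.
#'
#' @param records Annotation tibble.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[i]
    body <- substring(seq, seq(1, nchar(seq), 60),
                      pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
    c(paste0(">", records$snorna_id[i]), body)
  }))
  writeLines(lines, path)
  invisible(path)
}
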