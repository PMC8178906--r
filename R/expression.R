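# Expression-status module: reduce sample-level TPM to tissue means and call
# each snoRNA expressed or not. The study's rule: a snoRNA is expressed if it
# reaches the TPM threshold (default 1) in at least one sample.

#' Reduce a sample-level TPM matrix to per-tissue means
#'
#' Each cell is the arithmetic mean of the snoRNA's TPM over the samples of
#' one tissue. Column order follows the panel's canonical tissue order.
#'
#' @param abundance Abundance tibble (`snorna_id` + one column per sample).
#' @param panel Sample panel tibble mapping `sample_id` to `tissue`.
#' @return Tibble with `snorna_id` and one numeric column per tissue.
#' @export
tissue_means <- function(abundance, panel) {
  validate_abundance(abundance, panel)
  tissues <- tissue_order(panel)
  m <- as.matrix(abundance[, panel$sample_id, drop = FALSE])
  out <- tibble::tibble(snorna_id = abundance$snorna_id)
  for (t in tissues) {
    cols <- panel$sample_id[panel$tissue == t]
    out[[t]] <- rowMeans(m[, cols, drop = FALSE])
  }
  out
}

#' Expression status of a TPM vector
#'
#' `TRUE` when the maximum over samples reaches the threshold. The comparison
#' is inclusive (`>=`) by default; set `inclusive = FALSE` for a strict `>`.
#'
#' @param x Numeric vector of per-sample TPM for one snoRNA.
#' @param threshold Expression threshold in TPM (default 1).
#' @param inclusive Use `>=` (default) rather than `>`.
#' @return Logical scalar.
#' @export
is_expressed <- function(x, threshold = 1, inclusive = TRUE) {
  if (length(x) == 0) stop("empty TPM vector", call. = FALSE)
  if (inclusive) max(x) >= threshold else max(x) > threshold
}

#' Tissue where a snoRNA is most expressed
#'
#' Returns, per snoRNA, the tissue with the highest mean abundance. Ties are
#' resolved by the canonical tissue order (column order of `means`); rows that
#' are zero in every tissue get the sentinel `"none"`.
#'
#' @param means Tissue-means tibble from [tissue_means()].
#' @return Tibble with `snorna_id` and `top_tissue`.
#' @export
top_tissue <- function(means) {
  tissues <- tissue_cols(means)
  m <- as.matrix(means[, tissues, drop = FALSE])
  idx <- max.col(m, ties.method = "first")
  top <- tissues[idx]
  top[rowSums(m > 0) == 0] <- "none"
  tibble::tibble(snorna_id = means$snorna_id, top_tissue = top)
}

#' Per-snoRNA expression summary
#'
#' Emits the per-snoRNA expression columns: status, average/min/max TPM over
#' all samples, and the tissue of highest mean abundance.
#'
#' @inheritParams tissue_means
#' @inheritParams is_expressed
#' @return Tibble with `snorna_id`, `expressed`, `avg_tpm`, `min_tpm`,
#'   `max_tpm`, `top_tissue`.
#' @export
expression_table <- function(abundance, panel, threshold = 1,
                             inclusive = TRUE) {
  validate_abundance(abundance, panel)
  m <- as.matrix(abundance[, panel$sample_id, drop = FALSE])
  mx <- apply(m, 1, max)
  tbl <- tibble::tibble(
    snorna_id = abundance$snorna_id,
    expressed = if (inclusive) mx >= threshold else mx > threshold,
    avg_tpm = rowMeans(m),
    min_tpm = apply(m, 1, min),
    max_tpm = mx
  )
  dplyr::left_join(tbl, top_tissue(tissue_means(abundance, panel)),
                   by = "snorna_id")
}

#' Family-level expression summary
#'
#' Counts members and expressed members per family.
#'
#' @param records Annotation tibble.
#' @param statuses Tibble with `snorna_id` and logical `expressed` (e.g. from
#'   [expression_table()]).
#' @return Tibble with `family_id`, `box_type`, `n_members`, `n_expressed`
#'   and `fraction_expressed`.
#' @export
family_expression_summary <- function(records, statuses) {
  records |>
    dplyr::select("snorna_id", "family_id", "box_type") |>
    dplyr::inner_join(statuses[, c("snorna_id", "expressed")],
                      by = "snorna_id") |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_expressed = sum(.data$expressed),
      fraction_expressed = .data$n_expressed / .data$n_members,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family_id)
}
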