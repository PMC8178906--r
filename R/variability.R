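# Abundance-variability module: coefficient of variation at member and
# family level, the signed distance of each family from the x = y diagonal
# (family CV vs mean member CV), a rank test comparing the two snoRNA
# classes on that distance, and the family-size vs total-abundance
# correlation.

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)`. The standard deviation uses the sample
#' convention (n - 1 denominator) by default; `ddof = 0` gives the
#' population convention. Undefined (NA) when the mean is zero.
#'
#' @param x Numeric vector (at least 2 values).
#' @param ddof Delta degrees of freedom: 1 (sample, default) or 0
#'   (population).
#' @return CV as a percent, or `NA` when the mean is 0.
#' @export
cv_percent <- function(x, ddof = 1) {
  if (length(x) < 2) stop("CV needs at least 2 values", call. = FALSE)
  mu <- mean(x)
  if (mu == 0) return(NA_real_)
  s <- sd(x)
  if (ddof == 0) s <- s * sqrt((length(x) - 1) / length(x))
  100 * s / mu
}

#' Family vs member abundance variability
#'
#' For every family with at least one expressed member: the family CV is the
#' CV across tissues of the per-tissue sums of the expressed members'
#' abundance; the mean member CV averages each expressed member's own CV
#' across tissues. `diag_distance = (family_cv - mean_member_cv) / sqrt(2)`
#' is the signed perpendicular distance from the x = y diagonal — negative
#' when member variability exceeds family variability.
#'
#' @param records Annotation tibble.
#' @param means Tissue-means tibble from [tissue_means()].
#' @param statuses Tibble with `snorna_id` and `expressed`.
#' @param ddof Passed to [cv_percent()].
#' @return Tibble with `family_id`, `box_type`, `n_expressed`, `family_cv`,
#'   `mean_member_cv`, `diag_distance`. Families without expressed members
#'   are skipped.
#' @export
family_variability <- function(records, means, statuses, ddof = 1) {
  tissues <- tissue_cols(means)
  joined <- records[, c("snorna_id", "family_id", "box_type")] |>
    dplyr::inner_join(statuses[, c("snorna_id", "expressed")],
                      by = "snorna_id") |>
    dplyr::filter(.data$expressed) |>
    dplyr::inner_join(means, by = "snorna_id")
  joined |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      n_expressed = dplyr::n(),
      family_cv = cv_percent(
        colSums(as.matrix(dplyr::pick(dplyr::all_of(tissues)))), ddof),
      mean_member_cv = mean(apply(
        as.matrix(dplyr::pick(dplyr::all_of(tissues))), 1, cv_percent,
        ddof = ddof)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      diag_distance = (.data$family_cv - .data$mean_member_cv) / sqrt(2)) |>
    dplyr::arrange(.data$family_id)
}

#' Compare the two snoRNA classes on diagonal distance
#'
#' Two-sided Mann-Whitney U test (normal approximation with continuity
#' correction) on the diagonal-distance samples of box C/D versus box H/ACA
#' families. The reported statistic U is the number of (C/D, H/ACA) pairs in
#' which the C/D value is larger, counting ties as one half.
#'
#' @param cd,haca Numeric vectors of per-family diagonal distances.
#' @return A `snofam_mwu` object with `statistic`, `p_value` and sample
#'   sizes; see [tidy()].
#' @export
compare_classes_diag <- function(cd, haca) {
  if (length(cd) == 0 || length(haca) == 0) {
    stop("both classes need at least one value", call. = FALSE)
  }
  wt <- suppressWarnings(
    wilcox.test(cd, haca, alternative = "two.sided", exact = FALSE,
                correct = TRUE))
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_cd = length(cd), n_haca = length(haca),
         method = "Mann-Whitney U (two-sided, normal approximation)"),
    class = "snofam_mwu"
  )
}

#' @export
print.snofam_mwu <- function(x, ...) {
  cat(sprintf("%s\nU = %g (n = %d vs %d), p = %.4g\n",
              x$method, x$statistic, x$n_cd, x$n_haca, x$p_value))
  invisible(x)
}

#' @export
tidy.snofam_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_cd = x$n_cd, n_haca = x$n_haca, method = x$method)
}

#' @export
glance.snofam_mwu <- function(x, ...) tidy(x)

#' Correlate family size with total family abundance
#'
#' Per class, correlates the number of expressed members per family with the
#' family's average total abundance (the mean over samples of the summed
#' member TPM, equivalently the sum of the members' average TPM). Families
#' with at least one expressed member enter; by default the sum includes all
#' members (unexpressed members contribute near-zero TPM), set
#' `expressed_only_sum = TRUE` to restrict the sum to expressed members.
#'
#' @param records Annotation tibble.
#' @param abundance Abundance tibble.
#' @param statuses Tibble with `snorna_id` and `expressed`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param expressed_only_sum Restrict the abundance sum to expressed members.
#' @return Tibble with one row per class: `box_type`, `n`, `r`, `p_value`,
#'   `method`. `r` is `NA` when either variable has zero variance.
#' @export
correlate_size_abundance <- function(records, abundance, statuses,
                                     method = c("pearson", "spearman"),
                                     expressed_only_sum = FALSE) {
  method <- match.arg(method)
  fam <- family_total_abundance(records, abundance, statuses,
                                expressed_only_sum)
  fam <- fam[fam$n_expressed >= 1, ]
  per_class <- function(df) {
    if (nrow(df) < 3) {
      stop("need at least 3 families per class for correlation",
           call. = FALSE)
    }
    if (sd(df$n_expressed) == 0 || sd(df$average_sum_tpm) == 0) {
      return(tibble::tibble(n = nrow(df), r = NA_real_, p_value = NA_real_,
                            method = method))
    }
    ct <- suppressWarnings(
      cor.test(df$n_expressed, df$average_sum_tpm, method = method,
               exact = FALSE))
    tibble::tibble(n = nrow(df), r = unname(ct$estimate),
                   p_value = ct$p.value, method = method)
  }
  fam |>
    dplyr::group_by(.data$box_type) |>
    dplyr::group_modify(~per_class(.x)) |>
    dplyr::ungroup()
}

#' Average total abundance per family
#'
#' @inheritParams correlate_size_abundance
#' @param expressed_only Restrict the sum to expressed members.
#' @return Tibble with `family_id`, `box_type`, `n_expressed`,
#'   `average_sum_tpm`.
#' @export
family_total_abundance <- function(records, abundance, statuses,
                                   expressed_only = FALSE) {
  avg <- tibble::tibble(
    snorna_id = abundance$snorna_id,
    avg_tpm = rowMeans(as.matrix(abundance[, sample_cols(abundance),
                                           drop = FALSE]))
  )
  joined <- records[, c("snorna_id", "family_id", "box_type")] |>
    dplyr::inner_join(statuses[, c("snorna_id", "expressed")],
                      by = "snorna_id") |>
    dplyr::inner_join(avg, by = "snorna_id")
  joined |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      n_expressed = sum(.data$expressed),
      average_sum_tpm = if (expressed_only) sum(.data$avg_tpm[.data$expressed])
      else sum(.data$avg_tpm),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family_id)
}
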