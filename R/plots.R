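# ggplot2 views of the standard result types: per-family abundance
# profiles, family-size composition, family-vs-member variability, the
# top-member heatmap and per-family identity distributions.

#' Abundance profile of one family across tissues
#'
#' Grouped bar chart of per-tissue mean TPM for the (expressed, by default)
#' members of one family.
#'
#' @param means Tissue-means tibble from [tissue_means()].
#' @param records Annotation tibble.
#' @param family_id Family to plot.
#' @param statuses Optional status tibble; when given, only expressed
#'   members are drawn.
#' @param log_scale Use a log10 y axis.
#' @return A ggplot object.
#' @export
plot_family_profile <- function(means, records, family_id, statuses = NULL,
                                log_scale = TRUE) {
  ids <- records$snorna_id[records$family_id == family_id]
  if (!is.null(statuses)) {
    ids <- intersect(ids, statuses$snorna_id[statuses$expressed])
  }
  df <- means[means$snorna_id %in% ids, ] |>
    tidyr::pivot_longer(-"snorna_id", names_to = "tissue",
                        values_to = "mean_tpm") |>
    dplyr::mutate(tissue = factor(.data$tissue, levels = tissue_cols(means)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue,
                                        y = .data$mean_tpm,
                                        fill = .data$snorna_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = family_id, x = NULL, y = "mean abundance (TPM)",
                  fill = "member") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Family size composition, expressed vs not
#'
#' Stacked bars of expressed and non-detected member counts per family.
#'
#' @param fam_summary Output of [family_expression_summary()].
#' @param box_type Optional class filter ("CD" or "HACA").
#' @param min_members Smallest family size shown (default 3).
#' @return A ggplot object.
#' @export
plot_family_sizes <- function(fam_summary, box_type = NULL,
                              min_members = 3) {
  df <- fam_summary
  if (!is.null(box_type)) df <- df[df$box_type == box_type, ]
  df <- df[df$n_members >= min_members, ]
  df <- df |>
    dplyr::mutate(not_expressed = .data$n_members - .data$n_expressed) |>
    tidyr::pivot_longer(c("n_expressed", "not_expressed"),
                        names_to = "status", values_to = "count") |>
    dplyr::mutate(status = ifelse(.data$status == "n_expressed",
                                  "expressed", "not detected"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$family_id, -.data$n_members),
    y = .data$count, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(expressed = "#b2182b",
                                          `not detected` = "#fddbc7")) +
    ggplot2::labs(x = NULL, y = "members", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       size = 6))
}

#' Family vs member abundance variability
#'
#' Scatter of the family CV (total abundance across tissues) against the
#' mean member CV, with the x = y diagonal; families below the diagonal have
#' more member variability than family variability.
#'
#' @param fam_var Output of [family_variability()].
#' @return A ggplot object.
#' @export
plot_family_variability <- function(fam_var) {
  ggplot2::ggplot(fam_var, ggplot2::aes(x = .data$mean_member_cv,
                                        y = .data$family_cv,
                                        colour = .data$n_expressed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$box_type)) +
    ggplot2::labs(x = "mean member CV (%)", y = "family CV (%)",
                  colour = "expressed\nmembers") +
    ggplot2::theme_minimal()
}

#' Categorical heatmap of the top member per tissue
#'
#' Tiles coloured by the overall rank of the member most abundant in each
#' tissue; rank changes across a row reveal a switch.
#'
#' @param heat Output of [top_member_matrix()].
#' @return A ggplot object.
#' @export
plot_top_member_heatmap <- function(heat) {
  tissues <- setdiff(names(heat), c("family_id", "box_type"))
  df <- heat |>
    tidyr::pivot_longer(dplyr::all_of(tissues), names_to = "tissue",
                        values_to = "rank") |>
    dplyr::mutate(tissue = factor(.data$tissue, levels = tissues),
                  rank = factor(.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$family_id,
                                   fill = .data$rank)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "member rank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6),
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn family_identity Boxplot-style view of the pairwise identity
#'   distribution of one family.
#' @param object A `snofam_identity` object.
#' @param ... Unused.
#' @export
autoplot.snofam_identity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id,
                                   y = .data$identity)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "pairwise identity (%)") +
    ggplot2::ylim(min(60, min(df$identity)), 100) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
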