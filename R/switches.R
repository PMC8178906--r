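# Switch-detection module: rank expressed family members by total abundance,
# call the most abundant member per tissue, and flag families in which at
# least two distinct members rank first in different tissues.

#' Rank expressed members of a family by total abundance
#'
#' Expressed members sorted by descending total abundance (sum of tissue
#' means); ties broken by ascending member id.
#'
#' @param records Annotation tibble.
#' @param means Tissue-means tibble.
#' @param statuses Tibble with `snorna_id` and `expressed`.
#' @param family_id Family to rank.
#' @return Character vector of expressed member ids, rank 1 first.
#' @export
rank_members <- function(records, means, statuses, family_id) {
  ids <- records$snorna_id[records$family_id == family_id]
  expressed <- statuses$snorna_id[statuses$expressed]
  ids <- intersect(ids, expressed)
  if (length(ids) == 0) return(character())
  sub <- means[match(ids, means$snorna_id), ]
  totals <- rowSums(as.matrix(sub[, tissue_cols(means), drop = FALSE]))
  ids[order(-totals, ids)]
}

# Per-tissue top member among expressed members; ties resolve to the member
# with the better overall rank so floating-point ties cannot manufacture
# switches. All-zero tissues give NA ("none").
top_member_calls <- function(member_matrix, ranked_ids) {
  m <- member_matrix[ranked_ids, , drop = FALSE]  # rows in rank order
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (all(col == 0)) return(NA_character_)
    ranked_ids[which.max(col)]  # first max = best-ranked on ties
  }, character(1))
}

#' Per-family switch records
#'
#' For every family with at least one expressed member: the expressed-member
#' abundance rank, the most abundant member per tissue (`"none"`/NA where all
#' expressed members average zero), and the switch flag. A family switches
#' when at least two distinct members rank first in different tissues; only
#' families with two or more expressed members are switch-eligible.
#'
#' @inheritParams rank_members
#' @return Tibble with `family_id`, `box_type`, `n_expressed`, `eligible`,
#'   `switch`, `n_top_members`, list-columns `member_rank` and `top_members`
#'   (named by tissue).
#' @export
switch_table <- function(records, means, statuses) {
  tissues <- tissue_cols(means)
  fams <- records |>
    dplyr::inner_join(statuses[, c("snorna_id", "expressed")],
                      by = "snorna_id") |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(n_expressed = sum(.data$expressed), .groups = "drop") |>
    dplyr::filter(.data$n_expressed >= 1) |>
    dplyr::arrange(.data$family_id)

  mm <- as.matrix(means[, tissues, drop = FALSE])
  rownames(mm) <- means$snorna_id

  rows <- lapply(seq_len(nrow(fams)), function(i) {
    fid <- fams$family_id[i]
    ranked <- rank_members(records, means, statuses, fid)
    tops <- setNames(top_member_calls(mm, ranked), tissues)
    distinct <- unique(tops[!is.na(tops)])
    eligible <- length(ranked) >= 2
    list(member_rank = ranked, top_members = tops,
         n_top_members = length(distinct),
         eligible = eligible,
         switch = eligible && length(distinct) >= 2)
  })

  fams$eligible <- vapply(rows, `[[`, logical(1), "eligible")
  fams$switch <- vapply(rows, `[[`, logical(1), "switch")
  fams$n_top_members <- vapply(rows, `[[`, integer(1), "n_top_members")
  fams$member_rank <- lapply(rows, `[[`, "member_rank")
  fams$top_members <- lapply(rows, `[[`, "top_members")
  fams
}

#' Family-by-tissue matrix of top-member rank indices
#'
#' The categorical-heatmap matrix: for each family and tissue, the overall
#' abundance rank (1 = most abundant overall) of the member that is most
#' abundant in that tissue; `NA` for degenerate tissues. Only switch-eligible
#' families (two or more expressed members) are included.
#'
#' @param st Switch table from [switch_table()].
#' @return Wide tibble, one row per eligible family, one column per tissue.
#' @export
top_member_matrix <- function(st) {
  st <- st[st$eligible, ]
  if (nrow(st) == 0) {
    return(tibble::tibble(family_id = character()))
  }
  tissues <- names(st$top_members[[1]])
  out <- tibble::tibble(family_id = st$family_id, box_type = st$box_type)
  for (t in tissues) {
    out[[t]] <- vapply(seq_len(nrow(st)), function(i) {
      top <- st$top_members[[i]][[t]]
      if (is.na(top)) NA_integer_ else match(top, st$member_rank[[i]])
    }, integer(1))
  }
  out
}

#' Families whose expressed members share one top tissue
#'
#' Per class: `n` counts families with at least two expressed members, `k`
#' those whose expressed members are all most expressed in the same tissue.
#'
#' @param records Annotation tibble.
#' @param statuses Tibble with `snorna_id`, `expressed` and `top_tissue`
#'   (from [expression_table()]).
#' @return Tibble with `box_type`, `k`, `n`, `fraction`.
#' @export
same_tissue_top_fraction <- function(records, statuses) {
  assert_cols(statuses, c("snorna_id", "expressed", "top_tissue"),
              "statuses")
  joined <- records[, c("snorna_id", "family_id", "box_type")] |>
    dplyr::inner_join(
      statuses[, c("snorna_id", "expressed", "top_tissue")],
      by = "snorna_id") |>
    dplyr::filter(.data$expressed)
  per_fam <- joined |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      n_expressed = dplyr::n(),
      coherent = length(unique(.data$top_tissue)) == 1 &&
        !any(.data$top_tissue == "none"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_expressed >= 2)
  per_fam |>
    dplyr::group_by(.data$box_type) |>
    dplyr::summarise(k = sum(.data$coherent), n = dplyr::n(),
                     fraction = .data$k / .data$n, .groups = "drop")
}
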