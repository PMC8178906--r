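# Pairwise sequence identity within families. Identity between two snoRNAs
# is the optimal score of a global alignment rewarding 1 per matched residue
# with no mismatch or gap penalty — i.e. the longest-common-subsequence
# length — divided by the length of the shorter sequence, times 100. The
# score is unique even when optimal alignments are not, so no traceback is
# ever computed.

#' Percent identity between two sequences
#'
#' `100 * LCS(a, b) / min(|a|, |b|)`, where LCS is the longest common
#' subsequence length. Symmetric; always in (0, 100]; `pairwise_identity(s,
#' s)` is 100 for any non-empty `s`.
#'
#' @param a,b Nucleotide sequences (normalized internally).
#' @return Percent identity as a scalar.
#' @examples
#' pairwise_identity("AAAA", "AAAATTTT") # 100: shorter-sequence normalization
#' pairwise_identity("ACGT", "AGGT")     # 75: LCS "AGT" over min length 4
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("identity undefined for empty sequences", call. = FALSE)
  }
  a <- normalize_sequence(a)
  b <- normalize_sequence(b)
  100 * lcs_length_cpp(a, b) / min(nchar(a), nchar(b))
}

#' Identity matrix of one family
#'
#' Scores all unordered member pairs of a family and the per-member mean
#' identity against all other members (the per-snoRNA alignment-score
#' column). Undefined for singletons.
#'
#' @param records Annotation tibble.
#' @param family_id Family to score.
#' @return A `snofam_identity` object: list with `family_id`, the symmetric
#'   percent-identity `matrix` (diagonal 100) and a `member_means` tibble.
#' @export
family_identity <- function(records, family_id) {
  fam <- records[records$family_id == family_id, ]
  if (nrow(fam) == 0) stop("unknown family: ", family_id, call. = FALSE)
  if (nrow(fam) < 2) {
    stop("identity undefined for singleton family: ", family_id,
         call. = FALSE)
  }
  mat <- lcs_identity_matrix_cpp(normalize_sequence(fam$sequence))
  dimnames(mat) <- list(fam$snorna_id, fam$snorna_id)
  means <- (rowSums(mat) - 100) / (nrow(fam) - 1)
  structure(
    list(family_id = family_id, matrix = mat,
         member_means = tibble::tibble(snorna_id = fam$snorna_id,
                                       mean_identity = unname(means))),
    class = "snofam_identity"
  )
}

#' @export
print.snofam_identity <- function(x, ...) {
  offdiag <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("<snofam_identity> family %s: %d members, identity %.1f-%.1f%% (mean %.1f%%)\n",
              x$family_id, nrow(x$matrix), min(offdiag), max(offdiag),
              mean(offdiag)))
  invisible(x)
}

#' @export
tidy.snofam_identity <- function(x, ...) {
  mat <- x$matrix
  ids <- rownames(mat)
  pairs <- which(upper.tri(mat), arr.ind = TRUE)
  tibble::tibble(
    family_id = x$family_id,
    member_a = ids[pairs[, 1]],
    member_b = ids[pairs[, 2]],
    identity = mat[pairs]
  )
}

#' Per-snoRNA mean identity across the whole cohort
#'
#' Mean pairwise identity of each snoRNA against all other members of its
#' family; `NA` for singletons.
#'
#' @param records Annotation tibble.
#' @return Tibble with `snorna_id` and `alignment_score`.
#' @export
mean_member_identity <- function(records) {
  out <- tibble::tibble(snorna_id = records$snorna_id,
                        alignment_score = NA_real_)
  for (fid in unique(records$family_id)) {
    idx <- which(records$family_id == fid)
    if (length(idx) < 2) next
    mat <- lcs_identity_matrix_cpp(normalize_sequence(records$sequence[idx]))
    out$alignment_score[idx] <- (rowSums(mat) - 100) / (length(idx) - 1)
  }
  out
}

#' Families with at least one identical pair
#'
#' A pair counts as identical only when the two sequence strings are equal
#' (100% identity by LCS can also hold for nested, non-equal strings; read
#' assignment is only ambiguous between truly identical copies).
#'
#' @param records Annotation tibble.
#' @return Tibble of flagged families with `family_id`, `box_type` and
#'   `n_identical_pairs`.
#' @export
find_identical_pairs <- function(records) {
  records |>
    dplyr::mutate(sequence = normalize_sequence(.data$sequence)) |>
    dplyr::group_by(.data$family_id, .data$box_type) |>
    dplyr::summarise(
      n_identical_pairs = sum(choose(table(.data$sequence), 2)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_identical_pairs > 0) |>
    dplyr::arrange(.data$family_id)
}
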