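# Shared internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a nucleotide sequence
#'
#' Uppercases and rewrites U to T so that RNA and DNA spellings of the same
#' gene never count as mismatches during identity scoring.
#'
#' @param x Character vector of sequences.
#' @return Character vector over the alphabet A, C, G, T, N.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# GTF is 1-based closed; internal coordinates are 0-based half-open.
gtf_to_internal_start <- function(start) as.integer(start) - 1L
gtf_to_internal_end <- function(end) as.integer(end)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Sample columns of an abundance tibble (everything but the id column).
sample_cols <- function(abundance) setdiff(names(abundance), "snorna_id")

# Tissue columns of a tissue-means tibble.
tissue_cols <- function(means) setdiff(names(means), "snorna_id")
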