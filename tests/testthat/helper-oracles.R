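# Independent oracles used to validate the package's own computations.
# These deliberately use different algorithms from the implementation.

# Quadratic dynamic-programming LCS, in plain R.
oracle_lcs_dp <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(bv)
  prev <- integer(m + 1)
  for (i in seq_along(av)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (av[i] == bv[j]) prev[j] + 1L
      else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

# Exhaustive subsequence enumeration: longest subsequence of the shorter
# string that is also a subsequence of the longer one. Only for short
# strings (<= 12 nt).
oracle_lcs_enum <- function(a, b) {
  if (nchar(a) > nchar(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  stopifnot(n <= 12)
  is_subseq <- function(s) {
    i <- 1L
    for (ch in bv) if (i <= length(s) && s[i] == ch) i <- i + 1L
    i > length(s)
  }
  for (k in rev(seq_len(n))) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (idx in combos) if (is_subseq(av[idx])) return(k)
  }
  0L
}

oracle_identity <- function(a, b, oracle = oracle_lcs_dp) {
  100 * oracle(a, b) / min(nchar(a), nchar(b))
}

# Brute-force Mann-Whitney U: count of (x > y) pairs plus half-ties.
oracle_mwu_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
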