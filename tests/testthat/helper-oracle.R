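# Independent brute-force oracles; deliberately written from the textbook
# recurrences, not via adist/aregexec, so the package's fuzzy matching has a
# second route to check against.

# unit-cost Levenshtein distance, full DP matrix
lev_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (A[i] != B[j]))
    }
  }
  d[n + 1L, m + 1L]
}

# best infix occurrence of `pattern` in `text`: minimal distance over every
# substring, ties to the leftmost start; returns list(offset0, edit)
best_infix <- function(pattern, text) {
  n <- nchar(text)
  best <- list(offset0 = NA_integer_, edit = nchar(pattern))
  for (i in seq_len(n)) {
    for (j in (i - 1L):n) {   # j = i-1 is the empty substring
      sub <- if (j < i) "" else substr(text, i, j)
      d <- lev_dp(pattern, sub)
      if (d < best$edit) best <- list(offset0 = i - 1L, edit = d)
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# substitutions at positions spaced >= 3 apart, guaranteed to leave the
# Levenshtein distance equal to the substitution count (verified per use)
plant_subs <- function(seq, k, lo, hi) {
  stopifnot(hi - lo + 1L >= 3L * k)
  pos <- lo + (seq_len(k) - 1L) * 3L
  svjunction:::mutate_seq(seq, k, positions = pos)$seq
}
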