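#' In-silico cfDNA fragment size selection
#'
#' Retains fragments whose length lies in `[lo, hi]` (bounds inclusive).
#' Tumor-derived cell-free DNA is shorter on average than its wild-type
#' background, so selecting 90-150 bp fragments enriches the tumor fraction
#' ahead of copy-number analysis. Order is preserved and the operation is
#' idempotent. Fragments with zero, missing or negative length are dropped
#' with a counted warning.
#'
#' @param fragments data.frame with a `length` column (template/insert
#'   length in bp), or a numeric vector of lengths.
#' @param lo,hi inclusive length bounds in bp (defaults 90 and 150).
#' @return the retained subset, same type as the input.
#' @export
size_select <- function(fragments, lo = 90, hi = 150) {
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  len <- if (is.data.frame(fragments)) fragments$length else fragments
  len <- abs(as.numeric(len))
  bad <- is.na(len) | len <= 0
  if (any(bad))
    warning(sum(bad), " fragment(s) with zero/undefined length dropped")
  keep <- !bad & len >= lo & len <= hi
  if (is.data.frame(fragments)) fragments[keep, , drop = FALSE]
  else fragments[keep]
}

#' Fragment length histogram
#'
#' @param fragments data.frame with a `length` column, or numeric lengths.
#' @param bin bin width in bp (default 1).
#' @return data.frame `length` (bin lower edge), `count`; counts sum to the
#'   number of input fragments with finite length.
#' @export
size_histogram <- function(fragments, bin = 1) {
  len <- if (is.data.frame(fragments)) fragments$length else fragments
  len <- abs(as.numeric(len))
  len <- len[is.finite(len)]
  if (!length(len))
    return(data.frame(length = numeric(0), count = integer(0)))
  edges <- floor(len / bin) * bin
  tab <- table(edges)
  data.frame(length = as.numeric(names(tab)), count = as.integer(tab))
}
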