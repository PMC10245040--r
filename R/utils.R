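#' @importFrom Biostrings DNAString DNAStringSet reverseComplement readDNAStringSet writeXStringSet
#' @importFrom stats rbinom rgeom rnorm rpois runif setNames lm coef cor.test pt
#' @importFrom utils adist aregexec read.delim write.table regmatches
NULL

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Unit-cost Levenshtein distance between two sequences
#'
#' Mismatches, insertions and deletions each cost 1. Backed by
#' [utils::adist()].
#'
#' @param a,b character scalars.
#' @return integer edit distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 1)))
}

## Best approximate occurrence of `pattern` inside `text`:
## minimal edit distance first, then leftmost.  Implemented by widening the
## aregexec budget from 0 until a hit appears; at the first admitting budget
## every reported match has exactly that distance, so aregexec's leftmost
## semantics give the leftmost minimal-distance occurrence.
approx_find <- function(pattern, text, max_edit) {
  if (is.na(text) || nchar(text) == 0L || nchar(pattern) == 0L) return(NULL)
  ## fast path: exact substring
  hit <- regexpr(pattern, text, fixed = TRUE)
  if (hit > 0L) {
    return(list(offset = as.integer(hit) - 1L, edit = 0L,
                match_len = nchar(pattern)))
  }
  if (max_edit < 1L) return(NULL)
  for (d in seq_len(max_edit)) {
    m <- utils::aregexec(pattern, text, max.distance = d, fixed = TRUE)[[1]]
    if (m[1] > 0L) {
      return(list(offset = as.integer(m[1]) - 1L, edit = as.integer(d),
                  match_len = attr(m, "match.length")[1]))
    }
  }
  NULL
}

## aregexec counts substitutions/ins/del at unit cost by default when
## max.distance is an integer; confirmed against the DP oracle in tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

## chromosome ordering used when canonicalizing breakpoint pairs
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(num), num,
                 ifelse(core == "X", 23L, ifelse(core == "Y", 24L, 25L)))
  rank
}

is_primary_chrom <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  (!is.na(num) & num >= 1L & num <= 22L) | core %in% c("X", "Y")
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

## seeded RNG scope helper: runs expr with a local RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## plant k substitutions at given 1-based positions (or random positions)
mutate_seq <- function(seq, n_sub = 0L, positions = NULL) {
  if (n_sub == 0L) return(list(seq = seq, positions = integer(0)))
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) {
    positions <- sort(sample(seq_along(chars), n_sub))
  }
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- sample(alt, 1)
  }
  list(seq = paste(chars, collapse = ""), positions = positions)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
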