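#' Extract soft-clipped junction candidates from an alignment set
#'
#' Keeps mapped reads whose CIGAR begins or ends with a soft or hard clip of
#' at least `min_clip` bases — the signature of a read crossing a structural
#' variant junction. Records with unparseable CIGARs are skipped and counted.
#'
#' @param aln data.frame from [read_alignments()] (or a SAM/BAM path).
#' @param min_clip minimum terminal clip length (default 10).
#' @return the candidate subset, with attribute `n_skipped` giving the
#'   number of malformed records dropped.
#' @export
extract_softclip_candidates <- function(aln, min_clip = 10) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignments(aln)
  mapped <- !bitwAnd(aln$flag, 4L)
  skipped <- 0L
  keep <- vapply(seq_len(nrow(aln)), function(i) {
    if (!mapped[i]) return(FALSE)
    cg <- parse_cigar(aln$cigar[i])
    if (is.null(cg)) { skipped <<- skipped + 1L; return(FALSE) }
    first <- cg[1L, ]; last <- cg[nrow(cg), ]
    (first$op %in% c("S", "H") && first$len >= min_clip) ||
      (last$op %in% c("S", "H") && last$len >= min_clip)
  }, logical(1))
  if (skipped > 0L)
    warning(skipped, " record(s) with malformed CIGAR skipped")
  out <- aln[keep, , drop = FALSE]
  attr(out, "n_skipped") <- skipped
  out
}

#' Fuzzy-match a candidate read against a junction reference
#'
#' A read supports a junction when (i) the 20 bp of junction sequence on
#' each side of the breakpoint are both found in the read, in junction
#' order, each with at most `flank_max_edit` edits, and (ii) the Levenshtein
#' distance between the read and the corresponding window of the extended
#' junction sequence is at most `floor(max_edit_frac * effective read
#' length)`. Any UMI prefix is removed before matching and excluded from the
#' effective length. The reverse complement of the read is also tried; a hit
#' on either strand counts once.
#'
#' @param read_seq read sequence (character scalar).
#' @param junction junction reference (list with `sequence` and `center`).
#' @param flank_len flank probe length each side of the junction (default 20).
#' @param flank_max_edit edits allowed per flank probe (default 2; set
#'   `flank_substitutions_only = TRUE` for mismatch-only semantics).
#' @param max_edit_frac edit budget as a fraction of effective read length
#'   (default 0.025; the budget is floored).
#' @param umi_len length of a UMI prefix to strip (0 = none).
#' @param flank_substitutions_only restrict flank matching to substitutions.
#' @return `NULL`, or a list with `edit_distance` and `strand`.
#' @export
match_junction_read <- function(read_seq, junction, flank_len = 20,
                                flank_max_edit = 2, max_edit_frac = 0.025,
                                umi_len = 0,
                                flank_substitutions_only = FALSE) {
  jseq <- toupper(junction$sequence)
  ctr <- junction$center
  if (ctr < flank_len || nchar(jseq) - ctr < flank_len)
    stop("junction shorter than 2*flank_len around its center", call. = FALSE)
  read <- toupper(read_seq)
  if (umi_len > 0L) read <- substring(read, umi_len + 1L)
  budget <- floor(max_edit_frac * nchar(read))
  left <- substr(jseq, ctr - flank_len + 1L, ctr)
  right <- substr(jseq, ctr + 1L, ctr + flank_len)
  try_strand <- function(rd, strand) {
    hl <- flank_hit(left, rd, flank_max_edit, flank_substitutions_only)
    if (is.null(hl)) return(NULL)
    hr <- flank_hit(right, rd, flank_max_edit, flank_substitutions_only)
    if (is.null(hr)) return(NULL)
    if (hr$offset < hl$offset + hl$match_len) return(NULL)  # junction order
    ## junction window implied by the left flank offset, +/- a small band
    start0 <- (ctr - flank_len) - hl$offset
    d <- window_distance(rd, jseq, start0, band = budget + 2L)
    if (is.null(d) || d > budget) return(NULL)
    list(edit_distance = d, strand = strand)
  }
  try_strand(read, "+") %||% try_strand(revcomp(read), "-")
}

flank_hit <- function(flank, read, max_edit, subs_only) {
  if (!subs_only) return(approx_find(flank, read, max_edit))
  ## substitutions-only: slide the flank over the read, count mismatches
  fl <- nchar(flank); rl <- nchar(read)
  if (rl < fl) return(NULL)
  fchars <- strsplit(flank, "")[[1]]
  best <- NULL
  for (off in 0:(rl - fl)) {
    mm <- sum(strsplit(substr(read, off + 1L, off + fl), "")[[1]] != fchars)
    if (mm <= max_edit && (is.null(best) || mm < best$edit)) {
      best <- list(offset = off, edit = mm, match_len = fl)
      if (mm == 0L) break
    }
  }
  best
}

## minimal edit distance between `read` and a window of `ref` of the read's
## length starting near 0-based `start0` (searched over +/- band starts).
window_distance <- function(read, ref, start0, band) {
  rl <- nchar(read); reflen <- nchar(ref)
  starts <- (start0 - band):(start0 + band)
  starts <- starts[starts >= 0L & starts + rl <= reflen]
  ## also allow truncated windows at the reference ends
  if (!length(starts)) {
    starts <- max(0L, min(start0, reflen - 1L))
  }
  best <- NULL
  for (s in starts) {
    w <- substr(ref, s + 1L, min(s + rl, reflen))
    d <- edit_distance(read, w)
    if (is.null(best) || d < best) best <- d
  }
  best
}

#' Scan candidates against a junction panel and collect hits
#'
#' @param candidates data.frame of candidate reads (see
#'   [extract_softclip_candidates()]), or raw reads as a data.frame with
#'   `name`, `seq`, `umi`, `pos` columns.
#' @param junctions list of junction references.
#' @inheritParams match_junction_read
#' @return data.frame of junction hits: `sv_id`, `name`, `umi`,
#'   `align_start`, `edit_distance`, `mode`.
#' @export
scan_junction_hits <- function(candidates, junctions, flank_len = 20,
                               flank_max_edit = 2, max_edit_frac = 0.025,
                               umi_len = 0,
                               flank_substitutions_only = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    for (j in junctions) {
      h <- match_junction_read(candidates$seq[i], j, flank_len,
                               flank_max_edit, max_edit_frac, umi_len,
                               flank_substitutions_only)
      if (!is.null(h)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sv_id = j$sv_id, name = candidates$name[i],
          umi = candidates$umi[i] %||% "",
          align_start = candidates$pos[i] %||% NA_integer_,
          edit_distance = h$edit_distance, mode = "softclip_match",
          stringsAsFactors = FALSE)
        break   # a read supports at most one junction
      }
    }
  }
  if (!length(rows))
    return(data.frame(sv_id = character(0), name = character(0),
                      umi = character(0), align_start = integer(0),
                      edit_distance = integer(0), mode = character(0)))
  do.call(rbind, rows)
}

#' Count breakpoint-spanning reads in hybrid-capture alignments
#'
#' Reads are aligned to the junction-reference FASTA (one synthetic contig
#' per SV; `ref_name` equals the `sv_id`). A read is counted iff its
#' alignment fully covers the `window` bases either side of the junction
#' point and matches the reference base-for-base inside that window (no
#' mismatch, insertion or deletion).
#'
#' @param aln data.frame from [read_alignments()] (or a SAM/BAM path).
#' @param junctions list of junction references.
#' @param window half-width of the perfect-match window (default 20).
#' @return data.frame per SV: `sv_id`, `read_count`, `molecule_count`
#'   (UMI-deduplicated, see [dedup_by_umi()]).
#' @export
count_capture_reads <- function(aln, junctions, window = 20) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignments(aln)
  jmap <- stats::setNames(junctions,
                          vapply(junctions, `[[`, character(1), "sv_id"))
  unknown <- setdiff(unique(aln$ref_name), c(names(jmap), NA))
  if (length(unknown))
    warning("skipping reads on unknown reference(s): ",
            paste(unknown, collapse = ", "))
  hits <- list()
  for (i in seq_len(nrow(aln))) {
    j <- jmap[[aln$ref_name[i]]]
    if (is.null(j)) next
    if (spans_window_perfectly(aln$pos[i], aln$cigar[i], aln$seq[i],
                               j$sequence, j$center, window)) {
      hits[[length(hits) + 1L]] <- data.frame(
        sv_id = j$sv_id, name = aln$name[i], umi = aln$umi[i] %||% "",
        align_start = aln$pos[i], edit_distance = 0L,
        mode = "capture_window", stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sv_id = character(0), name = character(0), umi = character(0),
               align_start = integer(0), edit_distance = integer(0),
               mode = character(0))
  counts <- dedup_by_umi(hits)
  ## emit zero rows for panel SVs without hits
  missing <- setdiff(names(jmap), counts$sv_id)
  if (length(missing))
    counts <- rbind(counts, data.frame(sv_id = missing, read_count = 0L,
                                       molecule_count = 0L))
  counts[order(counts$sv_id), , drop = FALSE]
}

## TRUE iff the alignment covers ref positions [center-window, center+window)
## (0-based) with an exact base-for-base match in that window.
spans_window_perfectly <- function(pos, cigar, seq, ref_seq, center, window) {
  cg <- parse_cigar(cigar)
  if (is.null(cg)) return(FALSE)
  win_lo <- center - window   # 0-based inclusive
  win_hi <- center + window   # 0-based exclusive
  ref0 <- pos - 1L            # 0-based alignment start
  q <- 1L                     # 1-based query cursor
  covered <- rep(FALSE, win_hi - win_lo)
  exact <- TRUE
  for (k in seq_len(nrow(cg))) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      for (t in seq_len(len)) {
        r0 <- ref0 + t - 1L
        if (r0 >= win_lo && r0 < win_hi) {
          covered[r0 - win_lo + 1L] <- TRUE
          if (substr(seq, q + t - 1L, q + t - 1L) !=
              substr(ref_seq, r0 + 1L, r0 + 1L)) exact <- FALSE
        }
      }
      ref0 <- ref0 + len; q <- q + len
    } else if (op == "I") {
      ## insertion inside the window breaks the 100% match
      if (ref0 > win_lo && ref0 < win_hi) exact <- FALSE
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (ref0 < win_hi && ref0 + len > win_lo) exact <- FALSE
      ref0 <- ref0 + len
    } else if (op == "S") {
      q <- q + len
    }                                  # H/P consume nothing here
    if (!exact) return(FALSE)
  }
  all(covered) && exact
}

#' Collapse junction hits to unique molecules by UMI
#'
#' PCR duplicates of one DNA molecule share the UMI and alignment start, so
#' the molecule count is the number of distinct `(sv_id, umi, align_start)`
#' keys; hits with an empty UMI fall back to `(sv_id, read name)`, i.e. no
#' collapsing beyond identical read names. Deduplication never increases a
#' count and is idempotent.
#'
#' @param hits data.frame of junction hits.
#' @return data.frame per SV: `sv_id`, `read_count`, `molecule_count`.
#' @export
dedup_by_umi <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(sv_id = character(0), read_count = integer(0),
                      molecule_count = integer(0)))
  key <- ifelse(nzchar(hits$umi),
                paste(hits$sv_id, hits$umi, hits$align_start, sep = "\r"),
                paste(hits$sv_id, hits$name, sep = "\r"))
  out <- do.call(rbind, lapply(split(seq_len(nrow(hits)), hits$sv_id),
                               function(idx) {
    data.frame(sv_id = hits$sv_id[idx[1]], read_count = length(idx),
               molecule_count = length(unique(key[idx])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Whole-genome sequencing allele fraction from junction reads
#'
#' AF = reads / (2 x mean depth x number of targeted SVs): each diploid
#' genome equivalent contributes two chromosome copies per locus, and the
#' junction reads are pooled over all targeted SVs.
#'
#' @param total_junction_reads total breakpoint-spanning reads (all SVs).
#' @param mean_depth mean sequencing coverage depth of the sample.
#' @param n_svs number of patient-specific SVs targeted.
#' @return allele fraction (a fraction, not a percentage).
#' @export
wgs_af <- function(total_junction_reads, mean_depth, n_svs) {
  stopifnot_scalar_number(total_junction_reads, "total_junction_reads")
  stopifnot_scalar_number(mean_depth, "mean_depth", positive = TRUE)
  stopifnot_scalar_number(n_svs, "n_svs", positive = TRUE)
  if (total_junction_reads < 0)
    stop("read count must be non-negative", call. = FALSE)
  total_junction_reads / (2 * mean_depth * n_svs)
}
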