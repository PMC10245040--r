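#' Locate the best approximate occurrence of a primer in a read
#'
#' Finds the occurrence of `primer` in `read_seq` with the smallest
#' unit-cost Levenshtein distance (mismatch, insertion and deletion each
#' cost 1), breaking ties by leftmost offset. Returns `NULL` when the
#' minimal distance exceeds `max_edit`.
#'
#' @param read_seq read sequence (character scalar).
#' @param primer primer sequence, length >= 10.
#' @param max_edit maximum allowed edit distance (default 2).
#' @return `NULL`, or a list with `offset` (0-based), `edit` and
#'   `match_len` (length of the matched read substring, which may differ
#'   from the primer length under indels).
#' @export
locate_primer <- function(read_seq, primer, max_edit = 2) {
  if (nchar(primer) < 10L) stop("primer length must be >= 10", call. = FALSE)
  if (is.na(read_seq) || nchar(read_seq) == 0L) return(NULL)
  approx_find(primer, read_seq, max_edit)
}

## One read versus one amplicon in a fixed orientation.
## p5 is the primer expected at the 5' end of this read, p3 the primer whose
## reverse complement closes the amplicon on this read, expected the full
## amplicon sequence in this read's orientation.
## Returns list(stage, edits, total) where stage is "pass" or the gate failed.
match_read_one_amplicon <- function(read, p5, p3rc, expected,
                                    primer_max_edit = 2,
                                    amplicon_max_edit = 5,
                                    min_product = 25) {
  h5 <- approx_find(p5, read, primer_max_edit)
  if (is.null(h5)) return(list(stage = "no_primer"))
  tail_start <- h5$offset + h5$match_len + 1L
  tail_seq <- substring(read, tail_start)
  h3 <- approx_find(p3rc, tail_seq, primer_max_edit)
  if (is.null(h3)) return(list(stage = "no_primer"))
  insert_len <- h3$offset
  if (insert_len < min_product) return(list(stage = "short_product"))
  amp_end <- tail_start + h3$offset + h3$match_len - 1L
  observed <- substr(read, h5$offset + 1L, amp_end)
  d <- edit_distance(observed, expected)
  if (d > amplicon_max_edit) return(list(stage = "amplicon_mismatch"))
  list(stage = "pass",
       edits = c(p5 = h5$edit, p3 = h3$edit, amplicon = d),
       total = d)
}

#' Classify one read pair against an amplicon panel
#'
#' Implements the fuzzy amplicon matcher: for each candidate amplicon,
#' (a) the forward and reverse primers are located in read 1 and read 2
#' separately with up to `primer_max_edit` edits each, (b) read pairs whose
#' inter-primer target is shorter than `min_product` bp are discarded,
#' (c) the amplicon sequence flanked by and including the primers is
#' extracted, (d) compared with the expected amplicon allowing up to
#' `amplicon_max_edit` edits, and (e) the pair is counted only when both
#' reads match the same amplicon. Read 1 is tested against the amplicon as
#' written (forward primer first), read 2 against its reverse complement
#' (reverse primer first); with `swap_orientation` the roles are exchanged.
#'
#' When two or more amplicons fully pass, the pair is assigned to the lowest
#' total edit distance; an exact tie yields status `ambiguous` (excluded
#' from counting). Otherwise the status reflects the furthest gate reached
#' across all amplicons, in the order `no_primer`, `short_product`,
#' `amplicon_mismatch`, `discordant_pair`.
#'
#' @param pair list with `pair_id`, `seq1`, `seq2` (qualities optional and
#'   ignored: matching is on sequence only).
#' @param panel data.frame with columns `amplicon_id`, `sv_id`, `fwd_seq`,
#'   `rev_seq` (primer as synthesized), `expected_amplicon`, `is_control`.
#' @param primer_max_edit maximum edits per primer match (default 2).
#' @param amplicon_max_edit maximum edits for the full amplicon (default 5).
#' @param min_product minimum inter-primer target length in bp (default 25).
#' @param swap_orientation test read 1 as the reverse-primer strand.
#' @return list with `pair_id`, `amplicon_id` (or `NA`), `status`, `edits`.
#' @export
classify_read_pair <- function(pair, panel, primer_max_edit = 2,
                               amplicon_max_edit = 5, min_product = 25,
                               swap_orientation = FALSE) {
  stopifnot(nrow(panel) > 0L)
  r1 <- toupper(pair$seq1); r2 <- toupper(pair$seq2)
  if (swap_orientation) { tmp <- r1; r1 <- r2; r2 <- tmp }
  stage_rank <- c(no_primer = 0L, short_product = 1L, amplicon_mismatch = 2L,
                  pass = 3L)
  best_rank <- 0L
  r1_pass <- character(0)   # amplicons fully matched by read 1 alone
  r2_pass <- character(0)
  passes <- list()
  for (k in seq_len(nrow(panel))) {
    amp <- panel[k, ]
    expected <- toupper(amp$expected_amplicon)
    m1 <- match_read_one_amplicon(r1, toupper(amp$fwd_seq),
                                  revcomp(toupper(amp$rev_seq)), expected,
                                  primer_max_edit, amplicon_max_edit,
                                  min_product)
    m2 <- match_read_one_amplicon(r2, toupper(amp$rev_seq),
                                  revcomp(toupper(amp$fwd_seq)),
                                  revcomp(expected),
                                  primer_max_edit, amplicon_max_edit,
                                  min_product)
    if (m1$stage == "pass" && m2$stage == "pass") {
      passes[[length(passes) + 1L]] <- list(
        amplicon_id = amp$amplicon_id, total = m1$total + m2$total,
        edits = c(fwd_primer_r1 = unname(m1$edits["p5"]),
                  rev_primer_r1 = unname(m1$edits["p3"]),
                  amplicon_r1 = unname(m1$edits["amplicon"]),
                  amplicon_r2 = unname(m2$edits["amplicon"])))
    } else {
      ## the pair's stage for this amplicon is the earlier failing gate
      pair_rank <- min(stage_rank[[m1$stage]], stage_rank[[m2$stage]])
      best_rank <- max(best_rank, pair_rank)
      if (m1$stage == "pass") r1_pass <- c(r1_pass, amp$amplicon_id)
      if (m2$stage == "pass") r2_pass <- c(r2_pass, amp$amplicon_id)
    }
  }
  if (length(passes) == 1L) {
    p <- passes[[1L]]
    return(list(pair_id = pair$pair_id, amplicon_id = p$amplicon_id,
                status = "matched", edits = p$edits))
  }
  if (length(passes) > 1L) {
    totals <- vapply(passes, `[[`, numeric(1), "total")
    if (sum(totals == min(totals)) > 1L)
      return(list(pair_id = pair$pair_id, amplicon_id = NA_character_,
                  status = "ambiguous", edits = NULL))
    p <- passes[[which.min(totals)]]
    return(list(pair_id = pair$pair_id, amplicon_id = p$amplicon_id,
                status = "matched", edits = p$edits))
  }
  ## no joint pass: did the two reads each fully match different amplicons?
  status <- names(stage_rank)[match(best_rank, stage_rank)]
  if (length(r1_pass) && length(r2_pass)) status <- "discordant_pair"
  list(pair_id = pair$pair_id, amplicon_id = NA_character_, status = status,
       edits = NULL)
}

#' Classify all read pairs in a paired FASTQ run
#'
#' @param fq1,fq2 paths to the read 1 / read 2 FASTQ files (optionally
#'   gzipped), or character vectors of sequences (named by pair id).
#' @inheritParams classify_read_pair
#' @return data.frame with one row per pair: `pair_id`, `amplicon_id`,
#'   `status`, and the four edit counters (NA unless matched).
#' @export
classify_fastq_run <- function(fq1, fq2, panel, primer_max_edit = 2,
                               amplicon_max_edit = 5, min_product = 25,
                               swap_orientation = FALSE) {
  reads <- function(x) {
    if (length(x) == 1L && file.exists(x)) {
      s <- Biostrings::readDNAStringSet(x, format = "fastq")
      stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
    } else x
  }
  s1 <- reads(fq1); s2 <- reads(fq2)
  if (length(s1) != length(s2))
    stop("read 1 and read 2 counts differ", call. = FALSE)
  ids <- names(s1) %||% as.character(seq_along(s1))
  rows <- lapply(seq_along(s1), function(i) {
    m <- classify_read_pair(list(pair_id = ids[i], seq1 = s1[[i]],
                                 seq2 = s2[[i]]),
                            panel, primer_max_edit, amplicon_max_edit,
                            min_product, swap_orientation)
    data.frame(pair_id = m$pair_id,
               amplicon_id = m$amplicon_id %||% NA_character_,
               status = m$status,
               fwd_primer_r1 = if (is.null(m$edits)) NA_integer_ else m$edits[["fwd_primer_r1"]],
               rev_primer_r1 = if (is.null(m$edits)) NA_integer_ else m$edits[["rev_primer_r1"]],
               amplicon_r1 = if (is.null(m$edits)) NA_integer_ else m$edits[["amplicon_r1"]],
               amplicon_r2 = if (is.null(m$edits)) NA_integer_ else m$edits[["amplicon_r2"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tabulate matched read pairs per sample, well and amplicon
#'
#' @param matches data.frame from [classify_fastq_run()].
#' @param layout data.frame mapping `pair_id` to `sample_id` and `well_id`.
#' @param copies data.frame with `sample_id`, `well_id`, `input_copies`
#'   (amplifiable copies loaded per well); optional.
#' @param panel panel data.frame; zero rows are emitted for panel amplicons
#'   with no matches in a well.
#' @return a well count table: `sample_id`, `well_id`, `amplicon_id`,
#'   `sv_id`, `is_control`, `matched_pair_count`, `input_copies`.
#' @export
tabulate_counts <- function(matches, layout, copies = NULL, panel) {
  matched <- matches[matches$status == "matched", , drop = FALSE]
  missing <- setdiff(matched$pair_id, layout$pair_id)
  if (length(missing))
    stop("no layout entry for matched pair(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  m <- merge(matched, layout, by = "pair_id")
  wells <- unique(layout[, c("sample_id", "well_id")])
  grid <- merge(wells, panel[, c("amplicon_id", "sv_id", "is_control")])
  agg <- if (nrow(m)) {
    stats::aggregate(list(matched_pair_count = m$pair_id),
                     by = m[, c("sample_id", "well_id", "amplicon_id")],
                     FUN = length)
  } else {
    data.frame(sample_id = character(0), well_id = character(0),
               amplicon_id = character(0), matched_pair_count = integer(0))
  }
  out <- merge(grid, agg, all.x = TRUE)
  out$matched_pair_count[is.na(out$matched_pair_count)] <- 0L
  if (!is.null(copies)) out <- merge(out, copies, all.x = TRUE)
  else out$input_copies <- NA_real_
  out <- out[order(out$sample_id, out$well_id, out$amplicon_id), ]
  rownames(out) <- NULL
  out
}

#' Per-well QC from the internal positive control amplicon
#'
#' A well fails QC when the control amplicon (e.g. the housekeeper
#' `RPP30_97bp` assay) produced zero matched pairs, indicating amplification
#' failure.
#'
#' @param table well count table from [tabulate_counts()].
#' @return data.frame `sample_id`, `well_id`, `control_count`, `qc_pass`.
#' @export
control_qc <- function(table) {
  ctrl <- table[table$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0L)
    stop("panel has no control amplicon", call. = FALSE)
  agg <- stats::aggregate(list(control_count = ctrl$matched_pair_count),
                          by = ctrl[, c("sample_id", "well_id")], FUN = sum)
  agg$qc_pass <- agg$control_count > 0L
  if (!any(agg$qc_pass))
    warning("all wells failed control QC: run-level amplification failure")
  agg
}
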