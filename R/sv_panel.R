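#' Parse structural-variant calls from VCF (BND) or TSV
#'
#' Reads either a VCF 4.x file containing breakend (BND) records in bracket
#' notation, or a tab-separated table with columns `sv_id`, `chrom_a`,
#' `pos_a`, `orient_a`, `chrom_b`, `pos_b`, `orient_b`, `somatic_score`,
#' `inserted_seq`, `sample_id`. Each mated BND pair collapses to a single
#' call. Calls are canonicalized so that (`chrom_a`, `pos_a`) sorts at or
#' before (`chrom_b`, `pos_b`) by chromosome rank then position; swapping
#' sides flips both orientations and reverse-complements any inserted
#' sequence, leaving the implied junction identical up to reverse complement.
#'
#' Orientation convention: `orient_a = "+"` means the junction retains the
#' sequence ending at `pos_a` (reading left to right); `"-"` means it retains
#' the reverse complement of the sequence starting at `pos_a`. `orient_b`
#' mirrors this for the continuation after the junction point.
#'
#' @param path path to a `.vcf` or tabular file. Format is chosen by
#'   extension (`.vcf`/`.vcf.gz` versus anything else).
#' @param sample_id sample identifier recorded on calls parsed from VCF
#'   (TSV input carries its own column).
#' @return a data.frame of SV calls, one row per breakpoint pair, with a
#'   `span` column (`abs(pos_b - pos_a)` intra-chromosomal, `NA` otherwise).
#' @export
parse_sv_calls <- function(path, sample_id = "sample") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  calls <- if (ext == "vcf") parse_sv_vcf(path, sample_id) else parse_sv_tsv(path)
  validate_sv_calls(canonicalize_sv_calls(calls))
}

parse_sv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(inserted_seq = "character"))
  req <- c("sv_id", "chrom_a", "pos_a", "orient_a", "chrom_b", "pos_b",
           "orient_b", "somatic_score", "inserted_seq", "sample_id")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("SV TSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$pos_a) | !is.finite(df$pos_b) |
                 df$pos_a < 1 | df$pos_b < 1)
  if (length(bad))
    stop("malformed coordinates at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  df$inserted_seq[is.na(df$inserted_seq)] <- ""
  df[req]
}

## Interpret one BND ALT.  ALT beginning with the ref base/insert means the
## local retained side is to the LEFT of POS (orient '+'); ALT beginning with
## a bracket retains the RIGHT side (orient '-').  Bracket '[' means the mate
## piece extends rightwards on the forward strand (mate orient '+'); ']'
## means it ends at the mate position, i.e. is used reverse-complemented
## (mate orient '-').
parse_bnd_alt <- function(alt, ref) {
  m <- regmatches(alt, regexec("^(.*?)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])(.*)$",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0L || m[3] != m[6])
    stop("malformed BND ALT: ", alt, call. = FALSE)
  before <- m[2]; bracket <- m[3]; mate_chrom <- m[4]
  mate_pos <- as.integer(m[5]); after <- m[7]
  local_left <- nzchar(before)
  inserted <- if (local_left) substring(before, nchar(ref) + 1L) else
    substr(after, 1L, nchar(after) - nchar(ref))
  list(orient_local = if (local_left) "+" else "-",
       orient_mate = if (bracket == "[") "+" else "-",
       mate_chrom = mate_chrom, mate_pos = mate_pos,
       inserted = toupper(inserted))
}

parse_sv_vcf <- function(path, sample_id) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  info <- VariantAnnotation::info(vcf)
  is_bnd <- grepl("\\[|\\]", alt)
  ids <- names(rr)
  mate <- if ("MATEID" %in% names(info)) {
    sapply(info$MATEID, function(x) if (length(x)) as.character(x)[1] else NA_character_)
  } else rep(NA_character_, length(ids))
  score <- if ("SOMATICSCORE" %in% names(info)) as.integer(info$SOMATICSCORE)
           else rep(NA_integer_, length(ids))
  rec <- data.frame(id = ids,
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = BiocGenerics::start(rr),
                    ref = as.character(rr$REF), alt = alt,
                    mate = mate, score = score, stringsAsFactors = FALSE)
  rec <- rec[is_bnd, , drop = FALSE]
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (r$id %in% seen) next
    if (is.na(r$mate) || !(r$mate %in% rec$id))
      stop("unpaired BND record: ", r$id, call. = FALSE)
    m <- rec[rec$id == r$mate, ][1, ]
    seen <- c(seen, r$id, m$id)
    a <- parse_bnd_alt(r$alt, r$ref)
    if (a$mate_chrom != m$chrom || a$mate_pos != m$pos)
      stop("BND mate coordinates disagree for ", r$id, call. = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      sv_id = sub(":[0-9]+$", "", r$id),
      chrom_a = r$chrom, pos_a = r$pos, orient_a = a$orient_local,
      chrom_b = a$mate_chrom, pos_b = a$mate_pos, orient_b = a$orient_mate,
      somatic_score = r$score, inserted_seq = a$inserted,
      sample_id = sample_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

canonicalize_sv_calls <- function(df) {
  if (is.null(df) || nrow(df) == 0L)
    stop("no SV calls parsed", call. = FALSE)
  swap <- chrom_rank(df$chrom_a) > chrom_rank(df$chrom_b) |
    (df$chrom_a == df$chrom_b & df$pos_a > df$pos_b)
  if (any(swap)) {
    s <- df[swap, ]
    df[swap, c("chrom_a", "pos_a", "chrom_b", "pos_b")] <-
      s[, c("chrom_b", "pos_b", "chrom_a", "pos_a")]
    df$orient_a[swap] <- flip_orient(s$orient_b)
    df$orient_b[swap] <- flip_orient(s$orient_a)
    ins <- s$inserted_seq
    df$inserted_seq[swap] <- ifelse(nzchar(ins), revcomp(ins), "")
  }
  df$span <- ifelse(df$chrom_a == df$chrom_b, abs(df$pos_b - df$pos_a),
                    NA_integer_)
  rownames(df) <- NULL
  df
}

validate_sv_calls <- function(df) {
  if (anyDuplicated(df$sv_id))
    stop("duplicate sv_id in call set", call. = FALSE)
  if (any(df$pos_a < 1 | df$pos_b < 1))
    stop("breakpoint positions must be >= 1", call. = FALSE)
  if (!all(df$orient_a %in% c("+", "-")) || !all(df$orient_b %in% c("+", "-")))
    stop("orientations must be '+' or '-'", call. = FALSE)
  df
}

#' Copy-number step positions from a segmentation
#'
#' A step is the boundary between two adjacent segments of the same
#' chromosome whose copy numbers differ; its position is the end coordinate
#' of the left segment (0-based half-open segments, so the position equals
#' the start of the right segment).
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number` (0-based half-open; per-chromosome non-overlapping).
#' @return data.frame with columns `chrom`, `position`.
#' @export
find_cn_steps <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(segments)))
  if (any(segments$start >= segments$end))
    stop("segment start must be < end", call. = FALSE)
  segments <- segments[order(segments$chrom, segments$start), ]
  out <- list()
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, ]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping segments on ", chr, call. = FALSE)
    if (nrow(s) < 2L) next
    adjacent <- s$start[-1L] == s$end[-nrow(s)]
    differs <- s$copy_number[-1L] != s$copy_number[-nrow(s)]
    pos <- s$end[-nrow(s)][adjacent & differs]
    if (length(pos))
      out[[chr]] <- data.frame(chrom = chr, position = pos,
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), position = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read copy-number segments from a BED-like file
#'
#' Expects at least 4 columns: chrom, start, end, copy_number (no header).
#' @param path file path.
#' @return data.frame usable by [find_cn_steps()].
#' @export
read_cn_segments <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("CN BED needs >= 4 columns", call. = FALSE)
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "copy_number"))
}

#' Read a gap / simple-repeat mask from BED
#'
#' @param path BED file: chrom, start, end, and optionally a 4th column
#'   giving the interval kind (`gap` or `simple_repeat`; defaults to `gap`).
#' @return data.frame with columns `chrom`, `start`, `end`, `kind`.
#' @export
read_region_mask <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("mask BED needs >= 3 columns", call. = FALSE)
  kind <- if (ncol(df) >= 4L) df[, 4] else "gap"
  out <- data.frame(chrom = df[, 1], start = df[, 2], end = df[, 3],
                    kind = kind, stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("mask start must be < end", call. = FALSE)
  out
}

#' Blacklist recurrent breakpoints across a pooled cohort
#'
#' Pools breakpoints from calls of two or more samples and blacklists those
#' falling in recurrent clusters, using single-linkage clustering per
#' chromosome. Two clustering rules apply, mirroring standard artefact
#' removal for somatic SV panels:
#' \itemize{
#'   \item rule (i): breakpoints of *large* SVs (span > `large_span`, or
#'     inter-chromosomal) from different samples within `large_window` bp;
#'   \item rule (ii): any breakpoints from different samples within
#'     `any_window` bp.
#' }
#' A cluster is recurrent only if it contains breakpoints from at least two
#' distinct `sample_id`s.
#'
#' @param pooled_calls data.frame of SV calls (from [parse_sv_calls()])
#'   carrying `sample_id`.
#' @param large_span span above which rule (i) applies (default 100000).
#' @param large_window rule (i) linkage distance (default 2000).
#' @param any_window rule (ii) linkage distance (default 200).
#' @return data.frame of blacklisted breakpoints (`chrom`, `position`).
#' @export
cluster_recurrent_breakpoints <- function(pooled_calls, large_span = 1e5,
                                          large_window = 2000,
                                          any_window = 200) {
  if (length(unique(pooled_calls$sample_id)) < 2L) {
    warning("calls from a single sample only; empty blacklist")
    return(data.frame(chrom = character(0), position = integer(0)))
  }
  bp <- rbind(
    data.frame(chrom = pooled_calls$chrom_a, position = pooled_calls$pos_a,
               sample_id = pooled_calls$sample_id,
               large = is.na(pooled_calls$span) | pooled_calls$span > large_span),
    data.frame(chrom = pooled_calls$chrom_b, position = pooled_calls$pos_b,
               sample_id = pooled_calls$sample_id,
               large = is.na(pooled_calls$span) | pooled_calls$span > large_span))
  flag_clusters <- function(df, window) {
    hit <- rep(FALSE, nrow(df))
    for (chr in unique(df$chrom)) {
      idx <- which(df$chrom == chr)
      o <- idx[order(df$position[idx])]
      if (length(o) < 2L) next
      gaps <- diff(df$position[o])
      cl <- cumsum(c(0L, gaps >= window))   # single linkage: break at >= window
      for (g in split(o, cl)) {
        if (length(unique(df$sample_id[g])) >= 2L) hit[g] <- TRUE
      }
    }
    hit
  }
  hit_any <- flag_clusters(bp, any_window)
  hit_large <- rep(FALSE, nrow(bp))
  if (any(bp$large))
    hit_large[bp$large] <- flag_clusters(bp[bp$large, , drop = FALSE],
                                         large_window)
  keep <- hit_any | hit_large
  unique(bp[keep, c("chrom", "position")])
}

#' Filter SV calls to a high-confidence patient-specific panel
#'
#' An SV is retained iff all of the following hold:
#' \itemize{
#'   \item `somatic_score >= min_score` (default 31);
#'   \item both breakpoints lie on primary chromosomes (autosomes, X, Y);
#'   \item neither breakpoint is within `adjacency_window` bp of a gap
#'     interval nor inside a simple repeat longer than `repeat_min_len` bp;
#'   \item neither breakpoint is blacklisted as recurrent;
#'   \item the SV is inter-chromosomal or its span exceeds `min_span`;
#'   \item at least one breakpoint (both when `require_both_cn_steps`) lies
#'     within `cn_step_window` bp of a copy-number step.
#' }
#' Every failing rule is recorded, so the report is a complete audit trail.
#'
#' @param calls data.frame of canonical SV calls.
#' @param cn_steps data.frame from [find_cn_steps()] (may have zero rows).
#' @param mask data.frame from [read_region_mask()] or `NULL`.
#' @param blacklist data.frame from [cluster_recurrent_breakpoints()] or `NULL`.
#' @param min_score minimum somatic score (default 31).
#' @param min_span minimum intra-chromosomal span in bp (default 1e5, strict).
#' @param cn_step_window CN-step proximity window in bp (default 1e4).
#' @param repeat_min_len simple repeats longer than this are masked (default 100).
#' @param adjacency_window gap adjacency window in bp (default 100).
#' @param require_both_cn_steps require both breakpoints near a CN step.
#' @return a `FilterReport` data.frame: `sv_id`, `decision`
#'   (`retained`/`rejected`), `reject_reasons` (comma-joined).
#' @export
filter_high_confidence <- function(calls, cn_steps, mask = NULL,
                                   blacklist = NULL, min_score = 31,
                                   min_span = 1e5, cn_step_window = 1e4,
                                   repeat_min_len = 100,
                                   adjacency_window = 100,
                                   require_both_cn_steps = FALSE) {
  n <- nrow(calls)
  reasons <- vector("list", n)
  add <- function(i, r) reasons[[i]] <<- c(reasons[[i]], r)

  near_step <- function(chrom, pos) {
    if (is.null(cn_steps) || nrow(cn_steps) == 0L) return(rep(FALSE, length(chrom)))
    vapply(seq_along(chrom), function(i) {
      s <- cn_steps$position[cn_steps$chrom == chrom[i]]
      length(s) > 0L && min(abs(s - pos[i])) <= cn_step_window
    }, logical(1))
  }
  masked <- function(chrom, pos) {
    if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(chrom)))
    gap <- mask[mask$kind == "gap", , drop = FALSE]
    rep_ <- mask[mask$kind == "simple_repeat" &
                   (mask$end - mask$start) > repeat_min_len, , drop = FALSE]
    vapply(seq_along(chrom), function(i) {
      p0 <- pos[i] - 1L   # 0-based base position
      g <- gap[gap$chrom == chrom[i], , drop = FALSE]
      near_gap <- nrow(g) > 0L &&
        any(p0 >= g$start - adjacency_window & p0 < g$end + adjacency_window)
      r <- rep_[rep_$chrom == chrom[i], , drop = FALSE]
      in_rep <- nrow(r) > 0L && any(p0 >= r$start & p0 < r$end)
      near_gap || in_rep
    }, logical(1))
  }
  listed <- function(chrom, pos) {
    if (is.null(blacklist) || nrow(blacklist) == 0L)
      return(rep(FALSE, length(chrom)))
    paste(chrom, pos) %in% paste(blacklist$chrom, blacklist$position)
  }

  low <- calls$somatic_score < min_score
  nonprim <- !(is_primary_chrom(calls$chrom_a) & is_primary_chrom(calls$chrom_b))
  msk <- masked(calls$chrom_a, calls$pos_a) | masked(calls$chrom_b, calls$pos_b)
  blk <- listed(calls$chrom_a, calls$pos_a) | listed(calls$chrom_b, calls$pos_b)
  short <- !is.na(calls$span) & calls$span <= min_span
  near_a <- near_step(calls$chrom_a, calls$pos_a)
  near_b <- near_step(calls$chrom_b, calls$pos_b)
  no_step <- if (require_both_cn_steps) !(near_a & near_b) else !(near_a | near_b)

  for (i in seq_len(n)) {
    if (low[i]) add(i, "low_score")
    if (nonprim[i]) add(i, "non_primary_chrom")
    if (msk[i]) add(i, "repeat_or_gap_adjacent")
    if (blk[i]) add(i, "recurrent_breakpoint")
    if (short[i]) add(i, "short_intra_span")
    if (no_step[i]) add(i, "no_cn_step")
  }
  data.frame(
    sv_id = calls$sv_id,
    decision = ifelse(lengths(reasons) == 0L, "retained", "rejected"),
    reject_reasons = vapply(reasons, function(r) paste(r, collapse = ","),
                            character(1)),
    stringsAsFactors = FALSE)
}

#' Build the junction reference sequence for one SV
#'
#' Concatenates `flank_len` bases from each side of the predicted breakpoint
#' (plus any inserted sequence), honouring orientations: side A contributes
#' the `flank_len` bases ending at `pos_a` (reverse complement of the bases
#' starting at `pos_a` when `orient_a == "-"`); side B contributes the bases
#' starting at `pos_b` (reverse complement of the bases ending at `pos_b`
#' when `orient_b == "-"`). `center` is the 0-based index of the first base
#' contributed by side B.
#'
#' @param sv a one-row data.frame (an SV call).
#' @param genome a named character vector of contig sequences, or a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param flank_len flank length in bp (default 150).
#' @return list with `sv_id`, `sequence`, `center`, `flank_len`.
#' @export
build_junction_reference <- function(sv, genome, flank_len = 150) {
  genome <- as_genome(genome)
  for (chr in c(sv$chrom_a, sv$chrom_b))
    if (!chr %in% names(genome))
      stop("genome lacks contig ", chr, call. = FALSE)
  L <- flank_len
  grab <- function(chrom, from, to, rc = FALSE) {
    len <- nchar(genome[[chrom]])
    if (from < 1L || to > len)
      stop("breakpoint within ", L, " bp of the end of ", chrom,
           "; reduce flank_len", call. = FALSE)
    s <- substr(genome[[chrom]], from, to)
    if (rc) revcomp(s) else s
  }
  side_a <- if (sv$orient_a == "+") grab(sv$chrom_a, sv$pos_a - L + 1L, sv$pos_a)
            else grab(sv$chrom_a, sv$pos_a, sv$pos_a + L - 1L, rc = TRUE)
  side_b <- if (sv$orient_b == "+") grab(sv$chrom_b, sv$pos_b, sv$pos_b + L - 1L)
            else grab(sv$chrom_b, sv$pos_b - L + 1L, sv$pos_b, rc = TRUE)
  ins <- toupper(sv$inserted_seq %||% "")
  if (is.na(ins)) ins <- ""
  list(sv_id = sv$sv_id,
       sequence = toupper(paste0(side_a, ins, side_b)),
       center = as.integer(L + nchar(ins)),
       flank_len = as.integer(L))
}

#' Build junction references for a whole panel
#'
#' @param calls data.frame of retained SV calls.
#' @inheritParams build_junction_reference
#' @return list of junction references (see [build_junction_reference()]).
#' @export
build_junction_panel <- function(calls, genome, flank_len = 150) {
  genome <- as_genome(genome)
  lapply(seq_len(nrow(calls)), function(i)
    build_junction_reference(calls[i, ], genome, flank_len))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- stats::setNames(as.character(genome), nm)
  }
  if (is.null(names(genome))) stop("genome contigs must be named", call. = FALSE)
  genome
}

#' Write junction references to multi-FASTA
#'
#' Record id is the `sv_id`; the header carries the junction point as
#' `center=<int>` (0-based index of the first side-B base).
#'
#' @param junctions list of junction references.
#' @param path output FASTA path.
#' @export
write_junction_fasta <- function(junctions, path) {
  seqs <- Biostrings::DNAStringSet(vapply(junctions, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(junctions, function(j)
    sprintf("%s center=%d", j$sv_id, j$center), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read junction references from multi-FASTA with `center=` header tags
#'
#' @param path FASTA path written by [write_junction_fasta()].
#' @return list of junction references.
#' @export
read_junction_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    hdr <- names(seqs)[i]
    m <- regmatches(hdr, regexec("^(\\S+).*center=([0-9]+)", hdr))[[1]]
    if (length(m) == 0L) stop("junction FASTA header lacks center= tag: ", hdr,
                              call. = FALSE)
    list(sv_id = m[2], sequence = as.character(seqs[[i]]),
         center = as.integer(m[3]),
         flank_len = NA_integer_)
  })
}
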