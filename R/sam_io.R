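#' Read an alignment file (SAM or BAM) into a data.frame
#'
#' SAM text is converted with [Rsamtools::asBam()] before scanning, so both
#' formats take the same path. The UMI is taken from the `RX` tag when
#' present.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns `name`, `flag`, `ref_name`, `pos`,
#'   `mapq`, `cigar`, `seq`, `umi`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "RX")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  umi <- x$tag$RX
  if (is.null(umi)) umi <- rep("", length(x$qname))
  umi[is.na(umi)] <- ""
  data.frame(name = x$qname, flag = x$flag,
             ref_name = as.character(x$rname), pos = x$pos, mapq = x$mapq,
             cigar = x$cigar, seq = as.character(x$seq), umi = umi,
             stringsAsFactors = FALSE)
}

#' Write alignments to a SAM text file
#'
#' Minimal mandatory fields plus an `RX` UMI tag when `umi` is non-empty.
#' Mates, qualities and optional fields beyond the UMI are not modelled.
#'
#' @param aln data.frame as returned by [read_alignments()].
#' @param refs named integer vector of reference lengths for the `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(aln, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(refs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(refs[[nm]])), con)
  if (nrow(aln)) {
    tags <- ifelse(nzchar(aln$umi), paste0("\tRX:Z:", aln$umi), "")
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                     aln$name, aln$flag, aln$ref_name, aln$pos, aln$mapq,
                     aln$cigar, aln$seq, tags)
    writeLines(lines, con)
  }
  invisible(path)
}

## parse a CIGAR string into a two-column matrix (op, length)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar))
    return(NULL)
  data.frame(op = substr(ops, nchar(ops), nchar(ops)),
             len = as.integer(substr(ops, 1L, nchar(ops) - 1L)),
             stringsAsFactors = FALSE)
}
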