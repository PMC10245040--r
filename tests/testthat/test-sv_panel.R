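make_sv_row <- function(sv_id = "R001", chrom_a = "chr1", pos_a = 1000L,
                        orient_a = "+", chrom_b = "chr2", pos_b = 2000L,
                        orient_b = "+", somatic_score = 50L,
                        inserted_seq = "", sample_id = "P1",
                        truth = NULL) {
  df <- data.frame(sv_id = sv_id, chrom_a = chrom_a, pos_a = pos_a,
                   orient_a = orient_a, chrom_b = chrom_b, pos_b = pos_b,
                   orient_b = orient_b, somatic_score = somatic_score,
                   inserted_seq = inserted_seq, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  df$span <- ifelse(df$chrom_a == df$chrom_b, abs(df$pos_b - df$pos_a),
                    NA_integer_)
  df
}

write_sv_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df[, setdiff(names(df), "span")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

test_that("TSV parsing canonicalizes breakpoint order and flips orientations", {
  df <- rbind(
    make_sv_row("A", "chr2", 500000L, "+", "chr2", 100000L, "-"),
    make_sv_row("B", "chr5", 100L, "-", "chr1", 200L, "+"))
  calls <- parse_sv_calls(write_sv_tsv(df))
  a <- calls[calls$sv_id == "A", ]
  expect_equal(a$pos_a, 100000L)
  expect_equal(a$pos_b, 500000L)
  # swap flips both orientations: (+,-) becomes (+,-) reversed -> ('+','-')
  expect_equal(c(a$orient_a, a$orient_b), c("+", "-"))
  expect_equal(a$span, 400000L)
  b <- calls[calls$sv_id == "B", ]
  expect_equal(c(b$chrom_a, b$chrom_b), c("chr1", "chr5"))
  # swapping sides flips both orientations: (-,+) -> (flip +, flip -)
  expect_equal(c(b$orient_a, b$orient_b), c("-", "+"))
  expect_true(is.na(b$span))
})

test_that("TSV parsing reports malformed coordinates and duplicates", {
  df <- make_sv_row(pos_a = -5L)
  expect_error(parse_sv_calls(write_sv_tsv(df)), "line")
  dup <- rbind(make_sv_row("X"), make_sv_row("X", pos_a = 5000L))
  expect_error(parse_sv_calls(write_sv_tsv(dup)), "duplicate")
})

vcf_header <- c(
  "##fileformat=VCFv4.1",
  '##INFO=<ID=MATEID,Number=.,Type=String,Description="mate">',
  '##INFO=<ID=SOMATICSCORE,Number=1,Type=Integer,Description="score">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

test_that("mated BND records collapse to one inter-chromosomal call", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
    "1\t1000\tbnd_u\tA\tA[5:2000[\t.\tPASS\tMATEID=bnd_v;SOMATICSCORE=45",
    "5\t2000\tbnd_v\tG\t]1:1000]G\t.\tPASS\tMATEID=bnd_u;SOMATICSCORE=45"),
    path)
  calls <- parse_sv_calls(path, sample_id = "P7")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$chrom_a, "1")
  expect_equal(calls$chrom_b, "5")
  expect_equal(calls$pos_a, 1000L)
  expect_equal(calls$pos_b, 2000L)
  expect_equal(c(calls$orient_a, calls$orient_b), c("+", "+"))
  expect_equal(calls$somatic_score, 45L)
  expect_equal(calls$sample_id, "P7")
})

test_that("BND bracket orientations and insertions map to junction strands", {
  path <- tempfile(fileext = ".vcf")
  # t]p] keeps the left side and the reverse complement of the mate's left
  writeLines(c(vcf_header,
    "1\t1000\tbnd_u\tA\tATT]5:2000]\t.\tPASS\tMATEID=bnd_v;SOMATICSCORE=40",
    "5\t2000\tbnd_v\tG\tGAA]1:1000]\t.\tPASS\tMATEID=bnd_u;SOMATICSCORE=40"),
    path)
  calls <- parse_sv_calls(path)
  expect_equal(c(calls$orient_a, calls$orient_b), c("+", "-"))
  expect_equal(calls$inserted_seq, "TT")
})

test_that("a BND record with a missing mate is a parse error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
    "1\t1000\tbnd_u\tA\tA[5:2000[\t.\tPASS\tMATEID=bnd_v;SOMATICSCORE=45"),
    path)
  expect_error(parse_sv_calls(path), "unpaired.*bnd_u")
})

test_that("find_cn_steps returns one step per adjacent unequal-CN boundary", {
  seg <- function(...) data.frame(..., stringsAsFactors = FALSE)
  s1 <- seg(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
            copy_number = c(2, 4))
  expect_equal(find_cn_steps(s1),
               data.frame(chrom = "chr1", position = 1000))
  s2 <- seg(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
            copy_number = c(2, 2))
  expect_equal(nrow(find_cn_steps(s2)), 0L)
  s3 <- seg(chrom = "chr1", start = c(0, 1000, 5000),
            end = c(1000, 5000, 9000), copy_number = c(2, 3, 2))
  expect_equal(find_cn_steps(s3)$position, c(1000, 5000))
  # permutation invariance
  expect_equal(find_cn_steps(s3[c(3, 1, 2), ]), find_cn_steps(s3))
  overlapping <- seg(chrom = "chr1", start = c(0, 500), end = c(1000, 2000),
                     copy_number = c(2, 3))
  expect_error(find_cn_steps(overlapping), "overlapping")
})

test_that("recurrent breakpoint clustering applies both rules across samples", {
  # rule (ii): inter-chromosomal, different samples, 150 bp apart
  ii <- rbind(make_sv_row("a", sample_id = "P1", pos_a = 10000L),
              make_sv_row("b", sample_id = "P2", pos_a = 10150L))
  bl <- cluster_recurrent_breakpoints(ii)
  expect_true(all(c(10000L, 10150L) %in% bl$position))
  # rule (i): 250 kb spans, 1,500 bp apart
  i1 <- rbind(
    make_sv_row("a", "chr3", 100000L, "+", "chr3", 350000L, "+", sample_id = "P1"),
    make_sv_row("b", "chr3", 101500L, "+", "chr3", 351500L, "+", sample_id = "P2"))
  bl <- cluster_recurrent_breakpoints(i1)
  expect_true(all(c(100000L, 101500L) %in% bl$position))
  # rule (i) does not fire within 2 kb for small spans, nor rule (ii) at 1500bp
  small <- rbind(
    make_sv_row("a", "chr3", 100000L, "+", "chr3", 150000L, "+", sample_id = "P1"),
    make_sv_row("b", "chr3", 101500L, "+", "chr3", 151500L, "+", sample_id = "P2"))
  expect_equal(nrow(cluster_recurrent_breakpoints(small)), 0L)
  # same sample never blacklists
  same <- rbind(make_sv_row("a", sample_id = "P1", pos_a = 10000L),
                make_sv_row("b", sample_id = "P1", pos_a = 10100L))
  expect_equal(nrow(suppressWarnings(cluster_recurrent_breakpoints(same))), 0L)
  expect_warning(cluster_recurrent_breakpoints(make_sv_row()), "single sample")
})

test_that("high-confidence filter applies every rule and records reasons", {
  steps <- data.frame(chrom = c("chr1", "chr2"), position = c(1000L, 5000L))
  calls <- rbind(
    make_sv_row("low", somatic_score = 30L, pos_a = 2000L, pos_b = 4000L),
    make_sv_row("intra_ok", "chr1", 4000L, "+", "chr1", 254000L, "+"),
    make_sv_row("far_step", "chr1", 16000L, "+", "chr2", 27000L, "+"),
    make_sv_row("short", "chr1", 2000L, "+", "chr1", 101000L, "+"))
  rep <- filter_high_confidence(calls, steps)
  expect_setequal(rep$sv_id, calls$sv_id)
  get <- function(id) rep[rep$sv_id == id, ]
  expect_equal(get("low")$decision, "rejected")
  expect_match(get("low")$reject_reasons, "low_score")
  expect_equal(get("intra_ok")$decision, "retained")
  expect_equal(get("far_step")$reject_reasons, "no_cn_step")
  expect_match(get("short")$reject_reasons, "short_intra_span")
  # score exactly at the threshold is retained
  at <- filter_high_confidence(make_sv_row(somatic_score = 31L, pos_a = 1200L),
                               steps)
  expect_equal(at$decision, "retained")
})

test_that("filter handles masks, blacklist and non-primary chromosomes", {
  steps <- data.frame(chrom = c("chr1", "chr2", "chrM"),
                      position = c(1000L, 2000L, 500L))
  mask <- data.frame(chrom = "chr1", start = 1050L, end = 1300L,
                     kind = "simple_repeat")
  calls <- rbind(
    make_sv_row("in_rep", pos_a = 1100L, pos_b = 2000L),
    make_sv_row("near_gap", pos_a = 1400L, pos_b = 2000L),
    make_sv_row("mito", "chrM", 500L, "+", "chr2", 2000L, "+"),
    make_sv_row("black", pos_a = 900L, pos_b = 2000L))
  bl <- data.frame(chrom = "chr1", position = 900L)
  rep <- filter_high_confidence(calls, steps, mask = mask, blacklist = bl)
  get <- function(id) rep[rep$sv_id == id, ]
  expect_match(get("in_rep")$reject_reasons, "repeat_or_gap_adjacent")
  # repeat of 250 bp > 100 bp counts; 1400 is outside it and not near a gap
  expect_equal(get("near_gap")$decision, "retained")
  expect_match(get("mito")$reject_reasons, "non_primary_chrom")
  expect_match(get("black")$reject_reasons, "recurrent_breakpoint")
  gap <- data.frame(chrom = "chr1", start = 1450L, end = 1600L, kind = "gap")
  rep2 <- filter_high_confidence(calls[2, ], steps, mask = gap)
  expect_match(rep2$reject_reasons, "repeat_or_gap_adjacent")  # within 100 bp
})

test_that("filter is monotone in its thresholds and conserves inputs", {
  set.seed(42)
  steps <- data.frame(chrom = "chr1", position = seq(50000L, 450000L, 50000L))
  calls <- do.call(rbind, lapply(1:30, function(i)
    make_sv_row(sprintf("S%02d", i), "chr1", sample(1000:480000, 1), "+",
                sample(c("chr1", "chr2"), 1), sample(1000:480000, 1),
                "+", somatic_score = sample(10:80, 1))))
  calls <- svjunction:::canonicalize_sv_calls(calls)
  strict <- filter_high_confidence(calls, steps, min_score = 40,
                                   min_span = 2e5, cn_step_window = 5e3)
  loose <- filter_high_confidence(calls, steps, min_score = 20,
                                  min_span = 5e4, cn_step_window = 2e4)
  expect_equal(nrow(strict), nrow(calls))
  kept_strict <- strict$sv_id[strict$decision == "retained"]
  kept_loose <- loose$sv_id[loose$decision == "retained"]
  expect_true(all(kept_strict %in% kept_loose))
  expect_equal(sum(strict$decision == "retained") +
                 sum(strict$decision == "rejected"), nrow(calls))
})

test_that("junction references honor flanks, insertions and orientations", {
  set.seed(7)
  contig <- random_seq(1000)
  genome <- c(chrX = contig)
  sv <- make_sv_row("J1", "chrX", 300L, "+", "chrX", 700L, "+")
  j <- build_junction_reference(sv, genome, flank_len = 150)
  expect_equal(nchar(j$sequence), 300L)
  expect_equal(j$center, 150L)
  expect_equal(j$sequence,
               paste0(substr(contig, 151, 300), substr(contig, 700, 849)))
  # insertion shifts the center
  svi <- make_sv_row("J2", "chrX", 300L, "+", "chrX", 700L, "+",
                     inserted_seq = "ACGTT")
  ji <- build_junction_reference(svi, genome, flank_len = 150)
  expect_equal(nchar(ji$sequence), 305L)
  expect_equal(ji$center, 155L)
  expect_equal(substr(ji$sequence, 151, 155), "ACGTT")
  # inversion-type: side B flank is the reverse complement of the 150-mer
  svv <- make_sv_row("J3", "chrX", 300L, "+", "chrX", 700L, "-")
  jv <- build_junction_reference(svv, genome, flank_len = 150)
  expect_equal(substring(jv$sequence, 151),
               revcomp(substr(contig, 551, 700)))
  # too close to the contig end
  sve <- make_sv_row("J4", "chrX", 100L, "+", "chrX", 700L, "+")
  expect_error(build_junction_reference(sve, genome), "flank")
  expect_error(build_junction_reference(sv, c(other = contig)), "lacks contig")
})

test_that("junction FASTA round-trips sequences and center tags", {
  set.seed(1)
  genome <- c(c1 = random_seq(800))
  calls <- rbind(make_sv_row("A", "c1", 200L, "+", "c1", 600L, "+"),
                 make_sv_row("B", "c1", 250L, "-", "c1", 550L, "-",
                             inserted_seq = "GG"))
  jx <- build_junction_panel(calls, genome, flank_len = 100)
  path <- tempfile(fileext = ".fa")
  write_junction_fasta(jx, path)
  back <- read_junction_fasta(path)
  expect_equal(vapply(back, `[[`, character(1), "sv_id"), c("A", "B"))
  expect_equal(back[[2]]$sequence, jx[[2]]$sequence)
  expect_equal(back[[2]]$center, jx[[2]]$center)
})
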