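toy_junction <- local({
  set.seed(17)
  list(sv_id = "SVX", sequence = random_seq(400), center = 200L,
       flank_len = 200L)
})

aln_row <- function(name = "r1", cigar = "140M10S", seq = NULL,
                    ref_name = "chr1", pos = 100L, flag = 0L, umi = "") {
  if (is.null(seq)) {
    consumed <- sum(as.integer(
      regmatches(cigar, gregexpr("[0-9]+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
    seq <- strrep("A", consumed)
  }
  data.frame(name = name, flag = flag, ref_name = ref_name, pos = pos,
             mapq = 60L, cigar = cigar, seq = seq, umi = umi,
             stringsAsFactors = FALSE)
}

test_that("soft-clip candidate extraction applies the 10-base boundary", {
  aln <- rbind(aln_row("a", "140M10S"), aln_row("b", "9S141M"),
               aln_row("c", "150M"), aln_row("d", "15H135M"),
               aln_row("e", "140M10S", flag = 4L))
  cand <- extract_softclip_candidates(aln)
  expect_setequal(cand$name, c("a", "d"))   # unmapped "e" excluded
  bad <- rbind(aln_row("a", "140M10S"), aln_row("z", "MM10"))
  expect_warning(cand2 <- extract_softclip_candidates(bad), "malformed")
  expect_equal(cand2$name, "a")
  expect_equal(attr(cand2, "n_skipped"), 1L)
})

test_that("junction read matching enforces the 2.5% edit budget exactly", {
  j <- toy_junction
  window <- substr(j$sequence, 126, 275)   # 150 bp spanning the center
  expect_equal(match_junction_read(window, j)$edit_distance, 0L)
  # 3 scattered substitutions: 3 <= floor(0.025 * 150) = 3
  mut3 <- plant_subs(window, 3, 30, 45)
  expect_equal(lev_dp(window, mut3), 3L)
  expect_equal(match_junction_read(mut3, j)$edit_distance, 3L)
  # 4 substitutions exceed the budget
  mut4 <- plant_subs(window, 4, 30, 48)
  expect_equal(lev_dp(window, mut4), 4L)
  expect_null(match_junction_read(mut4, j))
})

test_that("both 20 bp flanks are required, in junction order", {
  j <- toy_junction
  window <- substr(j$sequence, 126, 275)
  # destroy the right flank (junction positions 201..220 = window 76..95)
  set.seed(18)
  broken <- paste0(substr(window, 1, 75), random_seq(20),
                   substring(window, 96))
  expect_null(match_junction_read(broken, j))
  # a read entirely on side A (never crosses the junction) has no right flank
  left_only <- substr(j$sequence, 1, 150)
  expect_null(match_junction_read(left_only, j))
  # up to 2 edits per flank are tolerated
  flanked <- window
  substr(flanked, 60, 60) <- if (substr(flanked, 60, 60) == "A") "C" else "A"
  substr(flanked, 80, 80) <- if (substr(flanked, 80, 80) == "A") "C" else "A"
  expect_false(is.null(match_junction_read(flanked, j)))
  shortj <- list(sv_id = "s", sequence = random_seq(30), center = 15L)
  expect_error(match_junction_read(window, shortj), "flank")
})

test_that("reverse-complement reads and UMI prefixes are handled", {
  j <- toy_junction
  window <- substr(j$sequence, 126, 275)
  hit <- match_junction_read(revcomp(window), j)
  expect_equal(hit$strand, "-")
  expect_equal(hit$edit_distance, 0L)
  set.seed(19)
  umi_read <- paste0(random_seq(10), window)
  expect_false(is.null(match_junction_read(umi_read, j, umi_len = 10)))
})

test_that("capture counting demands a perfect +/-20 bp breakpoint window", {
  j <- toy_junction
  # read spanning center +/- 25 (junction 0-based 175..225 -> 1-based 176..225)
  seq <- substr(j$sequence, 151, 250)
  aln <- aln_row("ok", "100M", seq = seq, ref_name = "SVX", pos = 151L)
  counts <- count_capture_reads(aln, list(j))
  expect_equal(counts$read_count[counts$sv_id == "SVX"], 1L)
  # one mismatch at center+5 (0-based 205 -> string offset 55 in seq)
  bad <- seq
  substr(bad, 56, 56) <- if (substr(bad, 56, 56) == "A") "C" else "A"
  aln2 <- aln_row("mm", "100M", seq = bad, ref_name = "SVX", pos = 151L)
  expect_equal(count_capture_reads(aln2, list(j))$read_count[1], 0L)
  # mismatches outside the window do not matter
  out <- seq
  substr(out, 5, 5) <- if (substr(out, 5, 5) == "A") "C" else "A"
  aln3 <- aln_row("out", "100M", seq = out, ref_name = "SVX", pos = 151L)
  expect_equal(count_capture_reads(aln3, list(j))$read_count[1], 1L)
  # window only partially covered
  part <- aln_row("part", "60M", seq = substr(j$sequence, 202, 261),
                  ref_name = "SVX", pos = 202L)
  expect_equal(count_capture_reads(part, list(j))$read_count[1], 0L)
  # a deletion crossing the window breaks the 100% match
  del <- aln_row("del", "50M2D48M",
                 seq = paste0(substr(j$sequence, 151, 200),
                              substr(j$sequence, 203, 250)),
                 ref_name = "SVX", pos = 151L)
  expect_equal(count_capture_reads(del, list(j))$read_count[1], 0L)
  expect_warning(count_capture_reads(aln_row("x", ref_name = "nope"),
                                     list(j)), "unknown")
})

test_that("UMI deduplication counts distinct molecules and is idempotent", {
  hit <- function(name, umi, start, sv = "SVX")
    data.frame(sv_id = sv, name = name, umi = umi, align_start = start,
               edit_distance = 0L, mode = "softclip_match",
               stringsAsFactors = FALSE)
  five <- do.call(rbind, lapply(1:5, function(i)
    hit(paste0("r", i), "AACCGGTT", 100L)))
  d <- dedup_by_umi(five)
  expect_equal(d$read_count, 5L)
  expect_equal(d$molecule_count, 1L)
  two_starts <- rbind(hit("r1", "AACCGGTT", 100L), hit("r2", "AACCGGTT", 250L))
  expect_equal(dedup_by_umi(two_starts)$molecule_count, 2L)
  mix <- do.call(rbind, lapply(1:3, function(m) rbind(
    hit(paste0("m", m, "a"), strrep(c("A", "C", "G")[m], 8), 100L * m),
    hit(paste0("m", m, "b"), strrep(c("A", "C", "G")[m], 8), 100L * m))))
  dm <- dedup_by_umi(mix)
  expect_equal(dm$molecule_count, 3L)
  expect_equal(dm$read_count, 6L)
  # empty UMI falls back to read name; dedup never increases counts
  noumi <- rbind(hit("r1", "", 1L), hit("r1", "", 1L), hit("r2", "", 9L))
  dn <- dedup_by_umi(noumi)
  expect_equal(dn$molecule_count, 2L)
  expect_true(all(dn$molecule_count <= dn$read_count))
})

test_that("wgs_af follows reads / (2 x depth x SVs)", {
  expect_equal(wgs_af(0, 20, 153), 0)
  expect_equal(wgs_af(1, 20, 153), 1 / (2 * 20 * 153))
  expect_equal(wgs_af(1, 20, 153), 1.634e-4, tolerance = 1e-3)
  expect_equal(wgs_af(10, 399, 30), 10 / (2 * 399 * 30))
  expect_equal(wgs_af(10, 399, 30), 4.177e-4, tolerance = 1e-3)
  # linear in reads, inverse in depth and panel size
  expect_equal(wgs_af(6, 30, 10), 3 * wgs_af(2, 30, 10))
  expect_equal(wgs_af(2, 60, 10), wgs_af(2, 30, 10) / 2)
  expect_error(wgs_af(-1, 20, 10), "non-negative")
  expect_error(wgs_af(1, 0, 10), "positive")
})

test_that("SAM round trip preserves records and UMI tags", {
  aln <- rbind(aln_row("a", "140M10S", seq = random_seq(150), pos = 5L,
                       umi = "ACGTACGTAC"),
               aln_row("b", "150M", seq = random_seq(150), pos = 50L))
  path <- tempfile(fileext = ".sam")
  write_sam(aln, c(chr1 = 1000L), path)
  back <- read_alignments(path)
  back <- back[order(back$name), ]
  expect_equal(back$name, c("a", "b"))
  expect_equal(back$cigar, aln$cigar)
  expect_equal(back$seq, aln$seq)
  expect_equal(back$umi, aln$umi)
  expect_equal(back$pos, aln$pos)
})

test_that("planted WGS junction molecules are recovered exactly at zero error", {
  g <- make_genome_with_svs(n_contigs = 2, contig_len = 3e5, n_svs = 3,
                            seed = 5)
  sim <- simulate_wgs_alignments(g, n_molecules = 4, reads_per_molecule = 2,
                                 per_base_error = 0, background_depth = 0.05,
                                 seed = 6)
  cand <- extract_softclip_candidates(sim$aln)
  # candidates are exactly the junction-derived reads
  expect_setequal(cand$name, sim$truth$name[sim$truth$sv_id != "wild_type"])
  hits <- scan_junction_hits(cand, g$junctions, umi_len = 0)
  counts <- dedup_by_umi(hits)
  expect_equal(sort(unique(hits$sv_id)), sort(names(g$junctions)))
  expect_equal(sum(counts$molecule_count), 3L * 4L)
  expect_equal(sum(counts$read_count), sum(sim$truth$sv_id != "wild_type"))
  # per-read agreement with truth
  expect_setequal(hits$name, sim$truth$name[sim$truth$expected_hit])
})

test_that("errored WGS reads are recovered iff within the edit budget", {
  g <- make_genome_with_svs(n_contigs = 2, contig_len = 3e5, n_svs = 2,
                            seed = 8)
  sim <- simulate_wgs_alignments(g, n_molecules = 8, reads_per_molecule = 1,
                                 per_base_error = 0.015,
                                 background_depth = 0, seed = 9)
  cand <- extract_softclip_candidates(sim$aln)
  hits <- scan_junction_hits(cand, g$junctions, umi_len = 0)
  expect_setequal(hits$name, sim$truth$name[sim$truth$expected_hit])
  expect_true(any(!sim$truth$expected_hit))  # the seed exercises both sides
})

test_that("no junction hits arise from wild-type reads (specificity)", {
  g <- make_genome_with_svs(n_contigs = 2, contig_len = 3e5, n_svs = 2,
                            seed = 12)
  sim <- simulate_wgs_alignments(g, n_molecules = 0, reads_per_molecule = 1,
                                 per_base_error = 0.01,
                                 background_depth = 0.2, seed = 13)
  wt <- sim$aln
  expect_true(nrow(wt) > 50)
  hits <- scan_junction_hits(wt, g$junctions, umi_len = 0)
  expect_equal(nrow(hits), 0L)
})
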