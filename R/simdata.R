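#' Simulate a toy genome with planted structural variants
#'
#' Builds a random reference genome, plants SVs by cut-and-paste (one
#' derived tumor contig per SV, covering all four orientation combinations
#' in rotation), and emits the matching SV call set, a copy-number
#' segmentation with steps at the breakpoints, and a ground-truth junction
#' sequence per SV taken from the derived contig. Junction-crossing 25-mers
#' are verified absent from the unmodified reference, so any junction match
#' in reference-derived reads is a false positive by construction.
#'
#' When `with_decoys` is set, extra calls are appended that must be
#' rejected by the high-confidence filter: a low-score call, a short
#' intra-chromosomal call, a call far from any copy-number step, and a
#' recurrent pair shared with a second dummy sample.
#'
#' @param n_contigs number of reference contigs (default 2).
#' @param contig_len contig length in bp (default 500000).
#' @param n_svs number of SVs to plant (default 3).
#' @param flank_len junction flank length used for the truth sequences.
#' @param gc reference GC content (default 0.41, human-like).
#' @param sample_id sample label on the emitted calls.
#' @param with_decoys also emit filter-testing decoy calls.
#' @param seed RNG seed.
#' @return list: `reference`, `tumor` (named sequence vectors), `calls`
#'   (SV call data.frame with a `truth` column `planted`/`decoy`),
#'   `cn_segments`, `junctions` (planted junction truth, one per SV).
#' @export
make_genome_with_svs <- function(n_contigs = 2, contig_len = 5e5, n_svs = 3,
                                 flank_len = 150, gc = 0.41,
                                 sample_id = "sim", with_decoys = FALSE,
                                 seed = 1) {
  if (contig_len < 4 * flank_len + 2e5)
    stop("contig_len too small for planted SV geometry", call. = FALSE)
  with_seed(seed, {
    reference <- stats::setNames(
      vapply(seq_len(n_contigs), function(i) random_dna(contig_len, gc),
             character(1)),
      paste0("chr", seq_len(n_contigs)))
    orient_cycle <- list(c("+", "+"), c("+", "-"), c("-", "+"), c("-", "-"))
    margin <- 2L * flank_len + 1000L
    calls <- list(); tumor <- character(0); junctions <- list()
    ## every junction-crossing 25-mer must be absent from the reference (a
    ## one-base overhang can coincide with the reference continuation, so
    ## breakpoints are resampled until the check passes)
    kmer_free <- function(jseq, center) {
      k <- 25L
      for (s in seq(max(1L, center - k + 2L),
                    min(center, nchar(jseq) - k + 1L))) {
        kmer <- substr(jseq, s, s + k - 1L)
        hit <- vapply(reference, function(r)
          grepl(kmer, r, fixed = TRUE) ||
            grepl(revcomp(kmer), r, fixed = TRUE), logical(1))
        if (any(hit)) return(FALSE)
      }
      TRUE
    }
    for (i in seq_len(n_svs)) {
      oo <- orient_cycle[[(i - 1L) %% 4L + 1L]]
      for (attempt in 1:25) {
        if (n_contigs >= 2L && i %% 2L == 1L) {      # translocation
          ca <- names(reference)[1L]; cb <- names(reference)[2L]
          pos_a <- sample(margin:(contig_len %/% 2), 1L)
          pos_b <- sample(margin:(contig_len - margin), 1L)
        } else {                                     # large intra (del/inv)
          ca <- cb <- names(reference)[(i - 1L) %% n_contigs + 1L]
          span_max <- contig_len - margin - (contig_len %/% 3)
          if (span_max < 150000L)
            stop("infeasible geometry: contig too short for the requested ",
                 "intra-chromosomal span", call. = FALSE)
          pos_a <- sample(margin:(contig_len %/% 3), 1L)
          pos_b <- pos_a + sample(150000:min(250000L, span_max), 1L)
        }
        ins <- if (i %% 3L == 0L) random_dna(5L) else ""
        left <- if (oo[1] == "+") substr(reference[[ca]], 1L, pos_a)
                else revcomp(substring(reference[[ca]], pos_a))
        right <- if (oo[2] == "+") substring(reference[[cb]], pos_b)
                 else revcomp(substr(reference[[cb]], 1L, pos_b))
        derived <- paste0(left, ins, right)
        jstart <- nchar(left) - flank_len + 1L
        jseq <- substr(derived, jstart, nchar(left) + nchar(ins) + flank_len)
        if (kmer_free(jseq, flank_len + nchar(ins))) break
        if (attempt == 25L)
          stop("could not place a reference-free junction; ",
               "rerun with another seed", call. = FALSE)
      }
      sv_id <- sprintf("SV%03d", i)
      tumor[[paste0("tumor_", sv_id)]] <- derived
      junctions[[sv_id]] <- list(sv_id = sv_id, sequence = jseq,
                                 center = flank_len + nchar(ins),
                                 flank_len = flank_len)
      calls[[sv_id]] <- data.frame(
        sv_id = sv_id, chrom_a = ca, pos_a = pos_a, orient_a = oo[1],
        chrom_b = cb, pos_b = pos_b, orient_b = oo[2],
        somatic_score = sample(40:99, 1L), inserted_seq = ins,
        sample_id = sample_id, truth = "planted", stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, calls)
    ## CN segmentation: a copy-number step at each breakpoint
    brk <- unique(rbind(data.frame(chrom = calls$chrom_a, pos = calls$pos_a),
                        data.frame(chrom = calls$chrom_b, pos = calls$pos_b)))
    cn <- do.call(rbind, lapply(names(reference), function(chr) {
      p <- sort(unique(c(0L, brk$pos[brk$chrom == chr], contig_len)))
      if (length(p) < 2L) return(NULL)
      data.frame(chrom = chr, start = p[-length(p)], end = p[-1L],
                 copy_number = 2L + (seq_len(length(p) - 1L) %% 2L),
                 stringsAsFactors = FALSE)
    }))
    if (with_decoys) {
      far <- contig_len - margin           # far from every CN step (w.h.p.)
      decoys <- data.frame(
        sv_id = c("DLOW", "DSHORT", "DNOSTEP", "DREC1", "DREC2"),
        chrom_a = names(reference)[1L],
        pos_a = c(calls$pos_a[1L], margin + 11L, far - 150000L,
                  260000L, 260100L),
        orient_a = "+",
        chrom_b = c(calls$chrom_b[1L], names(reference)[1L],
                    names(reference)[1L], names(reference)[1L],
                    names(reference)[1L]),
        pos_b = c(calls$pos_b[1L] + 40L, margin + 50011L, far,
                  380000L, 380100L),
        orient_b = "+",
        somatic_score = c(20L, 80L, 80L, 80L, 80L),
        inserted_seq = "",
        sample_id = c(sample_id, sample_id, sample_id, sample_id, "other"),
        truth = "decoy", stringsAsFactors = FALSE)
      calls <- rbind(calls, decoys)
    }
    rownames(calls) <- NULL
    list(reference = reference, tumor = tumor,
         calls = canonicalize_sv_calls(calls), cn_segments = cn,
         junctions = junctions)
  })
}

#' Derive a multiplex-PCR primer panel from junction references
#'
#' For each junction an amplicon spanning the breakpoint is chosen with a
#' total length drawn from `amp_len_range` (genome footprint sized for
#' fragmented cell-free DNA); the forward primer is its first
#' `primer_len` bases and the reverse primer the reverse complement of its
#' last `primer_len` bases, as synthesized. A synthetic housekeeper control
#' amplicon (`RPP30_97bp`, 97 bp, not derived from any junction) is
#' appended as the internal positive control.
#'
#' @param junctions list of junction references.
#' @param primer_len primer length (default 20).
#' @param amp_len_range inclusive amplicon length range (default 82-144 bp).
#' @param seed RNG seed.
#' @return panel data.frame: `amplicon_id`, `sv_id`, `fwd_seq`, `rev_seq`,
#'   `expected_amplicon`, `is_control`.
#' @export
make_primer_panel <- function(junctions, primer_len = 20,
                              amp_len_range = c(82, 144), seed = 1) {
  with_seed(seed, {
    rows <- lapply(junctions, function(j) {
      amp_len <- sample(amp_len_range[1]:amp_len_range[2], 1L)
      left <- sample(primer_len:(amp_len - primer_len - 5L), 1L)
      start <- j$center - left + 1L
      stopifnot(start >= 1L, start + amp_len - 1L <= nchar(j$sequence))
      amp <- substr(j$sequence, start, start + amp_len - 1L)
      data.frame(amplicon_id = j$sv_id, sv_id = j$sv_id,
                 fwd_seq = substr(amp, 1L, primer_len),
                 rev_seq = revcomp(substr(amp, amp_len - primer_len + 1L,
                                          amp_len)),
                 expected_amplicon = amp, is_control = FALSE,
                 stringsAsFactors = FALSE)
    })
    ctrl_amp <- random_dna(97L)
    rows[[length(rows) + 1L]] <- data.frame(
      amplicon_id = "RPP30_97bp", sv_id = "RPP30_97bp",
      fwd_seq = substr(ctrl_amp, 1L, primer_len),
      rev_seq = revcomp(substr(ctrl_amp, 97L - primer_len + 1L, 97L)),
      expected_amplicon = ctrl_amp, is_control = TRUE,
      stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## one amplicon read pair with substitution errors and adapter fill
amplicon_read_pair <- function(amp, read_len, per_base_error) {
  n_err1 <- stats::rbinom(1L, nchar(amp), per_base_error)
  n_err2 <- stats::rbinom(1L, nchar(amp), per_base_error)
  m1 <- mutate_seq(amp, n_err1)
  m2 <- mutate_seq(revcomp(amp), n_err2)
  fill <- function(s) {
    if (nchar(s) >= read_len) return(substr(s, 1L, read_len))
    paste0(s, random_dna(read_len - nchar(s)))
  }
  list(seq1 = fill(m1$seq), seq2 = fill(m2$seq),
       err1 = m1$positions, err2 = m2$positions)
}

## expected classifier outcome for planted substitution errors (positions are
## 1-based within the amplicon in each read's own orientation)
expected_amp_status <- function(err1, err2, amp_len, primer_len = 20,
                                primer_max_edit = 2, amplicon_max_edit = 5) {
  gate <- function(err) {
    in_fwd <- sum(err <= primer_len)
    in_rev <- sum(err > amp_len - primer_len)
    if (in_fwd > primer_max_edit || in_rev > primer_max_edit) return("no_primer")
    if (length(err) > amplicon_max_edit) return("amplicon_mismatch")
    "pass"
  }
  g1 <- gate(err1); g2 <- gate(err2)
  if (g1 == "pass" && g2 == "pass") "matched"
  else if ("no_primer" %in% c(g1, g2)) "no_primer"
  else "amplicon_mismatch"
}

#' Simulate a digital multiplex-PCR run
#'
#' Mutant molecule counts per (SV, well) are drawn as
#' `Poisson(copies_per_well x af)` — the limiting-dilution regime in which
#' the assay is digital — and each molecule emits a geometric number of
#' amplicon read pairs (mean `reads_per_molecule`) with independent
#' per-base substitution errors. The housekeeper control amplicon is
#' amplified in every well. A truth record per read pair carries the planted
#' error positions and the classification the matcher is expected to
#' produce.
#'
#' @param panel panel data.frame from [make_primer_panel()].
#' @param af allele fraction of the sample.
#' @param wells number of wells the sample is divided into.
#' @param copies_per_well amplifiable copies loaded per well.
#' @param reads_per_molecule mean read pairs per molecule (default 20).
#' @param per_base_error substitution probability per base (default 0.001).
#' @param read_len read length (default 150).
#' @param control_pairs_per_well control amplicon read pairs per well.
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return list: `reads1`, `reads2` (named sequence vectors), `layout`,
#'   `copies`, `truth` (per-pair data.frame), `n_molecules` (per SV x well).
#' @export
simulate_amplicon_run <- function(panel, af, wells, copies_per_well,
                                  reads_per_molecule = 20,
                                  per_base_error = 0.001, read_len = 150,
                                  control_pairs_per_well = 50,
                                  sample_id = "S1", seed = 1) {
  with_seed(seed, {
    targets <- panel[!panel$is_control, , drop = FALSE]
    ctrl <- panel[panel$is_control, , drop = FALSE]
    reads1 <- character(0); reads2 <- character(0)
    truth <- list(); layout <- list(); nmol <- list()
    pair_n <- 0L
    emit <- function(amp_row, well, molecule) {
      rp <- amplicon_read_pair(amp_row$expected_amplicon, read_len,
                               per_base_error)
      pair_n <<- pair_n + 1L
      id <- sprintf("pair%06d", pair_n)
      reads1[[id]] <<- rp$seq1; reads2[[id]] <<- rp$seq2
      layout[[id]] <<- data.frame(pair_id = id, sample_id = sample_id,
                                  well_id = well, stringsAsFactors = FALSE)
      truth[[id]] <<- data.frame(
        pair_id = id, amplicon_id = amp_row$amplicon_id, well_id = well,
        molecule = molecule, n_err_r1 = length(rp$err1),
        n_err_r2 = length(rp$err2),
        expected_status = expected_amp_status(rp$err1, rp$err2,
                                              nchar(amp_row$expected_amplicon)),
        stringsAsFactors = FALSE)
    }
    for (w in seq_len(wells)) {
      well <- sprintf("W%02d", w)
      for (k in seq_len(nrow(targets))) {
        n_mol <- stats::rpois(1L, copies_per_well * af)
        nmol[[paste(well, targets$sv_id[k])]] <- data.frame(
          well_id = well, sv_id = targets$sv_id[k], n_molecules = n_mol,
          stringsAsFactors = FALSE)
        if (n_mol == 0L) next
        for (m in seq_len(n_mol)) {
          n_reads <- 1L + stats::rgeom(1L, 1 / reads_per_molecule)
          for (r in seq_len(n_reads))
            emit(targets[k, ], well, sprintf("%s:%s:m%d", well,
                                             targets$sv_id[k], m))
        }
      }
      if (nrow(ctrl))
        for (r in seq_len(control_pairs_per_well))
          emit(ctrl[1L, ], well, sprintf("%s:ctrl", well))
    }
    layout <- if (length(layout)) do.call(rbind, layout) else
      data.frame(pair_id = character(0), sample_id = character(0),
                 well_id = character(0))
    copies <- data.frame(sample_id = sample_id,
                         well_id = sprintf("W%02d", seq_len(wells)),
                         input_copies = copies_per_well,
                         stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(pair_id = character(0), amplicon_id = character(0),
                 well_id = character(0), molecule = character(0),
                 n_err_r1 = integer(0), n_err_r2 = integer(0),
                 expected_status = character(0))
    rownames(layout) <- rownames(truth) <- NULL
    list(reads1 = reads1, reads2 = reads2, layout = layout, copies = copies,
         truth = truth, n_molecules = do.call(rbind, nmol))
  })
}

#' The standard 7-level tumor dilution design
#'
#' Three wells of 10, 30 and 300 copies each at 10%, 1% and 0.1% AF, then
#' five wells of 900 copies (4,500 total) at 0.01%, 0.003%, 0.001% and
#' 0.0004% AF.
#'
#' @return data.frame: `expected_af`, `wells`, `copies_per_well`.
#' @export
dilution_design <- function() {
  data.frame(
    expected_af = c(0.1, 0.01, 0.001, 1e-4, 3e-5, 1e-5, 4e-6),
    wells = c(3L, 3L, 3L, 5L, 5L, 5L, 5L),
    copies_per_well = c(10, 30, 300, 900, 900, 900, 900))
}

#' Simulate a tumor dilution series at count level
#'
#' Per dilution level, each (SV, well) target turns positive when at least
#' one mutant molecule lands in the well (`Poisson(copies_per_well x af)`
#' draws). In `"expectation"` mode the stochastic draw is replaced by its
#' expectation `wells x n_svs x (1 - exp(-copies_per_well x af))`, giving a
#' noise-free table for estimator checks. Observed AFs are the
#' Poisson-corrected estimates.
#'
#' @param n_svs number of SVs targeted by the panel.
#' @param design design table (default [dilution_design()]).
#' @param mode `"stochastic"` or `"expectation"`.
#' @param seed RNG seed (stochastic mode).
#' @return data.frame of dilution points: design columns plus
#'   `positive_events` and `observed_af`.
#' @export
simulate_dilution_series <- function(n_svs, design = dilution_design(),
                                     mode = c("stochastic", "expectation"),
                                     seed = 1) {
  mode <- match.arg(mode)
  with_seed(if (mode == "stochastic") seed else NULL, {
    ev <- vapply(seq_len(nrow(design)), function(i) {
      lambda <- design$copies_per_well[i] * design$expected_af[i]
      n_targets <- design$wells[i] * n_svs
      if (mode == "expectation") n_targets * (1 - exp(-lambda))
      else sum(stats::rpois(n_targets, lambda) > 0L)
    }, numeric(1))
    out <- design
    out$positive_events <- ev
    out$observed_af <- vapply(seq_len(nrow(out)), function(i) {
      if (ev[i] <= 0) return(0)
      if (ev[i] >= out$wells[i] * n_svs) return(NA_real_)  # saturated
      af_poisson(ev[i], out$copies_per_well[i], out$wells[i], n_svs)
    }, numeric(1))
    out
  })
}

#' Simulate soft-clipped WGS alignments over a junction panel
#'
#' Plants `n_molecules` junction-spanning molecules per SV; each emits a
#' geometric number of PCR duplicate reads sharing one UMI and one start
#' offset, aligned to the side-A locus with the side-B portion soft-clipped.
#' Wild-type background reads from the reference are emitted at
#' `background_depth` (CIGAR fully matched, no junction content). Errors
#' are uniform substitutions. The truth table records, per read, the planted
#' molecule, UMI, error count and whether the read is expected to pass the
#' flank and edit-budget gates.
#'
#' @param genome_sim output of [make_genome_with_svs()].
#' @param n_molecules junction molecules per SV (default 5).
#' @param reads_per_molecule mean PCR duplicates per molecule (default 2).
#' @param background_depth mean coverage of wild-type reads (default 0.02;
#'   reads, not bases — keep tiny for test speed).
#' @param per_base_error substitution probability (default 0).
#' @param read_len read length (default 150).
#' @param min_clip minimum soft-clip each side of the junction (default 10).
#' @param umi_len UMI length (default 10).
#' @param flank_len,flank_max_edit,max_edit_frac gate parameters mirrored
#'   into the truth annotation.
#' @param seed RNG seed.
#' @return list: `aln` (alignment data.frame for [write_sam()]), `refs`
#'   (reference lengths), `truth` (per-read data.frame).
#' @export
simulate_wgs_alignments <- function(genome_sim, n_molecules = 5,
                                    reads_per_molecule = 2,
                                    background_depth = 0.02,
                                    per_base_error = 0, read_len = 150,
                                    min_clip = 10, umi_len = 10,
                                    flank_len = 20, flank_max_edit = 2,
                                    max_edit_frac = 0.025, seed = 1) {
  with_seed(seed, {
    junctions <- genome_sim$junctions
    calls <- genome_sim$calls
    reference <- genome_sim$reference
    aln <- list(); truth <- list(); n <- 0L
    budget <- floor(max_edit_frac * read_len)
    for (j in junctions) {
      sv <- calls[calls$sv_id == j$sv_id, ]
      jlen <- nchar(j$sequence)
      for (m in seq_len(n_molecules)) {
        ## keep both 20 bp flank probes fully inside the read, so an
        ## error-free read is always recoverable (clips still >= min_clip)
        pad <- max(min_clip, flank_len)
        start0 <- sample((j$center - read_len + pad):(j$center - pad), 1L)
        start0 <- max(0L, min(start0, jlen - read_len))
        clean <- substr(j$sequence, start0 + 1L, start0 + read_len)
        umi <- random_dna(umi_len)
        n_reads <- 1L + stats::rgeom(1L, 1 / reads_per_molecule)
        matched_len <- j$center - start0          # side-A bases in the read
        for (r in seq_len(n_reads)) {
          n_err <- stats::rbinom(1L, read_len, per_base_error)
          mut <- mutate_seq(clean, n_err)
          err <- mut$positions
          left_ok <- sum(err > j$center - flank_len - start0 &
                           err <= j$center - start0) <= flank_max_edit
          right_ok <- sum(err > j$center - start0 &
                            err <= j$center + flank_len - start0) <= flank_max_edit
          expected_hit <- n_err <= budget && left_ok && right_ok
          n <- n + 1L
          name <- sprintf("wgs%06d", n)
          aln[[n]] <- data.frame(
            name = name, flag = 0L, ref_name = sv$chrom_a,
            pos = sv$pos_a - matched_len + 1L, mapq = 60L,
            cigar = sprintf("%dM%dS", matched_len, read_len - matched_len),
            seq = mut$seq, umi = umi, stringsAsFactors = FALSE)
          truth[[n]] <- data.frame(
            name = name, sv_id = j$sv_id,
            molecule = sprintf("%s:m%d", j$sv_id, m), umi = umi,
            n_err = n_err, expected_hit = expected_hit,
            stringsAsFactors = FALSE)
        }
      }
    }
    ## wild-type background
    for (chr in names(reference)) {
      len <- nchar(reference[[chr]])
      n_bg <- stats::rpois(1L, background_depth * len / read_len)
      if (n_bg == 0L) next
      for (b in seq_len(n_bg)) {
        p <- sample(len - read_len, 1L)
        n <- n + 1L
        name <- sprintf("wgs%06d", n)
        mut <- mutate_seq(substr(reference[[chr]], p + 1L, p + read_len),
                          stats::rbinom(1L, read_len, per_base_error))
        aln[[n]] <- data.frame(
          name = name, flag = 0L, ref_name = chr, pos = p + 1L, mapq = 60L,
          cigar = sprintf("%dM", read_len), seq = mut$seq,
          umi = random_dna(umi_len), stringsAsFactors = FALSE)
        truth[[n]] <- data.frame(
          name = name, sv_id = "wild_type", molecule = NA_character_,
          umi = NA_character_, n_err = length(mut$positions),
          expected_hit = FALSE, stringsAsFactors = FALSE)
      }
    }
    list(aln = do.call(rbind, aln),
         refs = vapply(reference, nchar, integer(1)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a two-component cfDNA fragment-length mixture
#'
#' Tumor-derived and wild-type fragment lengths are drawn from discretized
#' normal distributions (defaults: tumor mode 145 bp, normal mode 166 bp —
#' the canonical mononucleosomal cfDNA profile with the shorter tumor
#' component), truncated below 50 bp by redrawing.
#'
#' @param n number of fragments.
#' @param tumor_fraction fraction of tumor-derived fragments.
#' @param tumor_mode,normal_mode mixture component modes in bp.
#' @param sd common standard deviation in bp (default 25).
#' @param seed RNG seed.
#' @return data.frame: `name`, `length`, `is_tumor`.
#' @export
simulate_fragment_sizes <- function(n, tumor_fraction, tumor_mode = 145,
                                    normal_mode = 166, sd = 25, seed = 1) {
  stopifnot(tumor_mode > 0, normal_mode > 0, sd > 0,
            tumor_fraction >= 0, tumor_fraction <= 1)
  with_seed(seed, {
    is_tumor <- stats::runif(n) < tumor_fraction
    mu <- ifelse(is_tumor, tumor_mode, normal_mode)
    len <- round(stats::rnorm(n, mu, sd))
    while (any(len < 50)) {
      i <- which(len < 50)
      len[i] <- round(stats::rnorm(length(i), mu[i], sd))
    }
    data.frame(name = sprintf("frag%06d", seq_len(n)), length = len,
               is_tumor = is_tumor, stringsAsFactors = FALSE)
  })
}

#' Simulate non-specific background counts in negative controls
#'
#' Each control target (an SV in a well, or an SV for read-count assays)
#' independently shows non-specific reads with probability `bg_rate`;
#' positive counts are small (1-5 reads, decreasing frequency), matching
#' the low-level index-hopping signal seen in real negative controls.
#'
#' @param n_targets targets per sample (e.g. SVs x wells).
#' @param n_samples number of control samples.
#' @param bg_rate per-target probability of any non-specific reads.
#' @param seed RNG seed.
#' @return integer matrix `n_targets` x `n_samples` of read counts.
#' @export
simulate_control_counts <- function(n_targets, n_samples, bg_rate = 0.02,
                                    seed = 1) {
  with_seed(seed, {
    counts <- matrix(0L, n_targets, n_samples)
    hit <- matrix(stats::runif(n_targets * n_samples) < bg_rate,
                  n_targets, n_samples)
    counts[hit] <- sample(1:5, sum(hit), replace = TRUE,
                          prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
    counts
  })
}

#' Summarize control samples for detection thresholds
#'
#' @param counts matrix of per-target read counts (targets x control
#'   samples), as from [simulate_control_counts()].
#' @return list: `max_target_reads` (highest single count anywhere),
#'   `max_positive_svs` (highest per-sample number of targets with reads).
#' @export
summarize_controls <- function(counts) {
  counts <- as.matrix(counts)
  list(max_target_reads = max(counts, 0L),
       max_positive_svs = if (ncol(counts)) max(colSums(counts >= 1L)) else 0L)
}

#' Write sequences to a FASTQ file
#'
#' Constant `I` qualities (matching downstream matching, which is on
#' sequence only).
#'
#' @param seqs named character vector of sequences.
#' @param path output path (`.gz` for gzip).
#' @export
write_fastq <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("I", nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Write a named sequence vector to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(as.character(seqs), names(seqs))),
    path)
  invisible(path)
}
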