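---
title: "Detecting and quantifying ctDNA through SV breakpoint junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying ctDNA through SV breakpoint junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svjunction)
```

## The model

A somatic structural variant (SV) fuses two genomic loci. The fusion point —
the *breakpoint junction* — is flanked by sequence that exists in the
germline, but the joined combination does not. A tumor-informed liquid
biopsy assay therefore works by (1) selecting trustworthy patient-specific
SVs from tumor/normal sequencing, (2) building a *junction reference* for
each (150 bp of flank on either side of the predicted breakpoint, plus any
inserted bases), and (3) searching plasma cell-free DNA (cfDNA) reads for
molecules that span the junction. Because the junction sequence is absent
from normal genomes, specificity is structural rather than statistical, and
detection reduces to counting molecules above a background driven mainly by
index hopping between multiplexed libraries.

With DNA input deliberately limited, the multiplex PCR assay is *digital*:
each of `wells × n_svs` (SV, well) targets is an independent Bernoulli trial
whose success probability under Poisson loading of mutant fragments is
`1 - exp(-copies_per_well × AF)`. Three estimators follow:

* linear: `AF = events / (total_copies × n_svs)` — unbiased at low AF,
  saturating as wells begin to hold multiple mutant molecules of one SV;
* Poisson-corrected: `AF = -(1/copies_per_well) × ln(1 - events/(wells × n_svs))`
  — the exact inverse of the loading model, used for dilution series;
* whole-genome: `AF = reads / (2 × depth × n_svs)` — each genome equivalent
  contributes two chromosome copies per junction locus.

The theoretical limit of detection is the AF at which one positive event is
expected: `LOD = 1/(copies × n_svs)`, i.e. `af_linear(1, copies, n_svs)`.
Its inversions (`required_svs`, `required_copies`) answer the design
question "how many targets or copies do I need to see a given AF?" as
ceilings of `1/(AF × other)`.

## Panel selection

`filter_high_confidence()` retains an SV iff all of the following hold; all
failing rules are recorded per SV so the report is an audit trail:

| rule | default | notes |
|---|---|---|
| somatic score | ≥ 31 | caller-assigned confidence; strict `< 31` is rejected |
| chromosomes | autosomes + X + Y | mitochondrial/unplaced breaks excluded |
| repeat/gap | repeat > 100 bp overlapping; gap within 100 bp | see below |
| recurrence | blacklist from pooled cohort | single linkage, ≥ 2 samples per cluster |
| span | inter-chromosomal or > 100 kb | strict inequality: a 100,000 bp span is rejected |
| CN step | ≥ 1 breakpoint within 10 kb | both breakpoints optional |

Two decisions here were genuinely open and are parameterized rather than
guessed:

* **Gap adjacency** has no canonical window; we default to 100 bp
  (`adjacency_window`), the same order as the repeat-length cutoff, on the
  reasoning that a breakpoint called within a read length of an assembly gap
  is plausibly a mapping artefact.
* **CN-step proximity** could require one or both breakpoints near a
  copy-number step. We default to *one* (`require_both_cn_steps = FALSE`):
  unbalanced rearrangements often produce a step at only one side, and the
  permissive default maximizes panel size, which the LOD math rewards
  linearly.

Recurrent-breakpoint clustering is single linkage per chromosome: breaks
closer than the window are chained, and a cluster is blacklisted only when
it contains ≥ 2 distinct samples. Rule (i) applies a 2 kb window to
breakpoints of large SVs (span > 100 kb, or inter-chromosomal); rule (ii) a
200 bp window to all breakpoints.

## Coordinates and orientations

All interval arithmetic is 0-based half-open internally; VCF positions are
converted at parse time. A breakpoint position is the last reference base
before the junction on side A and the first base after it on side B.
`orient = "+"` on side A means the junction keeps the sequence *ending at*
`pos_a`; `"-"` keeps the reverse complement of the sequence starting there
(side B mirrors this). Breakend bracket notation maps directly: an ALT
beginning with the ref base retains the left side (`+`); bracket `[` means
the mate continues rightwards on the forward strand (`+`), `]` leftwards
reverse-complemented (`-`). Canonicalization (side A sorts first by
chromosome rank, then position) swaps sides by flipping both orientations
and reverse-complementing any inserted sequence — the junction it implies is
the reverse complement of the original, which all matching treats as
equivalent since both read strands are tried.

## Fuzzy matching

All matching uses unit-cost Levenshtein distance — a mismatch, insertion or
deletion each cost 1 — through base R's `adist`/`aregexec` machinery, with a
brute-force dynamic-programming oracle in the test suite as the independent
check.

**Amplicon matcher** (per read pair, per candidate amplicon): locate the
5' primer (≤ 2 edits, best distance first, leftmost on ties), locate the
other primer's reverse complement downstream (≤ 2 edits), discard
inter-primer targets < 25 bp (primer-dimer guard; interpreted as the insert
length, not the full product), extract the amplicon including primers and
require ≤ 5 edits against the expected sequence, and require both reads of
the pair to pass for the *same* amplicon. Read 1 is assumed to carry the
forward-primer strand (standard paired-end amplicon chemistry;
`swap_orientation` covers reversed layouts). When several amplicons pass,
the pair is assigned to the lowest total edit distance; exact ties are
`ambiguous` and excluded from counting — the conservative choice, since a
count assigned to the wrong SV is worse than a lost read. Failures are
reported as the furthest gate reached (`no_primer`, `short_product`,
`amplicon_mismatch`), with `discordant_pair` when the two reads each fully
matched different amplicons. Base qualities are parsed but ignored —
matching is on sequence alone.

**WGS junction matcher**: candidate reads have ≥ 10 soft/hard-clipped bases
at either alignment end. A candidate supports a junction when both 20 bp
flank probes (the junction sequence immediately left and right of the
breakpoint) occur in the read, in junction order, each within 2 edits
(indels allowed by default; `flank_substitutions_only` restores
mismatch-only semantics), and the read's edit distance to the junction
window implied by the flank offsets is at most `floor(0.025 × length)` —
for 150 bp reads, 3 edits. The window is searched over a small band
(budget + 2 start offsets) around the implied position, so flank-offset
error under indels cannot inflate the distance. Both strands are tried; a
hit on either counts once. Any UMI prefix is removed first and excluded
from the effective length. Rounding for the 2.5 % budget is `floor`, the
stricter choice, and the one the budget-exactness tests pin down (3
accepted, 4 rejected on 150 bp).

Note an interaction the simulator respects: reads clipped by 10–19 bases
are extracted as candidates but *cannot* contain a full 20 bp flank on the
clipped side, so they never become hits. The WGS simulator therefore plants
reads with at least 20 junction bases on each side, keeping recall exactly
1 at zero error rate.

**Capture counting**: reads aligned to the junction reference are counted
iff the alignment covers the breakpoint ± 20 bp completely and identically
(no mismatch, insertion or deletion inside the window; mismatches outside
are irrelevant). Single reads are counted — whether the original analysis
required pairs is unknowable from the text, and single-read counting is the
less restrictive reading of "reads spanning the breakpoint".

**UMI deduplication** counts distinct `(sv_id, UMI, alignment start)` keys,
approximating family collapsing without consensus building (consensus
calling is out of scope). Hits without a UMI fall back to
`(sv_id, read name)`.

## Detection thresholds

A target is positive only when its read count strictly exceeds twice the
highest non-specific count seen in any negative control or unrelated
sample. Strict inequality is forced by the worked values the rule must
reproduce: with a control maximum of 5, counts ≤ 10 are filtered; with a
control maximum of 4, "more than 8 reads" is detected. The capture assay
adds rule (b): detection when the *number* of SVs with any reads strictly
exceeds twice the control maximum of that same quantity — a guard for
diffuse index-hopping signal that no single SV would flag.

Positive events are counted per (SV, well), not per distinct SV: the
digital denominator `copies × n_svs` counts (SV, well) opportunities, and
the arithmetic of the worked examples (1 event in 211,500 targets) only
closes under that reading.

## The simulators: what a green test establishes

The generators emulate the *stated world* of the assay:

* dilution design: 10 % / 1 % / 0.1 % AF in 3 wells (30, 90, 900 total
  copies) and 0.01 % / 0.003 % / 0.001 % / 0.0004 % in 5 wells of 900
  copies (4,500 per level);
* molecule loading: Poisson per (SV, well) (binomial sampling differs
  negligibly at these copy numbers and is not modelled);
* reads per molecule: geometric with configurable mean — uneven PCR
  amplification matters only through the threshold, so any positive count
  distribution serves;
* errors: uniform substitutions (optional indels); constant quality
  strings, since matching ignores qualities;
* control background: each target shows non-specific reads with probability
  2 % per control, at 1–5 reads with decreasing frequency — the "low counts
  (≤ 5)" index-hopping regime actually observed in negative controls;
* fragment lengths: discretized two-component normal mixture, tumor mode
  145 bp, wild-type mode 166 bp, common SD 25 bp, truncated below 50 bp —
  the canonical mononucleosomal cfDNA profile with the shorter tumor
  component, which is what makes 90–150 bp size selection enrich tumor
  signal.

Every emitted read carries exactly one truth record (planted SV, well, UMI,
error positions, expected classification), so recall/precision are computed
against truth, not against the implementation. What a green suite does
**not** establish: performance under realistic sequencer error profiles, GC
and library-prep bias, barcode collisions, alignment ambiguity in repeats,
or cohort-level detection rates — those require real reads and real
controls. The simulators are a correctness harness, not a benchmark.

## Numerical choices

* Edit budgets use `floor`; thresholds and span/score cutoffs are strict
  inequalities (documented per rule above).
* `required_svs`/`required_copies` subtract 1e-9 before the ceiling so that
  exact integer ratios (e.g. inverting the LOD of an `n`-SV panel) are not
  bumped up by floating-point noise.
* Zero-AF dilution points are excluded from log-log regression — their
  logarithm is undefined and an undetected dilution carries no quantitative
  information. Saturated points (all targets positive) are unestimable and
  returned as `NA` with the advice to dilute.
* Assay cross-correlation uses Pearson on log10 AFs (AFs span orders of
  magnitude) and Spearman on raw values, dropping non-detected pairs.
* `af_as_percent()` rounds to 2 significant figures for reporting only;
  internal arithmetic is never rounded.

## Known limitations

* Breakend parsing assumes standard bracket semantics and complete mate
  pairs; multi-allelic breakends and single-breakend records are not
  modelled.
* The amplicon matcher scans whole reads for primers; anchored search is a
  flag, not the default, trading a little speed for robustness to 5' bases.
* Capture AF reuses the WGS formula with on-target depth — an explicit
  interpretation, flagged in the result metadata, since the capture AF
  definition is under-specified upstream.
* The recurrence blacklist is only as good as the supplied cohort; with a
  single sample it is empty (with a warning), not inferred.
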