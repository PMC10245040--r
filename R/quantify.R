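#' Detection threshold from negative-control read counts
#'
#' The threshold is twice the highest non-specific read count observed for
#' any target in any negative control (no-template, healthy donor) or
#' unrelated patient sample; a target is called positive only when its read
#' count strictly exceeds the threshold. With a control maximum of 5 the
#' threshold is 10, so counts of 10 or fewer are filtered.
#'
#' @param controls list or data.frame with `max_target_reads` (and, for the
#'   capture rules, `max_positive_svs`); or a numeric vector of control
#'   per-target read counts, from which the maxima are taken.
#' @return integer threshold.
#' @export
derive_threshold <- function(controls) {
  if (is.numeric(controls)) {
    if (!length(controls)) stop("no control counts supplied", call. = FALSE)
    controls <- list(max_target_reads = max(controls))
  }
  if (is.null(controls$max_target_reads))
    stop("threshold undefined without controls", call. = FALSE)
  as.integer(2L * controls$max_target_reads)
}

#' Linear allele-fraction estimator for the digital multiplex assay
#'
#' AF = positive events / (total input copies x number of targeted SVs).
#' An "event" is one positive (SV, well) pair, so the denominator is the
#' number of opportunities for a single mutant molecule to be observed.
#'
#' @param events number of positive (SV, well) events.
#' @param total_copies sum of amplifiable DNA input copies across wells.
#' @param n_svs number of patient-specific SVs targeted.
#' @return allele fraction (fraction, not percent).
#' @export
af_linear <- function(events, total_copies, n_svs) {
  stopifnot_scalar_number(events, "events")
  stopifnot_scalar_number(total_copies, "total_copies", positive = TRUE)
  stopifnot_scalar_number(n_svs, "n_svs", positive = TRUE)
  if (events < 0) stop("events must be non-negative", call. = FALSE)
  if (events > total_copies * n_svs)
    stop("more events than possible targets (events > copies x SVs)",
         call. = FALSE)
  events / (total_copies * n_svs)
}

#' Poisson-corrected allele-fraction estimator
#'
#' At high AF a well can hold several mutant molecules of the same SV yet
#' contribute a single positive event, so the linear estimator saturates.
#' Treating molecule loading as Poisson, the fraction of positive targets is
#' `1 - exp(-copies_per_well * AF)`; inverting gives
#' `AF = -(1/copies_per_well) * ln(1 - events / (wells * n_svs))`.
#'
#' @param events positive (SV, well) events.
#' @param copies_per_well amplifiable DNA copies loaded per well.
#' @param wells number of wells the sample was divided into.
#' @param n_svs number of targeted SVs.
#' @return allele fraction.
#' @export
af_poisson <- function(events, copies_per_well, wells, n_svs) {
  stopifnot_scalar_number(events, "events")
  stopifnot_scalar_number(copies_per_well, "copies_per_well", positive = TRUE)
  stopifnot_scalar_number(wells, "wells", positive = TRUE)
  stopifnot_scalar_number(n_svs, "n_svs", positive = TRUE)
  total <- wells * n_svs
  if (events < 0 || events > total)
    stop("events must lie in [0, wells x n_svs]", call. = FALSE)
  if (events == total)
    stop("all targets positive: assay saturated, dilute the sample",
         call. = FALSE)
  -(1 / copies_per_well) * log(1 - events / total)
}

#' Theoretical limit of detection of a digital multiplex assay
#'
#' The smallest AF at which at least one positive event is expected:
#' `1 / (input copies x number of targeted SVs)`, identical to
#' `af_linear(1, copies, n_svs)`.
#'
#' @param copies amplifiable DNA input copies.
#' @param n_svs number of targeted SVs.
#' @return allele fraction.
#' @export
theoretical_lod <- function(copies, n_svs) {
  stopifnot_scalar_number(copies, "copies", positive = TRUE)
  stopifnot_scalar_number(n_svs, "n_svs", positive = TRUE)
  1 / (copies * n_svs)
}

#' Assay-design inversions of the limit of detection
#'
#' `required_svs()` returns the smallest number of targeted SVs for which at
#' least one positive event is expected at allele fraction `af` with a fixed
#' DNA input; `required_copies()` the smallest input for a fixed panel size.
#' Both are ceilings of `1 / (af x other)`.
#'
#' @param af target allele fraction (fraction, > 0).
#' @param copies amplifiable DNA input copies.
#' @param n_svs number of targeted SVs.
#' @return integer count.
#' @export
required_svs <- function(af, copies) {
  stopifnot_scalar_number(af, "af", positive = TRUE)
  stopifnot_scalar_number(copies, "copies", positive = TRUE)
  if (af >= 1) return(1L)
  as.integer(ceiling(1 / (af * copies) - 1e-9))   # guard fp noise at integers
}

#' @rdname required_svs
#' @export
required_copies <- function(af, n_svs) {
  stopifnot_scalar_number(af, "af", positive = TRUE)
  stopifnot_scalar_number(n_svs, "n_svs", positive = TRUE)
  if (af >= 1) return(1L)
  as.integer(ceiling(1 / (af * n_svs) - 1e-9))
}

#' Detection call for a multiplex-PCR sample
#'
#' Counts positive (SV, well) events — control amplicon excluded — as those
#' with `matched_pair_count` strictly above the control-derived threshold,
#' and reports the linear AF together with the theoretical limit of
#' detection for the input used.
#'
#' @param table well count table (see [tabulate_counts()]); must carry
#'   `input_copies` per well.
#' @param n_svs number of SVs targeted by the panel.
#' @param threshold integer threshold from [derive_threshold()].
#' @param sample_id optional sample label.
#' @return list: `sample_id`, `assay`, `detected`, `positive_events`, `af`,
#'   `lod`, `threshold_used`, `total_copies`.
#' @export
call_multiplex <- function(table, n_svs, threshold, sample_id = NA_character_) {
  tgt <- table[!table$is_control, , drop = FALSE]
  if (any(is.na(tgt$input_copies)))
    stop("input_copies missing for assayed wells", call. = FALSE)
  events <- sum(tgt$matched_pair_count > threshold)
  wells <- unique(tgt[, c("sample_id", "well_id", "input_copies")])
  total_copies <- sum(wells$input_copies)
  list(sample_id = sample_id, assay = "multiplex",
       detected = events >= 1L, positive_events = as.integer(events),
       af = if (events > 0) af_linear(events, total_copies, n_svs) else 0,
       lod = theoretical_lod(total_copies, n_svs),
       threshold_used = as.integer(threshold),
       total_copies = total_copies)
}

#' Detection call for a hybrid-capture sample
#'
#' A sample is detected if (a) any targeted SV has a read count strictly
#' greater than twice the highest per-SV count seen in any control, or (b)
#' the number of SVs with any reads strictly exceeds twice the highest such
#' number seen in any control. The AF includes all positive reads and reuses
#' the WGS formula with the on-target mean depth.
#'
#' @param counts data.frame per SV with `read_count` (and optionally
#'   `molecule_count`, used for the AF when present).
#' @param controls list with `max_target_reads` and `max_positive_svs`.
#' @param mean_depth mean on-target coverage depth.
#' @param n_svs number of targeted SVs.
#' @param sample_id optional sample label.
#' @return list like [call_multiplex()], plus `rule` (`"a"`, `"b"`, `"a+b"`
#'   or `NA`).
#' @export
call_capture <- function(counts, controls, mean_depth, n_svs,
                         sample_id = NA_character_) {
  if (is.null(controls$max_target_reads) || is.null(controls$max_positive_svs))
    stop("capture detection needs control summaries (max_target_reads, ",
         "max_positive_svs)", call. = FALSE)
  thr_reads <- 2L * controls$max_target_reads
  thr_svs <- 2L * controls$max_positive_svs
  rule_a <- any(counts$read_count > thr_reads)
  n_pos <- sum(counts$read_count >= 1L)
  rule_b <- n_pos > thr_svs
  detected <- rule_a || rule_b
  reads <- if (!is.null(counts$molecule_count)) sum(counts$molecule_count)
           else sum(counts$read_count)
  list(sample_id = sample_id, assay = "capture", detected = detected,
       positive_events = as.integer(n_pos),
       af = if (detected) wgs_af(reads, mean_depth, n_svs) else 0,
       lod = theoretical_lod(2 * mean_depth, n_svs),
       threshold_used = as.integer(thr_reads),
       rule = if (rule_a && rule_b) "a+b" else if (rule_a) "a"
              else if (rule_b) "b" else NA_character_)
}

#' Log-log regression of observed on expected allele fraction
#'
#' Ordinary least squares of `log10(observed_af)` on `log10(expected_af)`.
#' Points with zero or missing observed AF are excluded (their logarithm is
#' undefined; a dilution with no positive events carries no quantitative
#' information). Reports the slope's Wald t-test p-value.
#'
#' @param points data.frame with `expected_af` and `observed_af`.
#' @return list: `slope`, `intercept`, `r_squared`, `p_slope`, `n_used`.
#' @export
fit_loglog <- function(points) {
  use <- points[!is.na(points$observed_af) & points$observed_af > 0 &
                  points$expected_af > 0, , drop = FALSE]
  if (nrow(use) < 3L)
    stop("need >= 3 dilution points with observed_af > 0", call. = FALSE)
  fit <- stats::lm(log10(observed_af) ~ log10(expected_af), data = use)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients[2L, 4L],
       n_used = nrow(use))
}

#' Correlate allele fractions measured by two assays
#'
#' Pearson correlation on the log10 AFs and Spearman rank correlation on the
#' raw values; pairs where either AF is missing or non-positive are dropped
#' and counted.
#'
#' @param af_a,af_b paired AF vectors.
#' @return list: `pearson_r`, `pearson_p`, `spearman_rho`, `n_used`,
#'   `n_dropped`.
#' @export
correlate_assays <- function(af_a, af_b) {
  stopifnot(length(af_a) == length(af_b))
  ok <- !is.na(af_a) & !is.na(af_b) & af_a > 0 & af_b > 0
  if (sum(ok) < 3L)
    stop("need >= 3 mutually detected pairs", call. = FALSE)
  pe <- stats::cor.test(log10(af_a[ok]), log10(af_b[ok]), method = "pearson")
  sp <- suppressWarnings(stats::cor.test(af_a[ok], af_b[ok],
                                         method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate),
       n_used = sum(ok), n_dropped = sum(!ok))
}

#' Format a fraction as a percentage to 2 significant figures
#'
#' Reporting helper matching the field's convention of quoting allele
#' fractions as percentages; internal arithmetic is never rounded.
#'
#' @param af allele fraction(s).
#' @return numeric percentage(s), 2 significant figures.
#' @export
af_as_percent <- function(af) signif(af * 100, 2)
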