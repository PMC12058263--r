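# Quantification arithmetic: internal-standard normalization (A_norm),
# the two percent-acylation strategies, ionization-efficiency response
# factors, intact-tRNA yield, and replicate comparisons.

#' Bench volumes entering the A_norm correction factors
#'
#' After RNase A cleavage a fixed aliquot of supernatant is taken for
#' LC-HRMS and spiked with internal standard; whatever supernatant
#' remains unsampled ("leftover") is recorded per sample.  The defaults
#' (20 ul aliquot + 2 ul Leu-Enk spike) reproduce the assay's standard
#' 22/20 dilution factor.
#'
#' @param aliquot_ul Supernatant volume analysed (ul).
#' @param spike_ul Internal-standard spike volume (ul).
#' @return A `parti_volumes` record.
#' @export
parti_volumes <- function(aliquot_ul = 20, spike_ul = 2) {
  stopifnot(aliquot_ul > 0, spike_ul > 0)
  structure(list(aliquot_ul = aliquot_ul, spike_ul = spike_ul),
            class = "parti_volumes")
}

#' Per-sample metadata
#'
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `"no substrate"`,
#'   `"1 mM BocK"`).
#' @param leftover_volume_ul Supernatant volume (ul) remaining beyond
#'   the analysed aliquot; >= 0.
#' @param standard Internal-standard identity (default `"Leu-Enk"`).
#' @return A `sample_meta` record.
#' @export
sample_meta <- function(sample_id, condition = "unknown",
                        leftover_volume_ul = 0, standard = "Leu-Enk") {
  stopifnot(leftover_volume_ul >= 0)
  structure(list(sample_id = sample_id, condition = condition,
                 leftover_volume_ul = leftover_volume_ul,
                 standard = standard),
            class = "sample_meta")
}

#' Normalized abundance (A_norm) of a species in a sample
#'
#' Computes
#' \deqn{A_{norm} = \frac{\mathrm{analyte\ area}}{\mathrm{standard\ area}}
#'   \times \frac{a + s}{a} \times \frac{a + \ell}{a}}
#' where \eqn{a} is the analysed aliquot volume, \eqn{s} the standard
#' spike volume and \eqn{\ell} the leftover supernatant volume (all
#' ul).  With the default 20/2 ul volumes this is the assay's
#' (area ratio) x 22/20 x (20 + leftover)/20 equation.  The first
#' factor corrects for dilution of the analyte by the standard spike,
#' the second for the fraction of supernatant never sampled.
#'
#' @param analyte_area Summed area of all validated, non-artifact peaks
#'   of the species (0 if undetected).
#' @param standard_area Internal-standard peak area; must be > 0 (an
#'   undetected standard makes the sample unquantifiable).
#' @param meta A [sample_meta()].
#' @param volumes A [parti_volumes()].
#' @param species Species label recorded in the result.
#' @return An `anorm_result`: list with `species`, `analyte_area`,
#'   `standard_area`, `a_norm`.
#' @examples
#' a_norm(2, 4, sample_meta("s1", leftover_volume_ul = 10))$a_norm  # 0.825
#' @export
a_norm <- function(analyte_area, standard_area, meta,
                   volumes = parti_volumes(), species = NA_character_) {
  stopifnot(inherits(meta, "sample_meta"), analyte_area >= 0)
  if (!is.numeric(standard_area) || standard_area <= 0)
    stop("internal standard not detected (area <= 0): sample '",
         meta$sample_id, "' is unquantifiable", call. = FALSE)
  a <- volumes$aliquot_ul
  s <- volumes$spike_ul
  val <- (analyte_area / standard_area) * ((a + s) / a) *
    ((a + meta$leftover_volume_ul) / a)
  structure(list(species = species, sample_id = meta$sample_id,
                 condition = meta$condition, analyte_area = analyte_area,
                 standard_area = standard_area, a_norm = val),
            class = "anorm_result")
}

#' @export
print.anorm_result <- function(x, ...) {
  cat(sprintf("<A_norm> %s / %s: %.4f (analyte %g, standard %g)\n",
              x$sample_id, x$species, x$a_norm, x$analyte_area,
              x$standard_area))
  invisible(x)
}

.yield <- function(value, strategy, inputs, warn_clamp = FALSE) {
  clamped <- min(100, max(0, value))
  if (warn_clamp && clamped != value)
    warning(sprintf("percent acylation %.2f outside [0, 100]; clamped", value),
            call. = FALSE)
  structure(list(percent_acylation = clamped, strategy = strategy,
                 inputs = inputs),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf("<yield> %.1f%% acylation (%s strategy)\n",
              x$percent_acylation, x$strategy))
  invisible(x)
}

#' Percent acylation from the acyl-Ade / free-Ade area ratio
#'
#' Within a single sample, free adenosine proxies unreacted tRNA and
#' the acyl adenosine proxies acylated tRNA, so percent acylation is
#' 100 x acyl / (acyl + Ade).  The free-Ade area must exclude
#' fragmentation-artifact peaks (see
#' [flag_fragmentation_artifacts()]), otherwise the estimate is biased.
#'
#' @param acyl_area Summed validated acyl-Ade peak area.
#' @param ade_area Free-adenosine peak area, artifacts excluded.
#' @return A `yield_estimate` (strategy `"ratio"`).
#' @export
yield_ratio <- function(acyl_area, ade_area) {
  stopifnot(acyl_area >= 0, ade_area >= 0)
  if (acyl_area == 0 && ade_area == 0)
    stop("both areas are zero; yield undefined", call. = FALSE)
  .yield(100 * acyl_area / (acyl_area + ade_area), "ratio",
         list(acyl_area = acyl_area, ade_area = ade_area))
}

#' Percent acylation from free-Ade A_norm against a negative control
#'
#' The alternative strategy: the free-Ade A_norm in the substrate
#' sample, normalized to the free-Ade A_norm in the no-substrate
#' control, gives the percent of unacylated tRNA; subtracting from 100
#' gives percent acylation.  Values outside \[0, 100\] (noise around an
#' unacylated sample) are clamped with a warning.
#'
#' @param a_norm_ade_sample Free-Ade A_norm with substrate present.
#' @param a_norm_ade_control Free-Ade A_norm in the no-substrate
#'   control; must be > 0.
#' @return A `yield_estimate` (strategy `"control_normalized"`).
#' @export
yield_vs_control <- function(a_norm_ade_sample, a_norm_ade_control) {
  if (inherits(a_norm_ade_sample, "anorm_result"))
    a_norm_ade_sample <- a_norm_ade_sample$a_norm
  if (inherits(a_norm_ade_control, "anorm_result"))
    a_norm_ade_control <- a_norm_ade_control$a_norm
  if (a_norm_ade_control <= 0)
    stop("control A_norm must be > 0", call. = FALSE)
  stopifnot(a_norm_ade_sample >= 0)
  val <- 100 - 100 * a_norm_ade_sample / a_norm_ade_control
  .yield(val, "control_normalized",
         list(sample = a_norm_ade_sample, control = a_norm_ade_control),
         warn_clamp = TRUE)
}

#' Percent acylation from intact-tRNA major-ion areas
#'
#' For intact tRNA LC-MS, yield is the integrated area of the acylated
#' tRNA's major ion over the summed areas of acylated and unreacted
#' tRNA major ions.
#'
#' @param acyl_major_ion_area,unreacted_major_ion_area Integrated
#'   major-ion areas, >= 0 and not both zero.
#' @return A `yield_estimate` (strategy `"ratio"`).
#' @export
yield_from_intact_areas <- function(acyl_major_ion_area,
                                    unreacted_major_ion_area) {
  stopifnot(acyl_major_ion_area >= 0, unreacted_major_ion_area >= 0)
  if (acyl_major_ion_area == 0 && unreacted_major_ion_area == 0)
    stop("both areas are zero; yield undefined", call. = FALSE)
  .yield(100 * acyl_major_ion_area /
           (acyl_major_ion_area + unreacted_major_ion_area),
         "ratio",
         list(acyl_area = acyl_major_ion_area,
              unreacted_area = unreacted_major_ion_area))
}

#' Ionization-efficiency response factor of a species
#'
#' Different acyl adenosines ionize with different efficiencies, so
#' equal acylation levels need not give equal A_norm.  Dividing a
#' species' A_norm by an independently determined acylation yield
#' (from intact-tRNA MS of the same reaction) gives a response factor
#' in A_norm units per percent acylation; dividing any later A_norm by
#' this factor makes cross-species comparisons response-independent.
#'
#' @param a_norm An `anorm_result` or numeric A_norm value.
#' @param independent_yield Percent acylation (> 0) of the calibration
#'   reaction, from intact-tRNA MS.
#' @param species Species label recorded in the result.
#' @return A `response_factor` record with `$factor`.
#' @export
response_factor <- function(a_norm, independent_yield,
                            species = NA_character_) {
  if (inherits(a_norm, "anorm_result")) {
    if (is.na(species)) species <- a_norm$species
    a_norm <- a_norm$a_norm
  }
  if (inherits(independent_yield, "yield_estimate"))
    independent_yield <- independent_yield$percent_acylation
  if (independent_yield <= 0)
    stop("independent yield must be > 0", call. = FALSE)
  stopifnot(a_norm >= 0)
  structure(list(species = species, factor = a_norm / independent_yield),
            class = "response_factor")
}

#' Response-corrected abundance
#'
#' @param a_norm An `anorm_result` or numeric.
#' @param rf A [response_factor()].
#' @return Numeric corrected abundance (percent-acylation scale).
#' @export
correct_abundance <- function(a_norm, rf) {
  if (inherits(a_norm, "anorm_result")) a_norm <- a_norm$a_norm
  stopifnot(inherits(rf, "response_factor"), rf$factor > 0)
  a_norm / rf$factor
}

.sig_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Compare A_norm values across conditions
#'
#' Per-group mean and standard deviation; a two-tailed Welch t-test for
#' two groups or a one-way ANOVA for more, with the familiar
#' significance tiers (ns / * / ** / *** at 0.05 / 0.01 / 0.001).
#' Pairwise contrasts for > 2 groups are reported unadjusted and
#' flagged as such.
#'
#' @param groups Named list of numeric vectors (one per condition).
#' @return A `condition_comparison`: list with `summary` (data.frame of
#'   group, n, mean, sd), `test`, `p_value`, `significance`, and for
#'   ANOVA a `pairwise` data.frame of unadjusted Welch contrasts.
#' @export
compare_conditions <- function(groups) {
  if (length(groups) == 0L) stop("no groups supplied", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  summ <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    row.names = NULL)
  test <- NA_character_
  p <- NA_real_
  pairwise <- NULL
  infer <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) == 2L && length(infer) == 2L) {
    test <- "Welch two-tailed t-test"
    p <- if (stats::sd(unlist(groups)) == 0) 1 else
      tryCatch(stats::t.test(groups[[1]], groups[[2]])$p.value,
               error = function(e) 1)
  } else if (length(groups) > 2L && length(infer) >= 2L) {
    test <- "one-way ANOVA"
    vals <- unlist(infer, use.names = FALSE)
    fac <- factor(rep(names(infer), vapply(infer, length, integer(1))))
    p <- if (stats::sd(vals) == 0) 1 else
      tryCatch(summary(stats::aov(vals ~ fac))[[1]][["Pr(>F)"]][1],
               error = function(e) 1)
    cmb <- utils::combn(names(infer), 2)
    pairwise <- data.frame(
      group1 = cmb[1, ], group2 = cmb[2, ],
      p_unadjusted = apply(cmb, 2, function(g) {
        a <- infer[[g[1]]]; b <- infer[[g[2]]]
        if (stats::sd(c(a, b)) == 0) return(1)
        tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      }))
    pairwise$significance <- vapply(pairwise$p_unadjusted, .sig_tier,
                                    character(1))
  }
  structure(list(summary = summ, test = test, p_value = p,
                 significance = .sig_tier(p), pairwise = pairwise),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  print(x$summary)
  if (!is.na(x$test))
    cat(sprintf("%s: p = %.4g (%s)\n", x$test, x$p_value, x$significance))
  invisible(x)
}
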