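# Extracted ion chromatograms and the discovery -> confirmation ->
# re-extraction procedure: discovery EIC at 100 ppm, peak detection,
# <5 ppm mass-error confirmation plus isotope-envelope check, then
# narrow re-extraction over the observed monoisotopic peak.

#' Extract an ion chromatogram
#'
#' For each spectrum, sums the intensities of all centroids inside a
#' symmetric ppm window around `target_mz`; one trace point per
#' spectrum (zero where nothing matches).  Discovery extraction uses
#' 100 ppm so that a species is found even with modest calibration
#' offset.
#'
#' @param run An `lcms_run`.
#' @param target_mz Target m/z in Da (must lie in the run's recorded
#'   m/z range).
#' @param ppm_window Half-width of the symmetric window in ppm.
#' @return An `eic`: list with `target_mz`, `window` (low/high Da), and
#'   `trace` (data.frame `rt`, `intensity`).
#' @export
extract_eic <- function(run, target_mz, ppm_window = 100) {
  stopifnot(inherits(run, "lcms_run"), is.numeric(target_mz),
            length(target_mz) == 1L, ppm_window > 0)
  if (target_mz < run$mz_range[1] || target_mz > run$mz_range[2])
    stop(sprintf("target m/z %.4f outside acquisition range [%g, %g]",
                 target_mz, run$mz_range[1], run$mz_range[2]), call. = FALSE)
  lo <- target_mz * (1 - ppm_window / 1e6)
  hi <- target_mz * (1 + ppm_window / 1e6)
  ints <- vapply(run$spectra, function(s) {
    sel <- s$mz >= lo & s$mz <= hi
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, numeric(1))
  structure(list(target_mz = target_mz, window = c(low = lo, high = hi),
                 trace = data.frame(rt = run_rts(run), intensity = ints)),
            class = "eic")
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("<eic> target %.5f Da, window [%.5f, %.5f], %d points, max %g\n",
              x$target_mz, x$window[1], x$window[2], nrow(x$trace),
              max(x$trace$intensity)))
  invisible(x)
}

# empty peak table with the full column contract
.empty_peaks <- function() {
  data.frame(apex_rt = numeric(0), rt_lo = numeric(0), rt_hi = numeric(0),
             area = numeric(0), apex_intensity = numeric(0),
             apex_mz_observed = numeric(0), mass_error_ppm = numeric(0),
             envelope_score = numeric(0), validated = logical(0),
             fragmentation_artifact = logical(0))
}

#' Detect chromatographic peaks in an EIC
#'
#' Local maxima above the noise floor become peak candidates.
#' Candidates whose apexes are separated by up to twice the median scan
#' interval are merged (the taller apex wins; ties go to the earlier
#' retention time).  Peak boundaries extend from the apex to the
#' flanking valley (the intensity minimum before the neighboring peak
#' or trace end) or to the first point at or below 1% of the apex
#' intensity, whichever is nearer; areas are trapezoidal integrals
#' over those bounds.
#' Deterministic: identical input yields identical output.
#'
#' @param eic An `eic` with at least 5 trace points.
#' @param noise_floor Intensity threshold; default 3x the median of
#'   the nonzero trace intensities (scale-free).
#' @return Peak table (data.frame), one row per peak, ordered by
#'   `apex_rt`; validation columns are `NA`/`FALSE` until
#'   [validate_peak()] runs.
#' @export
detect_peaks <- function(eic, noise_floor = NULL) {
  stopifnot(inherits(eic, "eic"))
  tr <- eic$trace
  if (nrow(tr) < 5L)
    stop("EIC trace has fewer than 5 points", call. = FALSE)
  y <- tr$intensity
  rt <- tr$rt
  if (is.null(noise_floor)) {
    nz <- y[y > 0]
    noise_floor <- if (length(nz)) 3 * stats::median(nz) else Inf
  }
  n <- length(y)
  is_max <- y > noise_floor &
    y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf) &
    (y > c(-Inf, y[-n]) | y > c(y[-1], -Inf))
  apexes <- which(is_max)
  if (length(apexes) == 0L) return(.empty_peaks())

  # merge apexes separated by up to 2x the median scan interval
  gap <- 2 * stats::median(diff(rt)) * (1 + 1e-9)
  keep <- integer(0)
  group <- apexes[1]
  for (i in apexes[-1]) {
    if (rt[i] - rt[group[length(group)]] <= gap) {
      group <- c(group, i)
    } else {
      keep <- c(keep, group[which.max(y[group])])  # ties: earlier RT wins
      group <- i
    }
  }
  keep <- c(keep, group[which.max(y[group])])

  # Boundaries: the valley (regional intensity minimum) between this
  # apex and its neighboring kept apex (or the trace end), clipped
  # inward to the first point at or below 1% of the apex intensity,
  # whichever lies nearer the apex.
  keep <- sort(keep)
  rows <- lapply(seq_along(keep), function(k) {
    a <- keep[k]
    floor_i <- 0.01 * y[a]
    left0 <- if (k > 1L) keep[k - 1L] else 1L
    seg <- left0:a
    lo <- seg[max(which(y[seg] == min(y[seg])))]
    below <- seg[y[seg] <= floor_i & seg < a]
    if (length(below)) lo <- max(lo, max(below))
    right0 <- if (k < length(keep)) keep[k + 1L] else n
    seg <- a:right0
    hi <- seg[min(which(y[seg] == min(y[seg])))]
    below <- seg[y[seg] <= floor_i & seg > a]
    if (length(below)) hi <- min(hi, min(below))
    data.frame(apex_rt = rt[a], rt_lo = rt[lo], rt_hi = rt[hi],
               area = pracma::trapz(rt[lo:hi], y[lo:hi]),
               apex_intensity = y[a], apex_mz_observed = NA_real_,
               mass_error_ppm = NA_real_, envelope_score = NA_real_,
               validated = FALSE, fragmentation_artifact = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$apex_rt), , drop = FALSE]
}

# intensity-weighted mean centroid m/z within [lo, hi] at one spectrum
.weighted_mz <- function(spec, lo, hi) {
  sel <- spec$mz >= lo & spec$mz <= hi
  if (!any(sel)) return(NA_real_)
  sum(spec$mz[sel] * spec$intensity[sel]) / sum(spec$intensity[sel])
}

#' Validate a detected peak by exact mass and isotope envelope
#'
#' Confirms a peak's identity per the assay's rule: the observed
#' monoisotopic m/z (intensity-weighted mean centroid inside the
#' discovery window at the apex spectrum) must agree with the
#' theoretical \[M+H\]+ within 5 ppm, and the observed M+1/M intensity
#' ratio must agree with the composition's isotope envelope.  The
#' envelope score is 1 at exact ratio agreement, 0 at a two-fold or
#' larger deviation, and linear in the fold-deviation between.
#'
#' @param run The source `lcms_run`.
#' @param peak One row of a [detect_peaks()] table.
#' @param species The targeted `acyl_adenosine_species` (or any object
#'   with `$protonated_mz` and `$composition`).
#' @param envelope Optional precomputed `isotope_envelope`.
#' @param ppm_window Discovery window used for the observed-m/z search.
#' @param ppm_confirm Mass-error bound in ppm (default 5).
#' @param envelope_threshold Minimum envelope score (default 0.5).
#' @return The peak row with `apex_mz_observed`, `mass_error_ppm`,
#'   `envelope_score` and `validated` filled in.
#' @export
validate_peak <- function(run, peak, species, envelope = NULL,
                          ppm_window = 100, ppm_confirm = 5,
                          envelope_threshold = 0.5) {
  stopifnot(inherits(run, "lcms_run"), nrow(peak) == 1L)
  theo <- species$protonated_mz
  if (is.null(envelope)) envelope <- isotope_envelope(species$composition)
  rts <- run_rts(run)
  apex_i <- which.min(abs(rts - peak$apex_rt))
  if (abs(rts[apex_i] - peak$apex_rt) > max(diff(rts)))
    stop("apex spectrum missing from run", call. = FALSE)
  spec <- run$spectra[[apex_i]]
  lo <- theo * (1 - ppm_window / 1e6)
  hi <- theo * (1 + ppm_window / 1e6)
  obs <- .weighted_mz(spec, lo, hi)
  if (is.na(obs)) {
    peak$validated <- FALSE
    return(peak)
  }
  err_ppm <- (obs - theo) / theo * 1e6
  # observed M+1/M ratio at the apex spectrum
  m0 <- sum(spec$intensity[spec$mz >= lo & spec$mz <= hi])
  lo1 <- (theo + ISOTOPE_SPACING) * (1 - ppm_window / 1e6)
  hi1 <- (theo + ISOTOPE_SPACING) * (1 + ppm_window / 1e6)
  m1 <- sum(spec$intensity[spec$mz >= lo1 & spec$mz <= hi1])
  r_theo <- envelope$abundance[envelope$offset == 1L] /
    envelope$abundance[envelope$offset == 0L]
  score <- if (m0 <= 0 || m1 <= 0) {
    0
  } else {
    r_obs <- m1 / m0
    fold <- max(r_obs, r_theo) / min(r_obs, r_theo)
    max(0, 2 - fold)
  }
  peak$apex_mz_observed <- obs
  peak$mass_error_ppm <- err_ppm
  peak$envelope_score <- score
  peak$validated <- abs(err_ppm) < ppm_confirm && score >= envelope_threshold
  peak
}

#' Validate every peak in a table
#'
#' @inheritParams validate_peak
#' @param peaks A [detect_peaks()] table.
#' @return The table with validation columns filled.
#' @export
validate_peaks <- function(run, peaks, species, envelope = NULL,
                           ppm_window = 100, ppm_confirm = 5,
                           envelope_threshold = 0.5) {
  if (nrow(peaks) == 0L) return(peaks)
  if (is.null(envelope)) envelope <- isotope_envelope(species$composition)
  out <- lapply(seq_len(nrow(peaks)), function(i)
    validate_peak(run, peaks[i, , drop = FALSE], species, envelope,
                  ppm_window, ppm_confirm, envelope_threshold))
  do.call(rbind, out)
}

#' Re-quantify a validated peak over its observed monoisotopic m/z
#'
#' Quantification re-extracts a narrow EIC (default +/- 25 ppm) centred
#' on the observed apex centroid rather than the theoretical mass, so
#' that the integrated area tracks the monoisotopic peak actually
#' present in the sample and excludes wide-window interferences.  The
#' area is re-integrated over the peak's existing RT bounds.  If the
#' narrow trace is empty the discovery-window area is retained with a
#' warning.
#'
#' @param run The source `lcms_run`.
#' @param peak A validated peak row.
#' @param ppm_requant Narrow half-window in ppm (default 25).
#' @return The peak row with `area` replaced.
#' @export
requantify_peak <- function(run, peak, ppm_requant = 25) {
  stopifnot(nrow(peak) == 1L)
  if (!isTRUE(peak$validated))
    stop("requantify_peak() expects a validated peak", call. = FALSE)
  eic <- extract_eic(run, peak$apex_mz_observed, ppm_window = ppm_requant)
  tr <- eic$trace
  sel <- tr$rt >= peak$rt_lo & tr$rt <= peak$rt_hi
  if (!any(tr$intensity[sel] > 0)) {
    warning("narrow re-extraction empty; keeping discovery-window area",
            call. = FALSE)
    return(peak)
  }
  peak$area <- pracma::trapz(tr$rt[sel], tr$intensity[sel])
  peak
}

#' Flag free-adenosine peaks caused by in-source fragmentation
#'
#' Acyl-adenosine ions partially fragment to the adenosine ion inside
#' the source, producing small Ade EIC peaks at the acyl species'
#' retention time.  Any Ade peak whose RT bounds overlap a validated
#' acyl-adenosine peak is flagged `fragmentation_artifact` and must be
#' excluded from free-Ade quantification.
#'
#' @param ade_peaks Peak table for the free-adenosine EIC.
#' @param acyl_peaks Peak table (or rbind of tables) for acyl species.
#' @return `ade_peaks` with `fragmentation_artifact` set.
#' @export
flag_fragmentation_artifacts <- function(ade_peaks, acyl_peaks) {
  if (nrow(ade_peaks) == 0L || nrow(acyl_peaks) == 0L) return(ade_peaks)
  ac <- acyl_peaks[acyl_peaks$validated, , drop = FALSE]
  if (nrow(ac) == 0L) return(ade_peaks)
  ade_peaks$fragmentation_artifact <- vapply(seq_len(nrow(ade_peaks)),
    function(i) any(ade_peaks$rt_lo[i] <= ac$rt_hi &
                    ade_peaks$rt_hi[i] >= ac$rt_lo), logical(1))
  ade_peaks
}
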