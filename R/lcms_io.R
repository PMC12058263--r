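# In-memory model of a centroided LC-MS run and mzML I/O (via mzR).
# Retention time is minutes throughout the package; mzML stores seconds
# and the conversion happens only at this boundary.

#' Create a centroided spectrum
#'
#' @param retention_time Retention time in minutes (>= 0).
#' @param mz Centroid m/z values, strictly increasing.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @return A `spectrum` object.
#' @export
spectrum <- function(retention_time, mz, intensity) {
  stopifnot(is.numeric(retention_time), length(retention_time) == 1L,
            retention_time >= 0, length(mz) == length(intensity))
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("spectrum m/z values must be strictly increasing", call. = FALSE)
  if (any(intensity < 0))
    stop("spectrum intensities must be >= 0", call. = FALSE)
  structure(list(retention_time = as.numeric(retention_time),
                 mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "spectrum")
}

#' Create an LC-MS run
#'
#' @param spectra List of `spectrum` objects with non-decreasing
#'   retention times.
#' @param sample Sample label.
#' @param polarity `"positive"` or `"negative"`.
#' @param rt_window Acquisition window in minutes (default 1.4-7 min,
#'   the assay's standard collection window).
#' @param mz_range Recorded m/z range in Da (default 100-3000).
#' @return An `lcms_run` object.
#' @export
lcms_run <- function(spectra, sample = "sample", polarity = "positive",
                     rt_window = c(1.4, 7), mz_range = c(100, 3000)) {
  if (length(spectra) == 0L) stop("a run needs >= 1 spectrum", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  rts <- vapply(spectra, `[[`, numeric(1), "retention_time")
  if (any(diff(rts) < 0))
    stop("spectra must be in acquisition order (non-decreasing RT)",
         call. = FALSE)
  structure(list(spectra = spectra, sample = sample, polarity = polarity,
                 rt_window = as.numeric(rt_window),
                 mz_range = as.numeric(mz_range)),
            class = "lcms_run")
}

#' @export
print.lcms_run <- function(x, ...) {
  rts <- run_rts(x)
  cat(sprintf(
    "<lcms_run> '%s': %d spectra, RT %.2f-%.2f min, m/z %g-%g, %s mode\n",
    x$sample, length(x$spectra), min(rts), max(rts),
    x$mz_range[1], x$mz_range[2], x$polarity))
  invisible(x)
}

#' Retention times of a run
#' @param run An `lcms_run`.
#' @return Numeric vector, minutes.
#' @export
run_rts <- function(run) {
  vapply(run$spectra, `[[`, numeric(1), "retention_time")
}

#' Total ion current of a run
#' @param run An `lcms_run`.
#' @return Per-spectrum summed intensity.
#' @export
total_ion_current <- function(run) {
  vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
}

#' Read a centroided mzML run
#'
#' Loads all MS1 spectra in acquisition order.  Profile-mode data are
#' rejected: the pipeline's extraction and validation rules assume
#' centroided peaks, and silently treating profile points as centroids
#' would corrupt every downstream area.
#'
#' @param path Path to an mzML file.
#' @param sample Sample label; defaults to the file name.
#' @return An `lcms_run`.
#' @export
read_run <- function(path, sample = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) stop("mzML contains no spectra: ", path, call. = FALSE)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) stop("mzML contains no MS1 spectra", call. = FALSE)
  if (any(!hdr$centroided[ms1], na.rm = TRUE))
    stop("profile-mode spectra found in ", path,
         "; partiq consumes centroided data only", call. = FALSE)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(ms1, function(i) {
    p <- pk[[i]]
    spectrum(hdr$retentionTime[i] / 60, p[, 1L], p[, 2L])
  })
  lcms_run(spectra, sample = sample,
           polarity = if (all(hdr$polarity[ms1] >= 0)) "positive" else "negative",
           rt_window = range(hdr$retentionTime[ms1]) / 60,
           mz_range = c(min(hdr$scanWindowLowerLimit[ms1], na.rm = TRUE),
                        max(hdr$scanWindowUpperLimit[ms1], na.rm = TRUE)))
}

#' Write a run to mzML
#'
#' Emits standards-conformant centroided mzML readable by `read_run()`
#' and third-party readers.
#'
#' @param run An `lcms_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "lcms_run"))
  n <- length(run$spectra)
  pks <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  tic <- total_ion_current(run)
  bp <- vapply(run$spectra, function(s) {
    if (length(s$intensity) == 0L) return(c(NA_real_, 0))
    i <- which.max(s$intensity)
    c(s$mz[i], s$intensity[i])
  }, numeric(2))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = if (identical(run$polarity, "negative")) 0L else 1L,
    peaksCount = vapply(run$spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = tic,
    retentionTime = run_rts(run) * 60,
    basePeakMZ = bp[1L, ], basePeakIntensity = bp[2L, ],
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = run$mz_range[1], highMZ = run$mz_range[2],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = run$mz_range[1],
    scanWindowUpperLimit = run$mz_range[2],
    stringsAsFactors = FALSE)
  if (file.exists(path)) unlink(path)
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
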