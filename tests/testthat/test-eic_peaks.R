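# EIC extraction window arithmetic, peak detection, mass/envelope
# validation, and narrow re-extraction.

phe_mz <- 415.1724

test_that("discovery window is symmetric in ppm around the target", {
  run <- gaussian_eic_run(phe_mz, seq(1.4, 7, 0.01), 1000, 3.0, 0.03)
  eic <- extract_eic(run, phe_mz, ppm_window = 100)
  expect_equal(unname(eic$window["low"]), 415.13088, tolerance = 1e-4)
  expect_equal(unname(eic$window["high"]), 415.21392, tolerance = 1e-4)
  expect_error(extract_eic(run, 5000), "outside acquisition range")
})

test_that("a run with no centroid in the window gives an all-zero trace", {
  run <- gaussian_eic_run(800, seq(1.4, 3, 0.01), 1000, 2.0, 0.03)
  eic <- extract_eic(run, 400, ppm_window = 100)
  expect_true(all(eic$trace$intensity == 0))
  expect_equal(nrow(eic$trace), length(run$spectra))
})

test_that("summed EIC intensity never exceeds the run's total ion current", {
  sim <- simulate_run(make_parti_fixture("phe_invitro", seed = 2))
  targets <- c(268.10403, phe_mz, 556.27657)
  total <- Reduce(`+`, lapply(targets, function(mz)
    extract_eic(sim$run, mz, 100)$trace$intensity))
  expect_true(all(total <= total_ion_current(sim$run) + 1e-9))
})

test_that("peak detection recovers resolved Gaussians with accurate areas", {
  rts <- seq(1.4, 7, 0.01)
  run <- gaussian_eic_run(phe_mz, rts, 1000, 3.0, 0.03)
  eic <- extract_eic(run, phe_mz, 100)
  pks <- detect_peaks(eic, noise_floor = 1)
  expect_equal(nrow(pks), 1L)
  expect_equal(pks$apex_rt, 3.0, tolerance = 0.011)
  expect_equal(pks$area, 1000, tolerance = 0.01)  # closed-form integral

  # two peaks at the 2'/3'-isomer spacing
  spectra <- lapply(rts, function(rt) {
    h <- 550 * dnorm(rt, 2.9, 0.03) + 450 * dnorm(rt, 3.1, 0.03)
    spectrum(rt, phe_mz, h)
  })
  run2 <- lcms_run(spectra, rt_window = range(rts))
  pks2 <- detect_peaks(extract_eic(run2, phe_mz, 100), noise_floor = 1)
  expect_equal(nrow(pks2), 2L)
  expect_equal(pks2$apex_rt, c(2.9, 3.1), tolerance = 0.011)
})

test_that("peak detection handles flat traces, short traces, and is deterministic", {
  rts <- seq(1.4, 2, 0.01)
  run <- lcms_run(lapply(rts, function(rt) spectrum(rt, 400, 0)),
                  rt_window = range(rts))
  eic <- extract_eic(run, 400, 100)
  expect_equal(nrow(detect_peaks(eic)), 0L)

  short <- lcms_run(lapply(rts[1:4], function(rt) spectrum(rt, 400, 1)),
                    rt_window = range(rts[1:4]))
  expect_error(detect_peaks(extract_eic(short, 400, 100)), "fewer than 5")

  sim <- simulate_run(make_parti_fixture("phe_invitro", seed = 9))
  e <- extract_eic(sim$run, phe_mz, 100)
  expect_identical(detect_peaks(e), detect_peaks(e))
})

test_that("peak detection is translation-equivariant in retention time", {
  rts <- seq(1.4, 5, 0.01)
  delta <- 0.8
  run_a <- gaussian_eic_run(phe_mz, rts, 500, 2.5, 0.04)
  run_b <- gaussian_eic_run(phe_mz, rts + delta, 500, 2.5 + delta, 0.04)
  pa <- detect_peaks(extract_eic(run_a, phe_mz, 100), noise_floor = 1)
  pb <- detect_peaks(extract_eic(run_b, phe_mz, 100), noise_floor = 1)
  expect_equal(pb$apex_rt, pa$apex_rt + delta, tolerance = 1e-9)
  expect_equal(pb$area, pa$area, tolerance = 1e-9)
})

test_that("validation applies the <5 ppm rule on the observed apex m/z", {
  species <- mono_species("Phe")
  env <- isotope_envelope(species$composition)
  r <- env$abundance[2] / env$abundance[1]
  rts <- seq(2.5, 3.5, 0.01)
  make_run <- function(obs_mz)
    gaussian_eic_run(obs_mz, rts, 1000, 3.0, 0.03, m1_frac = r)

  # centroids exactly at theory: 0 ppm, validated
  run <- make_run(species$protonated_mz)
  pk <- detect_peaks(extract_eic(run, species$protonated_mz, 100),
                     noise_floor = 1)
  v <- validate_peak(run, pk, species)
  expect_equal(v$mass_error_ppm, 0, tolerance = 1e-6)
  expect_true(v$validated)

  # (observed - calc)/calc x 1e6: +4.5 ppm confirms, +5.5 ppm does not
  for (ppm_true in c(4.5, 5.5)) {
    run_off <- make_run(species$protonated_mz * (1 + ppm_true * 1e-6))
    pk_off <- detect_peaks(extract_eic(run_off, species$protonated_mz, 100),
                           noise_floor = 1)
    v_off <- validate_peak(run_off, pk_off, species)
    expect_equal(v_off$mass_error_ppm, ppm_true, tolerance = 0.01)
    expect_identical(v_off$validated, ppm_true < 5)
  }
})

test_that("a peak without the M+1 isotope line fails the envelope check", {
  species <- mono_species("Phe")
  rts <- seq(2.5, 3.5, 0.01)
  run <- gaussian_eic_run(species$protonated_mz, rts, 1000, 3.0, 0.03,
                          m1_frac = 1e-9)  # no isotope line injected
  pk <- detect_peaks(extract_eic(run, species$protonated_mz, 100),
                     noise_floor = 1)
  v <- validate_peak(run, pk, species)
  expect_lt(abs(v$mass_error_ppm), 5)
  expect_equal(v$envelope_score, 0)
  expect_false(v$validated)
})

test_that("narrow re-extraction excludes a wide-window interference", {
  species <- mono_species("Phe")
  mz0 <- species$protonated_mz
  rts <- seq(2.5, 3.5, 0.01)
  env <- isotope_envelope(species$composition)
  r <- env$abundance[2] / env$abundance[1]
  spectra <- lapply(rts, function(rt) {
    h <- 1000 * dnorm(rt, 3.0, 0.03)
    # analyte at theory plus a weak co-eluting interference 60 ppm away
    mzs <- c(mz0, mz0 * (1 + 60e-6), mz0 + 1.0033548)
    ord <- order(mzs)
    spectrum(rt, mzs[ord], c(h, 0.05 * h, r * h)[ord])
  })
  run <- lcms_run(spectra, rt_window = range(rts))
  pk <- detect_peaks(extract_eic(run, mz0, 100), noise_floor = 1)
  expect_equal(nrow(pk), 1L)
  v <- validate_peak(run, pk, species)
  discovery_area <- v$area
  rq <- requantify_peak(run, v)
  expect_lt(rq$area, discovery_area)
  expect_equal(rq$area, 1000, tolerance = 0.02)
})

test_that("empty narrow trace falls back to the discovery area with a warning", {
  species <- mono_species("Phe")
  env <- isotope_envelope(species$composition)
  rts <- seq(2.5, 3.5, 0.01)
  run <- gaussian_eic_run(species$protonated_mz, rts, 1000, 3.0, 0.03,
                          m1_frac = env$abundance[2] / env$abundance[1])
  pk <- detect_peaks(extract_eic(run, species$protonated_mz, 100),
                     noise_floor = 1)
  v <- validate_peak(run, pk, species)
  # simulate a bogus observed m/z far from every centroid
  v$apex_mz_observed <- species$protonated_mz * (1 + 90e-6)
  expect_warning(rq <- requantify_peak(run, v), "keeping discovery")
  expect_equal(rq$area, v$area)
})

test_that("Ade peaks co-eluting with validated acyl peaks are flagged as artifacts", {
  sim <- simulate_run(make_parti_fixture("phe_invitro", seed = 4,
                                         acylated_fraction = 0.4,
                                         fragmentation_fraction = 0.1))
  cfg <- pipeline_config()
  phe <- mono_species("Phe")
  acyl <- quantify_species(sim$run, phe, cfg)
  ade <- quantify_species(sim$run, compose_species(NULL, 0), cfg)
  ade <- flag_fragmentation_artifacts(ade, acyl)
  flagged <- ade[ade$fragmentation_artifact & ade$validated, ]
  expect_equal(nrow(flagged), 2L)  # one artifact per isomer peak
  # flagged artifact area ~ fragmentation_fraction x acyl area
  truth <- sim$truth
  expect_equal(sum(flagged$area),
               sum(truth$area_mono[truth$is_artifact]),
               tolerance = 0.05)
})
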