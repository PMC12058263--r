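# Seeded generator of synthetic centroided LC-MS runs with complete
# ground truth.  Emulates the structure of the assay's runs: 2'/3'
# isomer peak pairs (or diastereomer quartets), single-peak diacyl and
# free-Ade species, a Leu-Enk internal-standard peak, in-source
# fragmentation of acyl-Ade to Ade, and simple chromatographic noise.

#' A non-adenosine MS species (e.g. the internal standard)
#'
#' @param name Species label.
#' @param formula Hill-notation formula or `element_composition`.
#' @return An `ms_species` with the same mass fields as
#'   [compose_species()] output.
#' @export
standard_species <- function(name = "Leu-Enk", formula = "C28H37N5O7") {
  comp <- if (is.character(formula)) parse_formula(formula) else formula
  mass <- monoisotopic_mass(comp)
  structure(list(monomer = NULL, acyl_count = NA_integer_,
                 composition = comp, monoisotopic_mass = mass,
                 protonated_mz = mass + PROTON_MASS, label = name),
            class = "ms_species")
}

#' Declare an analyte for a synthetic run
#'
#' @param species An `acyl_adenosine_species` or `ms_species`.
#' @param isomer_rts Retention times (minutes) of the species' isobaric
#'   peaks; the count must respect [expected_isomer_count()] for
#'   acyl-adenosine species.
#' @param abundance Molar abundance (arbitrary units).
#' @param response Ionization response factor; the injected
#'   monoisotopic-line area, summed over isomer peaks, is
#'   `abundance * response` (intensity-minutes) -- the monoisotopic
#'   peak is what the workflow integrates, and the M+1.. lines are
#'   emitted on top at the envelope ratios.
#' @param width Gaussian chromatographic peak sigma in minutes.
#' @param split Optional area proportions across isomer peaks; default
#'   55:45 for a pair and a mildly decreasing split for more peaks.
#' @return An `analyte_spec`.
#' @export
analyte <- function(species, isomer_rts, abundance, response = 1,
                    width = 0.03, split = NULL) {
  stopifnot(abundance >= 0, response > 0, width > 0,
            length(isomer_rts) >= 1L)
  if (inherits(species, "acyl_adenosine_species")) {
    bounds <- expected_isomer_count(species)
    if (length(isomer_rts) < bounds[1] || length(isomer_rts) > bounds[2])
      stop(sprintf("%s admits %d-%d isobaric peaks, got %d",
                   species$label, bounds[1], bounds[2], length(isomer_rts)),
           call. = FALSE)
  }
  k <- length(isomer_rts)
  if (is.null(split)) {
    split <- if (k == 1L) 1 else seq(1.1, 0.9, length.out = k)
    split <- split / sum(split)
  }
  stopifnot(length(split) == k, all(split > 0))
  structure(list(species = species, isomer_rts = sort(isomer_rts),
                 abundance = abundance, response = response,
                 width = width, split = split / sum(split)),
            class = "analyte_spec")
}

#' Specify a synthetic LC-MS run
#'
#' @param analytes List of [analyte()] specs.
#' @param rt_window Acquisition window, minutes (default 1.4-7).
#' @param scan_interval Scan spacing in minutes (default 0.01).
#' @param mz_range Recorded m/z range in Da.
#' @param fragmentation_fraction Fraction of each acyl-adenosine peak's
#'   intensity re-emitted as a co-eluting free-adenosine cluster
#'   (in-source fragmentation); in \[0, 1).
#' @param baseline Mean baseline intensity of the chemical background
#'   at each monitored mass.
#' @param jitter_sd Standard deviation of the per-scan multiplicative
#'   log-normal intensity jitter.
#' @param mz_jitter_ppm Centroid m/z jitter bound (uniform, ppm).
#' @param seed Integer seed; identical seeds give identical runs.
#' @param sample Sample label.
#' @return A `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(analytes, rt_window = c(1.4, 7),
                               scan_interval = 0.01,
                               mz_range = c(100, 3000),
                               fragmentation_fraction = 0,
                               baseline = 5, jitter_sd = 0.05,
                               mz_jitter_ppm = 2, seed = 1L,
                               sample = "synthetic") {
  stopifnot(all(vapply(analytes, inherits, logical(1), "analyte_spec")),
            scan_interval > 0, fragmentation_fraction >= 0,
            fragmentation_fraction < 1, baseline >= 0, jitter_sd >= 0)
  for (an in analytes) {
    mz_hi <- an$species$protonated_mz + 3 * ISOTOPE_SPACING
    if (an$species$protonated_mz < mz_range[1] || mz_hi > mz_range[2])
      stop("m/z range does not cover the envelope of ", an$species$label,
           call. = FALSE)
  }
  structure(list(analytes = analytes, rt_window = as.numeric(rt_window),
                 scan_interval = scan_interval, mz_range = as.numeric(mz_range),
                 fragmentation_fraction = fragmentation_fraction,
                 baseline = baseline, jitter_sd = jitter_sd,
                 mz_jitter_ppm = mz_jitter_ppm, seed = as.integer(seed),
                 sample = sample),
            class = "synthetic_run_spec")
}

#' Simulate a centroided LC-MS run from a spec
#'
#' Each analyte isomer peak is a Gaussian chromatographic profile whose
#' injected monoisotopic-line area is `abundance * response * split`;
#' every scan emits the species' isotope envelope (offsets 0-3) at the
#' theoretical m/z with uniform centroid jitter, scaled by per-scan
#' log-normal intensity jitter.  A low-level exponential baseline is emitted at
#' every monitored mass in every scan.  If `fragmentation_fraction`
#' > 0, each acyl-adenosine peak co-emits a free-adenosine envelope
#' cluster at that fraction of its intensity.
#'
#' @param spec A [synthetic_run_spec()].
#' @return List with `run` (an `lcms_run`) and `truth` (data.frame of
#'   injected areas: per isomer peak, `area_total` over all
#'   isotopologues and `area_mono` for the monoisotopic line; artifact
#'   rows carry `is_artifact = TRUE`).
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  withr::with_seed(spec$seed, .simulate_run_impl(spec))
}

.simulate_run_impl <- function(spec) {
  rts <- seq(spec$rt_window[1], spec$rt_window[2], by = spec$scan_interval)
  nscan <- length(rts)
  ade <- compose_species(NULL, 0L)
  ade_env <- isotope_envelope(ade$composition)$abundance

  # Per-analyte envelope and per-isomer injected areas.  `areas` is the
  # injected monoisotopic-line area (the quantity the workflow
  # integrates); the M+1.. lines are emitted on top at envelope ratios.
  ana <- lapply(spec$analytes, function(an) {
    env <- isotope_envelope(an$species$composition)$abundance
    list(an = an, env = env, rel_env = env / env[1],
         areas = an$abundance * an$response * an$split)
  })

  truth <- list()
  for (a in ana) {
    an <- a$an
    for (j in seq_along(an$isomer_rts)) {
      truth[[length(truth) + 1L]] <- data.frame(
        species = an$species$label, isomer = j, rt = an$isomer_rts[j],
        area_mono = a$areas[j], area_total = a$areas[j] / a$env[1],
        is_artifact = FALSE)
      if (spec$fragmentation_fraction > 0 &&
          inherits(an$species, "acyl_adenosine_species") &&
          an$species$acyl_count > 0L) {
        f <- spec$fragmentation_fraction
        truth[[length(truth) + 1L]] <- data.frame(
          species = "Ade", isomer = j, rt = an$isomer_rts[j],
          area_mono = f * a$areas[j],
          area_total = f * a$areas[j] / ade_env[1],
          is_artifact = TRUE)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(0), isomer = integer(0), rt = numeric(0),
               area_mono = numeric(0), area_total = numeric(0),
               is_artifact = logical(0))

  monitored <- unique(vapply(ana, function(a) a$an$species$protonated_mz,
                             numeric(1)))
  if (spec$fragmentation_fraction > 0)
    monitored <- unique(c(monitored, ade$protonated_mz))

  spectra <- vector("list", nscan)
  for (i in seq_len(nscan)) {
    rt <- rts[i]
    mzs <- numeric(0)
    ints <- numeric(0)
    emit <- function(mz0, envelope, height) {
      k <- seq_along(envelope) - 1L
      jit <- stats::runif(length(k), -spec$mz_jitter_ppm, spec$mz_jitter_ppm)
      mzs <<- c(mzs, (mz0 + k * ISOTOPE_SPACING) * (1 + jit / 1e6))
      ints <<- c(ints, height * envelope)
    }
    for (a in ana) {
      an <- a$an
      for (j in seq_along(an$isomer_rts)) {
        h <- a$areas[j] * stats::dnorm(rt, an$isomer_rts[j], an$width)
        if (h < 1e-9 * a$areas[j]) next
        h <- h * exp(stats::rnorm(1, 0, spec$jitter_sd))
        emit(an$species$protonated_mz, a$rel_env, h)
        if (spec$fragmentation_fraction > 0 &&
            inherits(an$species, "acyl_adenosine_species") &&
            an$species$acyl_count > 0L)
          emit(ade$protonated_mz, ade_env / ade_env[1],
               h * spec$fragmentation_fraction)
      }
    }
    if (spec$baseline > 0)
      for (mz0 in monitored)
        emit(mz0, 1, spec$baseline * stats::rexp(1))
    ord <- order(mzs)
    mzs <- mzs[ord]
    ints <- ints[ord]
    # merge coincident centroids (strictly increasing m/z required)
    if (length(mzs) > 1L) {
      same <- c(FALSE, diff(mzs) <= 0)
      if (any(same)) {
        grp <- cumsum(!same)
        ints <- as.numeric(tapply(ints, grp, sum))
        mzs <- as.numeric(tapply(mzs, grp, min))
      }
    }
    spectra[[i]] <- spectrum(rt, mzs, ints)
  }
  run <- lcms_run(spectra, sample = spec$sample,
                  rt_window = spec$rt_window, mz_range = spec$mz_range)
  list(run = run, truth = truth)
}

#' Prebuilt synthetic scenarios mirroring the assay's experiments
#'
#' Returns fully parameterized run specs with documented ground truth:
#' \describe{
#'   \item{`no_substrate`}{Negative control: only the Leu-Enk internal
#'     standard elutes.}
#'   \item{`phe_invitro`}{An in vitro acylation mixture: free Ade (one
#'     peak) plus a chiral monoacyl species as a 2'/3' pair, with the
#'     acylated fraction set by `acylated_fraction`; optional in-source
#'     fragmentation.}
#'   \item{`enantiomer_panel`}{Three runs (hydroxy acid plus the two
#'     beta2-hydroxy enantiomers) at unequal abundances, one of which
#'     also carries a single-peak diacyl species.}
#'   \item{`diacyl`}{A single-peak diacyl species alongside its
#'     two-peak monoacyl counterpart.}
#'   \item{`metabolism`}{Two monoacyl species at equal molar abundance
#'     but 1.5-fold different ionization response, mirroring a
#'     substrate-metabolism comparison.}
#'   \item{`prochiral`}{A prochiral benzylmalonate monoacyl species
#'     eluting as four diastereomer peaks.}
#' }
#' All scenarios include the Leu-Enk standard (area 1000, RT 4.5 min).
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @param acylated_fraction True acylated fraction for `phe_invitro`.
#' @param fragmentation_fraction In-source fragmentation fraction.
#' @param scale Overall abundance scale.
#' @return A single `synthetic_run_spec`, or a named list of them for
#'   multi-run scenarios.
#' @export
make_parti_fixture <- function(scenario, seed = 1L,
                               acylated_fraction = 0.74,
                               fragmentation_fraction = 0,
                               scale = 2000) {
  reg <- read_monomer_registry()
  std <- analyte(standard_species(), 4.5, abundance = 1000)
  mono <- function(name) compose_species(reg$monomers[[name]], 1L)
  di <- function(name) compose_species(reg$monomers[[name]], 2L)
  ade <- compose_species(NULL, 0L)
  switch(scenario,
    no_substrate = synthetic_run_spec(list(std), seed = seed,
                                      sample = "no_substrate"),
    phe_invitro = {
      stopifnot(acylated_fraction > 0, acylated_fraction < 1)
      synthetic_run_spec(
        list(std,
             analyte(ade, 1.6, abundance = scale * (1 - acylated_fraction)),
             analyte(mono("Phe"), c(2.9, 3.1),
                     abundance = scale * acylated_fraction)),
        fragmentation_fraction = fragmentation_fraction,
        seed = seed, sample = "phe_invitro")
    },
    enantiomer_panel = {
      ab <- c("OH-BocK" = 2.76, "(R)-b2-OH-BocK" = 2.18,
              "(S)-b2-OH-BocK" = 0.20)
      specs <- lapply(seq_along(ab), function(i) {
        name <- names(ab)[i]
        al <- list(std,
                   analyte(mono(name), c(3.0, 3.2), abundance = scale * ab[[i]]))
        if (name == "(R)-b2-OH-BocK")
          al <- c(al, list(analyte(di(name), 3.9,
                                   abundance = scale * 0.1 * ab[[i]])))
        synthetic_run_spec(al, seed = seed + i, sample = name)
      })
      names(specs) <- names(ab)
      specs
    },
    diacyl = synthetic_run_spec(
      list(std,
           analyte(mono("(R)-b2-OH-BocK"), c(3.0, 3.2), abundance = scale),
           analyte(di("(R)-b2-OH-BocK"), 3.9, abundance = 0.2 * scale)),
      seed = seed, sample = "diacyl"),
    metabolism = synthetic_run_spec(
      list(std,
           analyte(mono("BocK"), c(2.9, 3.1), abundance = scale,
                   response = 1.5),
           analyte(mono("N-Me-BocK"), c(3.4, 3.6), abundance = scale,
                   response = 1)),
      seed = seed, sample = "metabolism"),
    prochiral = synthetic_run_spec(
      list(std,
           analyte(mono("m-CF3-bma"), c(2.8, 3.0, 3.2, 3.4),
                   abundance = scale)),
      seed = seed, sample = "prochiral"),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}
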