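# Independent oracles used by the tests; deliberately different code
# paths from the package implementation.

# Brute-force aggregated isotope distribution: for each element,
# enumerate all isotope count vectors of its n atoms (multinomial),
# then combine elements by exhaustive outer product.  Exponential in
# atom count; use only on small compositions.
oracle_isotope_dist <- function(counts, abundances, max_offset = 8L) {
  # abundances: named list, element -> per-offset abundance vector
  el_dist <- lapply(names(counts), function(el) {
    ab <- abundances[[el]]
    n <- counts[[el]]
    k <- length(ab)
    if (k == 1L) return(stats::setNames(1, "0"))
    # all count vectors of n atoms over k isotopes
    grid <- expand.grid(rep(list(0:n), k))
    grid <- grid[rowSums(grid) == n, , drop = FALSE]
    offs <- as.matrix(grid) %*% (seq_len(k) - 1L)
    probs <- apply(grid, 1, function(cv) stats::dmultinom(cv, prob = ab))
    tapply(probs, offs, sum)
  })
  total <- stats::setNames(1, "0")
  for (d in el_dist) {
    new <- numeric(0)
    for (i in names(total)) for (j in names(d)) {
      off <- as.character(as.integer(i) + as.integer(j))
      new[off] <- (if (off %in% names(new)) new[[off]] else 0) +
        total[[i]] * d[[j]]
    }
    total <- new
  }
  out <- numeric(max_offset + 1L)
  for (i in names(total)) {
    off <- as.integer(i)
    if (off <= max_offset) out[off + 1L] <- total[[i]]
  }
  out
}

# IUPAC abundances duplicated here so the oracle does not depend on the
# package's internal tables.
ORACLE_ABUNDANCES <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  Br = c(0.5069, 0, 0.4931)
)

# Gaussian-peak EIC built directly (no simulator): one analyte at a
# fixed m/z, area in intensity-minutes.
gaussian_eic_run <- function(mz0, rts, area, mu, sigma,
                             m1_frac = 0.12, mz_range = c(100, 3000)) {
  spectra <- lapply(rts, function(rt) {
    h <- area * dnorm(rt, mu, sigma)
    spectrum(rt, c(mz0, mz0 + 1.0033548), c(h, h * m1_frac))
  })
  lcms_run(spectra, sample = "toy", rt_window = range(rts),
           mz_range = mz_range)
}

registry <- read_monomer_registry()
mono_species <- function(name) compose_species(registry$monomers[[name]], 1L)
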