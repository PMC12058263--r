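# Elemental-composition arithmetic, species composition, exact masses,
# isotope envelopes, isomer multiplicity.

test_that("composition arithmetic is element-wise, commutative, and guards negatives", {
  a <- composition(C = 2, H = 6, O = 1)
  b <- composition(H = 2, O = 1)
  expect_true((a + b) == (b + a))
  expect_true(((a + b) + b) == (a + (b + b)))
  expect_true((a + b - b) == a)
  expect_true((2 * b) == composition(H = 4, O = 2))
  expect_error(b - a, "negative element count")
  expect_error(composition(Xx = 1), "unknown element")
  expect_error(composition(C = -1), "non-negative")
})

test_that("Hill-notation formulas parse and format round-trip", {
  leu_enk <- parse_formula("C28H37N5O7")
  expect_identical(format(leu_enk), "C28H37N5O7")
  expect_identical(format(parse_formula("BrCH3")), "CH3Br")
  expect_error(parse_formula("C2x"), "cannot parse")
})

test_that("compose_species applies the condensation stoichiometry", {
  ade <- compose_species(NULL, 0)
  expect_true(ade$composition == parse_formula("C10H13N5O4"))

  phe <- monomer("Phe", "C9H11NO2", "amide", "chiral")
  expect_true(compose_species(phe, 1)$composition ==
                parse_formula("C19H22N6O5"))

  bock <- monomer("BocK", "C11H22N2O4", "amide", "chiral")
  expect_true(compose_species(bock, 2)$composition ==
                parse_formula("C32H53N9O10"))

  expect_error(compose_species(phe, 3), "acyl_count")
  expect_error(compose_species(NULL, 1), "monomer")
  # a "monomer" without enough atoms to lose a water is rejected upstream
  expect_error(monomer("bad", "C1O1"), ">= 2 O")
})

test_that("free adenosine [M+H]+ matches independent atomic-mass summation", {
  # independent: sum tabulated atomic masses directly
  ref <- 10 * 12 + 13 * 1.00782503207 + 5 * 14.0030740048 +
    4 * 15.9949146196 + 1.007276
  expect_equal(protonated_mz(compose_species(NULL, 0)), ref, tolerance = 1e-9)
  expect_equal(round(ref, 4), 268.1040)
})

test_that("mass additivity: diacyl minus monoacyl equals monomer minus water", {
  h2o <- monoisotopic_mass(parse_formula("H2O"))
  for (m in registry$monomers) {
    mono <- compose_species(m, 1)
    di <- compose_species(m, 2)
    expect_equal(di$protonated_mz - mono$protonated_mz,
                 monoisotopic_mass(m$composition) - h2o,
                 tolerance = 1e-9, label = m$name)
  }
})

test_that("N-methylation shifts each acyl group by one CH2", {
  bock <- registry$monomers[["BocK"]]
  nme <- registry$monomers[["N-Me-BocK"]]
  ch2 <- 14.01565
  for (k in 1:2) {
    shift <- compose_species(nme, k)$protonated_mz -
      compose_species(bock, k)$protonated_mz
    expect_equal(shift, k * ch2, tolerance = 1e-4 * k)
  }
})

test_that("isotope envelopes match the brute-force multinomial oracle", {
  cases <- list(
    C1 = c(C = 1), H2O = c(H = 2, O = 1),
    glucose = c(C = 6, H = 12, O = 6),
    bromomethane = c(C = 1, H = 3, Br = 1)
  )
  for (nm in names(cases)) {
    comp <- composition(cases[[nm]])
    env <- isotope_envelope(comp, n_peaks = 4)
    ref <- oracle_isotope_dist(as.list(unclass(comp)), ORACLE_ABUNDANCES)
    ref <- ref[1:4] / sum(ref[1:4])
    expect_equal(env$abundance, unname(ref), tolerance = 1e-9, label = nm)
    expect_equal(sum(env$abundance), 1, tolerance = 1e-9)
  }
  # single-atom carbon base case, straight from the IUPAC table
  c1 <- isotope_envelope(composition(C = 1), n_peaks = 2)
  expect_equal(c1$abundance[1], 0.9893, tolerance = 1e-4)
  expect_equal(c1$abundance[2], 0.0107, tolerance = 1e-4)
  # water is almost purely monoisotopic
  expect_gt(isotope_envelope("H2O")$abundance[1], 0.997)
  # adenosine M+1/M ratio
  env <- isotope_envelope(compose_species(NULL, 0)$composition)
  expect_equal(env$abundance[2] / env$abundance[1], 0.125, tolerance = 0.04)
  # composition with no polyisotopic atoms collapses to the offset-0 line
  env_p <- isotope_envelope(composition(P = 1, F = 3))
  expect_equal(env_p$abundance, c(1, 0, 0, 0))
  expect_error(isotope_envelope("H2O", n_peaks = 1), "n_peaks")
})

test_that("expected isomer multiplicities follow acyl count and chirality", {
  ade <- compose_species(NULL, 0)
  expect_equal(unname(expected_isomer_count(ade)), c(1, 1))
  chiral <- compose_species(registry$monomers[["BocK"]], 1)
  expect_equal(unname(expected_isomer_count(chiral)), c(1, 2))
  prochiral <- compose_species(registry$monomers[["m-CF3-bma"]], 1)
  expect_equal(unname(expected_isomer_count(prochiral)), c(1, 4))
  diacyl <- compose_species(registry$monomers[["(R)-b2-OH-BocK"]], 2)
  expect_equal(unname(expected_isomer_count(diacyl)), c(1, 1))
})

test_that("the shipped registry holds the assay's monomers and the standard", {
  expect_setequal(names(registry$monomers),
                  c("Phe", "BocK", "N-Me-BocK", "OH-BocK", "(R)-b2-OH-BocK",
                    "(S)-b2-OH-BocK", "m-Br-Phe", "m-CF3-bma", "m-Br-bma",
                    "m-CH3-bma"))
  expect_named(registry$standards, "Leu-Enk")
  expect_true(registry$standards[["Leu-Enk"]] == parse_formula("C28H37N5O7"))
  pro <- vapply(registry$monomers, function(m) m$chirality == "prochiral",
                logical(1))
  expect_setequal(names(registry$monomers)[pro],
                  c("m-CF3-bma", "m-Br-bma", "m-CH3-bma"))
  expect_true(registry$monomers[["N-Me-BocK"]]$n_alkylated)
})
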