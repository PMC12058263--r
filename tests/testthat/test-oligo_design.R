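# Capture-oligo design: reverse complement, nearest-neighbor Tm,
# brute-force-verified span selection.

test_that("DNA reverse complement of an RNA span is correct and involutive", {
  expect_identical(reverse_complement_dna("ACGU"), "ACGT")
  expect_identical(reverse_complement_dna("GGCAU"), "ATGCC")
  expect_error(reverse_complement_dna("ACGT"), "RNA alphabet")
  # involution up to the U -> T substitution
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
               collapse = "")
    dna <- reverse_complement_dna(s)
    back <- chartr("ACGT", "UGCA", dna)
    back <- paste(rev(strsplit(back, "")[[1]]), collapse = "")
    expect_identical(back, chartr("U", "U", s))
  }
})

test_that("nearest-neighbor Tm matches an independent hand summation", {
  # independent summation over the unified parameter table for
  # 5'-CGTTGAAGGCAT-3' (duplicated here, not read from the package)
  dH_tab <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
              CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
              CC = -8.0)
  dS_tab <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
              CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
              CC = -19.9)
  s <- "CGTTGAAGGCAT"
  b <- strsplit(s, "")[[1]]
  steps <- paste0(b[-length(b)], b[-1])
  dH <- sum(dH_tab[steps]) + 0.1 + 2.3     # GC start, AT end initiation
  dS <- sum(dS_tab[steps]) + (-2.8) + 4.1
  salt <- 0.05
  dS <- dS + 0.368 * (nchar(s) - 1) * log(salt)
  tm_ref <- dH * 1000 / (dS + 1.9872 * log(2.5e-7 / 4)) - 273.15
  expect_equal(predict_tm(s, salt = salt, oligo_conc = 2.5e-7), tm_ref,
               tolerance = 0.5 / abs(tm_ref))
})

test_that("Tm behaves physically: GC-rich melts higher, deterministic", {
  at10 <- strrep("AT", 5)
  gc10 <- strrep("GC", 5)
  expect_lt(predict_tm(at10), predict_tm(gc10))
  expect_identical(predict_tm("ACGTACGTACGT"), predict_tm("ACGTACGTACGT"))
  expect_error(predict_tm("ACGTACG"), "too short")
  expect_error(predict_tm("ACGUACGUACGU"), "DNA alphabet")
})

test_that("candidate enumeration counts spans and respects modifications", {
  trna <- target_trna("toy", strrep("ACGU", 10))  # 40 nt, no mods
  ref_tm <- 50
  des <- design_capture_oligo(trna, ref_tm, length_range = 20,
                              tm_tolerance = Inf)
  expect_equal(nrow(des), 40 - 20 + 1)

  # a modified base inside every window -> no feasible span
  blocked <- target_trna("blocked", strrep("ACGU", 10),
                         modified_positions = c(10, 30))
  expect_error(
    design_capture_oligo(blocked, ref_tm, length_range = 25,
                         tm_tolerance = Inf),
    "no feasible span")
})

test_that("design matches exhaustive brute force on a toy target", {
  set.seed(11)
  seq40 <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
                 collapse = "")
  trna <- target_trna("toy", seq40, modified_positions = 8)
  ref <- capture_oligo(target_trna("ref", strrep("GCAU", 8)), 1, 24)
  des <- design_capture_oligo(trna, ref, length_range = c(20, 24),
                              tm_tolerance = Inf)

  # brute force: every span of every length, skipping position 8
  best <- Inf
  feasible <- 0L
  for (len in 20:24) for (start in 1:(40 - len + 1)) {
    end <- start + len - 1
    if (8 >= start && 8 <= end) next
    feasible <- feasible + 1L
    tm <- predict_tm(reverse_complement_dna(substr(seq40, start, end)))
    best <- min(best, abs(tm - ref$predicted_tm))
  }
  expect_equal(nrow(des), feasible)
  expect_equal(des$delta_tm[1], best, tolerance = 1e-9)
  expect_false(any(des$span_start <= 8 & des$span_end >= 8))

  # every returned oligo satisfies the reverse-complement invariant
  for (i in seq_len(nrow(des))) {
    span <- substr(seq40, des$span_start[i], des$span_end[i])
    expect_identical(des$dna[i], reverse_complement_dna(span))
  }
  # ranking is a deterministic total order
  des2 <- design_capture_oligo(trna, ref, length_range = c(20, 24),
                               tm_tolerance = Inf)
  expect_identical(des[, names(des)], des2[, names(des2)])
})

test_that("modified-base avoidance holds exhaustively on sequences <= 50 nt", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(30:50, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    mods <- sample(n, 2)
    trna <- target_trna("t", s, modified_positions = mods)
    des <- tryCatch(
      design_capture_oligo(trna, 60, length_range = c(10, 14),
                           tm_tolerance = Inf),
      error = function(e) NULL)
    if (is.null(des)) next
    for (m in mods)
      expect_false(any(des$span_start <= m & des$span_end >= m))
  }
})
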