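---
title: "Methods: quantifying acyl-adenosine species from LC-HRMS runs of RNase A-digested tRNA"
author: "partiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying acyl-adenosine species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partiq)
```

## The measurement problem

When an aminoacyl-tRNA synthetase/tRNA pair is expressed in cells with a
candidate substrate, the tRNA population can end up unreacted,
3'-monoacylated, 2'/3'-diacylated, or acylated with a metabolized
derivative of the substrate. PARTI (3-Prime Adenosine-Retaining
aminoacyl-tRNA Isolation) resolves these states by capturing the tRNA
isoacceptor with a biotinylated complementary DNA oligo, digesting with
RNase A — which releases the 3'-terminal adenosine still carrying any
acyl group(s) — and detecting the released small molecules by
LC-HRMS. The exact mass of each acyl-adenosine identifies the monomer
and the acyl count; `partiq` implements everything downstream of the
instrument.

## Exact-mass chemistry

Every analyte is `adenosine + n × monomer − n × H2O` for n in {0, 1, 2}:
each acyl bond is a condensation and loses one water, identically for
amide-forming amino acids and ester-forming hydroxy acids or
malonates (the linkage matters for isomer semantics, not mass).
Monoisotopic masses come from hard-coded IUPAC atomic masses (six or
more decimals) and the proton mass 1.007276 Da; only the singly
protonated ion is considered, since that is the species quantified.
Diacyl species are restricted to homo-diacylation — two copies of the
same monomer — which covers every diacyl product reported for this
chemistry; a request for hetero-diacylation is rejected rather than
silently mis-modeled.

One printed literature value for the N-methylated monoacyl species
appears both as 510.26707 and rounded to 510.2671; we treat the
five-decimal value as canonical and the four-decimal ones as
roundings. Our computed value (510.26707) agrees with both at their
stated precision.

Isotope envelopes are aggregated by nominal mass offset and computed by
convolving per-element isotope distributions, truncating at four
offsets (M to M+3) and renormalizing; species below ~800 Da carry
negligible abundance beyond M+3. The unit tests check this convolution
against an independent brute-force multinomial enumeration.

Expected chromatographic multiplicity follows the chemistry: free
adenosine gives one peak; monoacyl species interconvert between 2'- and
3'-regio-isomers (up to two isobaric peaks; chirality of the monomer
does not change this); prochiral malonates additionally form two
diastereomers per regio-isomer (up to four peaks); diacyl species give
one peak.

## The EIC procedure

Identification and quantification deliberately use different mass
windows:

* **Discovery**, ±100 ppm around the theoretical [M+H]+: wide enough to
  find a peak despite calibration offset.
* **Confirmation**: the intensity-weighted mean centroid m/z at the
  apex spectrum must lie within 5 ppm of theory, and the observed
  M+1/M intensity ratio must match the composition's envelope. The
  envelope score is 1 at exact agreement, falls linearly with the
  fold-deviation of the ratio, and reaches 0 at two-fold; the default
  acceptance threshold is 0.5 (i.e. within ~1.5-fold). Only M+1/M is
  used because higher isotopologues of sub-800 Da species are close to
  noise. The apex-m/z estimator and the envelope tolerance are design
  choices of this package (instrument software does not disclose its
  rules) and are recorded in the peak table so they are auditable.
* **Re-quantification**, ±25 ppm around the *observed* apex centroid:
  quantification re-extracts over the monoisotopic peak actually
  present in the sample; ±25 ppm covers Orbitrap-class centroid jitter
  while excluding interferences that a 100 ppm window admits. If the
  narrow trace is empty the discovery-window area is kept and a
  warning is emitted.

Peak detection takes local maxima above a noise floor of 3× the median
nonzero trace intensity (scale-free and deterministic). Apexes
separated by up to twice the median scan interval are treated as one
peak (the taller apex wins, ties go to the earlier retention time);
this absorbs jitter-split apexes without merging genuinely resolved
isomer pairs, which in this assay elute ~0.2 min apart. Boundaries run
from the apex to the intensity minimum before the neighboring peak (or
trace end), clipped to the first point at or below 1% of the apex;
areas are trapezoidal integrals. Using the regional minimum rather
than the first local uptick keeps boundaries stable under multiplicative
noise.

Acyl-adenosine ions partly fragment to the adenosine ion in the
source, so the free-Ade EIC shows small peaks at the acyl species'
retention times. Any Ade peak whose bounds overlap a validated acyl
peak is flagged and excluded from free-Ade quantification; disabling
the exclusion is supported (and regression-tested) to demonstrate the
bias it reintroduces.

## Quantification

With aliquot volume $a$ (default 20 µl), standard spike $s$ (2 µl) and
recorded leftover supernatant $\ell$:

$$A_{\mathrm{norm}} = \frac{\text{analyte area}}{\text{standard area}}
\cdot \frac{a+s}{a} \cdot \frac{a+\ell}{a}$$

which with the defaults is the familiar (area ratio) × 22/20 ×
(20 + leftover)/20. The volumes are symbolic so other bench volumes can
be used. A species' analyte area is the **sum** of all validated,
non-artifact peaks (never the maximum), and an undetected species
reports exactly 0 rather than missing. A sample whose internal
standard (leucine-enkephalin by default) is not detected is
unquantifiable and fails hard; the pipeline continues with the other
samples and signals partial failure.

Percent acylation has two estimators: the within-sample ratio
$100 \cdot \mathrm{acyl}/(\mathrm{acyl}+\mathrm{Ade})$, and the
control-normalized form
$100 - 100 \cdot A_{\mathrm{norm}}^{\mathrm{Ade}}(\text{sample}) /
A_{\mathrm{norm}}^{\mathrm{Ade}}(\text{control})$, clamped to
[0, 100] with a warning. For intact-tRNA runs the yield is the
major-ion area ratio.

Because ionization efficiency differs between species, cross-species
comparisons use response factors: a species' $A_{\mathrm{norm}}$ from a
calibration reaction divided by an independently measured acylation
yield (e.g. from intact-tRNA MS). Dividing any later
$A_{\mathrm{norm}}$ by the factor puts species on a common
percent-acylation scale.

`compare_conditions()` reports per-group mean and SD, a two-tailed
Welch t-test for two groups (group sizes in this kind of experiment are
2–5 with day-to-day variance shifts, so the unequal-variance form is
the safer default) or a one-way ANOVA for more, with ns/*/**/*** tiers
at 0.05/0.01/0.001. Pairwise contrasts after ANOVA are unadjusted and
labeled as such.

## The synthetic-run generator

`simulate_run()` produces centroided runs with complete ground truth so
that every downstream stage is testable without instrument data. It
emulates: Gaussian chromatographic profiles (default σ = 0.03 min) at
user-set isomer retention times, the 2'/3' area split (default 55:45
for pairs — pairs of similar magnitude, slightly favoring one isomer,
as real traces show), the isotope envelope emitted per scan at
theoretical m/z with ≤2 ppm uniform centroid jitter, per-scan
multiplicative log-normal intensity jitter (σ = 0.05), a low
exponential baseline at each monitored mass, in-source fragmentation
as a co-eluting Ade cluster at a set fraction of each acyl peak, and a
Leu-Enk standard peak. The acquisition defaults (RT 1.4–7 min,
0.01 min scan interval, m/z 100–3000) follow the assay's standard
collection window.

An analyte's `abundance × response` parameterizes the injected
**monoisotopic-line** area, with M+1..M+3 emitted on top at envelope
ratios. This makes the generator's ground truth the same quantity the
workflow integrates (the re-extracted monoisotopic peak), so recovery,
yield and linearity checks compare like with like; the total envelope
area is also recorded.

The generator does **not** model saturation and detector nonlinearity,
retention-time drift between runs, realistic ion (shot-noise)
statistics, co-eluting isobars, or profile-mode peak shapes. Green
tests therefore demonstrate correctness of the computational procedure
under clean, calibrated conditions, not robustness to every instrument
pathology.

All randomness flows from the spec's single seed; identical seeds give
bit-identical runs.

## Capture-oligo design

Capture oligos are DNA reverse complements of a tRNA span.  The
designer enumerates every span in the requested length range that
avoids annotated modified-base positions (modifications can impair
hybridization), scores candidates by |Tm − reference Tm|, and breaks
ties by anticodon proximity (when annotated) and then leftmost span —
a deterministic total order.  Tm comes from the unified
nearest-neighbor DNA/DNA parameter set with the 0.368·N·ln[Na+]
entropic salt correction, at default 50 mM Na+ and 250 nM strands.
DNA/DNA parameters are used as a proxy for the DNA:RNA capture hybrid,
as common design tools do, and the model is recorded in the output.
Published oligo Tm values from proprietary calculators will differ in
absolute terms; the designer's contract is correct relative ranking
under a single stated model, which is what span selection needs.  Span
and oligo length are treated as independent inputs; the designer never
infers one from the other.

## Problem sizes and numerical tolerances

The test and acceptance workloads use runs of ~560 scans (1.4–7 min at
0.01 min) with one to four analytes, which a laptop-class CPU
simulates and quantifies in well under a second per run; dilution
series use five points over a 100× range. At these sizes the pipeline
recovers injected monoisotopic areas within 2%, ratio-strategy percent
acylation within 2 points of truth, response-factor-corrected
abundances within 5%, and end-to-end linearity with R² > 0.99.
Exact-mass computations reproduce eight independent literature
[M+H]+ values within 0.001 Da.

## Known limitations

* Centroid-only: profile-mode mzML is rejected, not centroided.
* No retention-time alignment across runs and no deconvolution of
  co-eluting isobars.
* Quantification is relative (internal-standard normalized), not
  absolute molar.
* Intact-tRNA deconvolution is out of scope; `yield_from_intact_areas()`
  consumes already-integrated major-ion areas.
* Single polarity, MS1 only, [M+H]+ only.
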