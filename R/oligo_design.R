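# Design of biotinylated DNA capture oligonucleotides complementary to
# a target tRNA: avoid modified-base positions, match a reference
# oligo's predicted melting temperature.

#' Target tRNA description
#'
#' @param name tRNA name.
#' @param sequence RNA sequence (ACGU), 5'->3', 1-based positions.
#' @param modified_positions Integer positions carrying modified bases
#'   (e.g. 4-thiouridine, 1-methylpseudouridine) that a capture oligo
#'   must not span, since modifications can impair hybridization.
#' @param anticodon_center Optional 1-based position at the centre of
#'   the anticodon, used as a ranking tie-break.
#' @return A `target_trna`.
#' @export
target_trna <- function(name, sequence, modified_positions = integer(0),
                        anticodon_center = NULL) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!nzchar(sequence)) stop("empty tRNA sequence", call. = FALSE)
  if (grepl("[^ACGU]", sequence))
    stop("tRNA sequence must use the RNA alphabet (ACGU)", call. = FALSE)
  n <- nchar(sequence)
  modified_positions <- as.integer(modified_positions)
  if (length(modified_positions) &&
      (min(modified_positions) < 1L || max(modified_positions) > n))
    stop("modified positions outside [1, ", n, "]", call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 modified_positions = sort(unique(modified_positions)),
                 anticodon_center = anticodon_center),
            class = "target_trna")
}

#' DNA reverse complement of an RNA span
#'
#' @param rna_span RNA sequence (ACGU), 5'->3'.
#' @return DNA reverse complement (ACGT), 5'->3' (A-T pairing with U,
#'   G-C pairing).
#' @examples
#' reverse_complement_dna("GGCAU")  # "ATGCC"
#' @export
reverse_complement_dna <- function(rna_span) {
  s <- toupper(rna_span)
  if (grepl("[^ACGU]", s))
    stop("span must use the RNA alphabet (ACGU)", call. = FALSE)
  comp <- chartr("ACGU", "TGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Unified nearest-neighbor DNA/DNA parameters (SantaLucia 1998).
# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotides.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
.NN_INIT <- list(GC = c(dH = 0.1, dS = -2.8), AT = c(dH = 2.3, dS = 4.1))

#' Nearest-neighbor duplex melting temperature
#'
#' Two-state nearest-neighbor Tm for a DNA/DNA duplex with the unified
#' parameter set (stacking dH/dS per dinucleotide plus terminal AT/GC
#' initiation terms) and an entropic monovalent-salt correction of
#' 0.368 x (pairs) x ln\[Na+\] cal/(mol K).  DNA/DNA parameters are
#' used as a proxy for the DNA:RNA capture hybrid, as standard design
#' tools do.  Tm = 1000 dH / (dS + R ln(C/4)) - 273.15 for
#' non-self-complementary duplexes at total strand concentration C.
#'
#' @param dna DNA sequence (ACGT), length >= 8.
#' @param salt Monovalent-cation concentration, molar Na+ equivalents
#'   (default 0.05).
#' @param oligo_conc Total strand concentration, molar (default 2.5e-7).
#' @return Predicted Tm in degrees Celsius.
#' @export
predict_tm <- function(dna, salt = 0.05, oligo_conc = 2.5e-7) {
  s <- toupper(dna)
  if (grepl("[^ACGT]", s))
    stop("sequence must use the DNA alphabet (ACGT)", call. = FALSE)
  n <- nchar(s)
  if (n < 8L) stop("sequence too short for a stable duplex (< 8 nt)",
                   call. = FALSE)
  stopifnot(salt > 0, oligo_conc > 0)
  b <- strsplit(s, "")[[1]]
  steps <- paste0(b[-n], b[-1L])
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])
  for (term in c(b[1L], b[n])) {
    init <- if (term %in% c("G", "C")) .NN_INIT$GC else .NN_INIT$AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  dS <- dS + 0.368 * (n - 1L) * log(salt)
  R <- 1.9872
  tm_k <- dH * 1000 / (dS + R * log(oligo_conc / 4))
  tm_k - 273.15
}

#' Construct a capture oligo for a tRNA span
#'
#' @param target A [target_trna()].
#' @param span_start,span_end 1-based inclusive span on the tRNA.
#' @param biotin_end `"5prime"` (as used for capture here) or
#'   `"3prime"`.
#' @param salt,oligo_conc Passed to [predict_tm()].
#' @return A `capture_oligo`: DNA sequence (reverse complement of the
#'   span), span, biotin end, predicted Tm.
#' @export
capture_oligo <- function(target, span_start, span_end,
                          biotin_end = "5prime",
                          salt = 0.05, oligo_conc = 2.5e-7) {
  stopifnot(inherits(target, "target_trna"),
            span_start >= 1L, span_end <= nchar(target$sequence),
            span_start <= span_end)
  biotin_end <- match.arg(biotin_end, c("5prime", "3prime"))
  span <- substr(target$sequence, span_start, span_end)
  dna <- reverse_complement_dna(span)
  structure(list(dna = dna, target = target$name,
                 span = c(start = as.integer(span_start),
                          end = as.integer(span_end)),
                 biotin_end = biotin_end,
                 predicted_tm = predict_tm(dna, salt, oligo_conc),
                 tm_model = "nearest-neighbor DNA/DNA (unified), salt-corrected"),
            class = "capture_oligo")
}

#' @export
print.capture_oligo <- function(x, ...) {
  cat(sprintf("<capture_oligo> %s[%d-%d] %s-biotin  Tm %.1f C\n  5'-%s-3'\n",
              x$target, x$span[1], x$span[2], x$biotin_end,
              x$predicted_tm, x$dna))
  invisible(x)
}

#' Design capture oligonucleotides for a target tRNA
#'
#' Enumerates every span of the requested lengths that avoids all
#' modified-base positions, builds the reverse-complement DNA oligo
#' for each, and ranks candidates by |Tm - reference Tm|, breaking
#' ties by proximity to the anticodon centre (when annotated) and then
#' by leftmost span.  Deterministic: identical input yields an
#' identical ranking.
#'
#' @param target A [target_trna()].
#' @param reference A `capture_oligo` (the established oligo whose Tm
#'   is matched) or a numeric reference Tm in Celsius.
#' @param length_range Integer vector `c(min_len, max_len)` (a single
#'   value fixes the length).
#' @param tm_tolerance Keep candidates within this many degrees of the
#'   reference Tm (default 3).
#' @param biotin_end Biotinylated end for all candidates.
#' @param salt,oligo_conc Passed to [predict_tm()].
#' @return Data.frame of candidates (columns `dna`, `span_start`,
#'   `span_end`, `length`, `tm`, `delta_tm`, `biotin_end`), best first;
#'   the `capture_oligo` objects are attached as attribute `oligos`.
#' @export
design_capture_oligo <- function(target, reference, length_range,
                                 tm_tolerance = 3, biotin_end = "5prime",
                                 salt = 0.05, oligo_conc = 2.5e-7) {
  stopifnot(inherits(target, "target_trna"))
  ref_tm <- if (inherits(reference, "capture_oligo"))
    reference$predicted_tm else as.numeric(reference)
  lens <- if (length(length_range) == 1L) length_range
          else seq(min(length_range), max(length_range))
  n <- nchar(target$sequence)
  if (min(lens) > n) stop("length_range infeasible for this sequence",
                          call. = FALSE)
  cand <- list()
  for (len in lens) {
    if (len > n) next
    for (start in seq_len(n - len + 1L)) {
      end <- start + len - 1L
      if (any(target$modified_positions >= start &
              target$modified_positions <= end)) next
      cand[[length(cand) + 1L]] <-
        capture_oligo(target, start, end, biotin_end, salt, oligo_conc)
    }
  }
  if (length(cand) == 0L)
    stop("no feasible span: every window intersects a modified position",
         call. = FALSE)
  tab <- data.frame(
    dna = vapply(cand, `[[`, character(1), "dna"),
    span_start = vapply(cand, function(o) o$span[["start"]], integer(1)),
    span_end = vapply(cand, function(o) o$span[["end"]], integer(1)),
    tm = vapply(cand, `[[`, numeric(1), "predicted_tm"),
    biotin_end = biotin_end)
  tab$length <- tab$span_end - tab$span_start + 1L
  tab$delta_tm <- abs(tab$tm - ref_tm)
  centrality <- if (is.null(target$anticodon_center)) rep(0, nrow(tab))
    else abs((tab$span_start + tab$span_end) / 2 - target$anticodon_center)
  ord <- order(tab$delta_tm, centrality, tab$span_start, tab$length)
  tab <- tab[ord, c("dna", "span_start", "span_end", "length", "tm",
                    "delta_tm", "biotin_end")]
  keep <- tab$delta_tm <= tm_tolerance
  if (!any(keep))
    warning("no candidate within tm_tolerance; returning full ranking",
            call. = FALSE)
  out <- if (any(keep)) tab[keep, , drop = FALSE] else tab
  rownames(out) <- NULL
  attr(out, "oligos") <- cand[ord][if (any(keep)) keep else TRUE]
  attr(out, "reference_tm") <- ref_tm
  attr(out, "tm_model") <- "nearest-neighbor DNA/DNA (unified), salt-corrected"
  out
}
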