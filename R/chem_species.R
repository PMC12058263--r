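# Acyl-adenosine chemistry: monomers, RNase A cleavage products, exact
# masses, isotope envelopes, and expected 2'/3' isomer multiplicities.

# RNase A cleavage of tRNA releases the 3'-terminal adenosine; if the tRNA
# was acylated, the adenosine retains the acyl group(s).  All species are
# therefore adenosine plus n monomer residues (n = 0, 1, 2), each acyl
# bond formed by condensation with loss of one water.
.ADENOSINE <- c(C = 10L, H = 13L, N = 5L, O = 4L)
.WATER <- c(H = 2L, O = 1L)

.LINKAGES <- c("amide", "ester_hydroxy", "ester_malonate")
.CHIRALITY <- c("chiral", "prochiral", "achiral")

#' Define an acyl monomer
#'
#' A monomer is a candidate aminoacyl-tRNA synthetase substrate: an
#' alpha-amino acid (amide-forming), an alpha- or beta2-hydroxy acid
#' (ester-forming), or a 2-substituted malonate (ester-forming,
#' prochiral).  The free-acid elemental composition is supplied; the
#' carboxylate condenses onto the 2'/3'-OH of the tRNA's terminal
#' adenosine with loss of one water.
#'
#' @param name Monomer name.
#' @param formula Hill-notation formula of the free acid, or an
#'   `element_composition`.
#' @param linkage One of `"amide"` (alpha-amino acid),
#'   `"ester_hydroxy"` (alpha-/beta2-hydroxy acid), `"ester_malonate"`.
#' @param chirality One of `"chiral"`, `"prochiral"`, `"achiral"`.
#'   Prochiral monomers (2-benzylmalonates) gain a stereocenter on
#'   acylation, so their monoacyl products are diastereomer mixtures.
#' @param n_alkylated Logical; `TRUE` for N-alkylated amino acids such
#'   as N-methyl amino acids.
#' @return A `monomer` object.
#' @examples
#' monomer("Phe", "C9H11NO2", "amide", "chiral")
#' @export
monomer <- function(name, formula, linkage = "amide",
                    chirality = "chiral", n_alkylated = FALSE) {
  comp <- if (is.character(formula)) parse_formula(formula) else formula
  stopifnot(inherits(comp, "element_composition"))
  linkage <- match.arg(linkage, .LINKAGES)
  chirality <- match.arg(chirality, .CHIRALITY)
  if (is.na(match("C", names(comp))) || comp[["C"]] < 1L ||
      is.na(match("O", names(comp))) || comp[["O"]] < 2L)
    stop("monomer '", name, "' must contain >= 1 C and >= 2 O ",
         "(a carboxylate is required to acylate tRNA)", call. = FALSE)
  structure(
    list(name = name, composition = comp, linkage = linkage,
         chirality = chirality, n_alkylated = isTRUE(n_alkylated)),
    class = "monomer"
  )
}

#' @export
print.monomer <- function(x, ...) {
  cat(sprintf("<monomer> %s  %s  (%s, %s%s)\n", x$name, format(x$composition),
              x$linkage, x$chirality,
              if (x$n_alkylated) ", N-alkylated" else ""))
  invisible(x)
}

#' Read a monomer registry
#'
#' Reads a TSV with columns `name`, `formula`, `linkage`,
#' `chirality_class`, `n_alkylated`.  Rows with linkage `"standard"`
#' are internal standards (e.g. leucine-enkephalin) and are returned as
#' plain composition records rather than monomers.
#'
#' @param path Path to the TSV.  Defaults to the registry shipped with
#'   the package, which holds the assay's monomers plus Leu-Enk.
#' @return Named list with elements `monomers` (list of `monomer`) and
#'   `standards` (named list of `element_composition`).
#' @export
read_monomer_registry <- function(path = system.file("extdata", "monomers.tsv",
                                                     package = "partiq")) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "linkage", "chirality_class", "n_alkylated")
  if (!all(need %in% names(tab)))
    stop("registry must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  std <- tab$linkage == "standard"
  monomers <- lapply(which(!std), function(i)
    monomer(tab$name[i], tab$formula[i], tab$linkage[i],
            tab$chirality_class[i], as.logical(tab$n_alkylated[i])))
  names(monomers) <- tab$name[!std]
  standards <- lapply(which(std), function(i) parse_formula(tab$formula[i]))
  names(standards) <- tab$name[std]
  list(monomers = monomers, standards = standards)
}

#' Compose an acyl-adenosine species
#'
#' Builds the RNase A cleavage product carrying `acyl_count` copies of
#' the monomer: free adenosine (`acyl_count = 0`), the 2'/3' monoacyl
#' adenosine (1), or the 2',3'-diacyl adenosine (2).  Each acyl bond is
#' a condensation, so the composition is
#' adenosine + acyl_count * monomer - acyl_count * H2O; amide and ester
#' linkages lose the same water.  Only homo-diacylation is supported.
#'
#' @param monomer A `monomer`, or `NULL` for free adenosine.
#' @param acyl_count Integer 0, 1 or 2.
#' @return An `acyl_adenosine_species` with fields `monomer`,
#'   `acyl_count`, `composition`, `monoisotopic_mass`, `protonated_mz`,
#'   `label`.
#' @examples
#' bock <- monomer("BocK", "C11H22N2O4", "amide", "chiral")
#' compose_species(bock, 1)$protonated_mz  # 496.2514
#' @export
compose_species <- function(monomer = NULL, acyl_count = 0L) {
  if (!(length(acyl_count) == 1L && acyl_count %in% 0:2))
    stop("acyl_count must be 0, 1 or 2", call. = FALSE)
  acyl_count <- as.integer(acyl_count)
  if (acyl_count > 0L && is.null(monomer))
    stop("a monomer is required when acyl_count > 0", call. = FALSE)
  if (!is.null(monomer)) stopifnot(inherits(monomer, "monomer"))
  comp <- composition(.ADENOSINE)
  if (acyl_count > 0L)
    comp <- comp + acyl_count * monomer$composition -
      acyl_count * composition(.WATER)
  mass <- monoisotopic_mass(comp)
  label <- if (acyl_count == 0L) "Ade"
           else paste0(if (acyl_count == 2L) "di-" else "",
                       monomer$name, "-Ade")
  structure(
    list(monomer = monomer, acyl_count = acyl_count, composition = comp,
         monoisotopic_mass = mass, protonated_mz = mass + PROTON_MASS,
         label = label),
    class = "acyl_adenosine_species"
  )
}

#' @export
print.acyl_adenosine_species <- function(x, ...) {
  cat(sprintf("<species> %s  %s  [M+H]+ = %.5f Da\n",
              x$label, format(x$composition), x$protonated_mz))
  invisible(x)
}

#' Protonated m/z of a species or composition
#'
#' Monoisotopic mass plus the proton mass (1.007276 Da); the assay
#' quantifies singly protonated ions only.
#'
#' @param x An `acyl_adenosine_species`, `element_composition`, or
#'   formula string.
#' @return \[M+H\]+ in Da.
#' @export
protonated_mz <- function(x) {
  if (inherits(x, "acyl_adenosine_species")) return(x$protonated_mz)
  monoisotopic_mass(x) + PROTON_MASS
}

#' Aggregated isotope envelope of a composition
#'
#' Computes the relative abundances of the M, M+1, ... isotopologue
#' peaks (aggregated by nominal mass offset) by convolving the
#' per-element isotope distributions, truncating to `n_peaks` offsets
#' and renormalizing.  Species under ~800 Da are well described by the
#' first four offsets.
#'
#' @param composition An `element_composition` or formula string.
#' @param n_peaks Number of offsets to keep (>= 2).
#' @return An `isotope_envelope`: data.frame with columns `offset` and
#'   `abundance` (summing to 1).
#' @export
isotope_envelope <- function(composition, n_peaks = 4L) {
  if (is.character(composition)) composition <- parse_formula(composition)
  stopifnot(inherits(composition, "element_composition"))
  if (n_peaks < 2L) stop("n_peaks must be >= 2", call. = FALSE)
  # working length: enough offsets that truncation loss is negligible
  len <- as.integer(n_peaks + 6L)
  dist <- c(1, numeric(len - 1L))
  for (el in names(composition)) {
    ab <- .ISOTOPE_ABUNDANCE[[el]]
    if (is.null(ab)) stop("unknown element: ", el, call. = FALSE)
    single <- c(ab, numeric(max(0L, len - length(ab))))[seq_len(len)]
    for (i in seq_len(composition[[el]]))
      dist <- .convolve_trunc(dist, single, len)
  }
  ab <- dist[seq_len(n_peaks)]
  ab <- ab / sum(ab)
  structure(data.frame(offset = seq_len(n_peaks) - 1L, abundance = ab),
            class = c("isotope_envelope", "data.frame"))
}

# linear convolution truncated to the first len coefficients
.convolve_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), len - i + 1L)
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Expected number of EIC peaks for a species
#'
#' Free adenosine elutes as one peak.  Monoacyl adenosines interconvert
#' between the 2'- and 3'-acyl regio-isomers and elute as up to two
#' isobaric peaks for chiral or achiral monomers; prochiral monomers
#' (2-benzylmalonates) additionally form two diastereomers per
#' regio-isomer, so up to four isobaric peaks.  Diacyl adenosines have
#' a single arrangement and elute as one peak.
#'
#' @param species An `acyl_adenosine_species`.
#' @return Integer vector `c(min_peaks, max_peaks)`.
#' @export
expected_isomer_count <- function(species) {
  stopifnot(inherits(species, "acyl_adenosine_species"))
  if (species$acyl_count %in% c(0L, 2L)) return(c(min_peaks = 1L, max_peaks = 1L))
  if (species$monomer$chirality == "prochiral")
    c(min_peaks = 1L, max_peaks = 4L)
  else
    c(min_peaks = 1L, max_peaks = 2L)
}
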