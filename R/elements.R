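# Atomic data: monoisotopic masses (Da) and nominal-offset isotope
# distributions for the elements occurring in the assay's analytes.
# Masses are IUPAC/CODATA values to >= 6 decimal places.

.MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.998403163,
  Na = 22.9897692809,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Br = 78.9183376,
  I  = 126.904473
)

#' @noRd
PROTON_MASS <- 1.007276

# Spacing between successive isotopologue peaks (13C - 12C), used when
# locating the M+1 line of an envelope in observed spectra.
ISOTOPE_SPACING <- 1.0033548

# Relative isotope abundances per element, indexed by nominal mass offset
# (position 1 = offset 0).  Monoisotopic elements carry a single entry.
.ISOTOPE_ABUNDANCE <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  F  = 1,
  Na = 1,
  P  = 1,
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  Cl = c(0.7576, 0, 0.2424),
  K  = c(0.932581, 0.000117, 0.067302),
  Br = c(0.5069, 0, 0.4931),
  I  = 1
)

#' Known chemical elements
#'
#' Element symbols for which `partiq` carries monoisotopic masses and
#' isotope abundances.
#'
#' @return Character vector of element symbols.
#' @export
known_elements <- function() names(.MONOISOTOPIC_MASS)

#' Create an elemental composition
#'
#' An elemental composition is a bag of non-negative integer element
#' counts, the arithmetic substrate for all exact-mass computation in
#' the package.  Compositions support `+`, `-` and integer `*`;
#' subtraction that would drive any count negative is an error (it
#' indicates a malformed monomer, e.g. one that cannot lose a water on
#' condensation).
#'
#' @param ... Named integer counts, e.g. `composition(C = 10, H = 13,
#'   N = 5, O = 4)`, or a single named numeric vector.
#' @return An `element_composition` object.
#' @examples
#' adenosine <- composition(C = 10, H = 13, N = 5, O = 4)
#' water <- composition(H = 2, O = 1)
#' adenosine - water + water
#' @export
composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) {
    return(structure(integer(0), class = "element_composition"))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("composition counts must be named by element symbol", call. = FALSE)
  unknown <- setdiff(names(counts), known_elements())
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers", call. = FALSE)
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0]
  x <- as.integer(counts)
  names(x) <- names(counts)
  x <- x[order(match(names(x), known_elements()))]
  structure(x, class = "element_composition")
}

#' Parse a molecular formula in Hill notation
#'
#' @param formula Character scalar, e.g. `"C9H11NO2"`.
#' @return An `element_composition`.
#' @examples
#' parse_formula("C28H37N5O7")  # leucine-enkephalin
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("\\s", "", formula)
  if (!nzchar(s)) stop("empty formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)
  toks <- regmatches(s, m)[[1]]
  if (sum(nchar(toks)) != nchar(s))
    stop("cannot parse formula: ", formula, call. = FALSE)
  els <- sub("[0-9]*$", "", toks)
  ns <- sub("^[A-Za-z]+", "", toks)
  ns <- ifelse(nzchar(ns), as.integer(ns), 1L)
  names(ns) <- els
  composition(ns)
}

#' @export
Ops.element_composition <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    stopifnot(inherits(e1, "element_composition"),
              inherits(e2, "element_composition"))
    els <- union(names(e1), names(e2))
    a <- b <- stats::setNames(integer(length(els)), els)
    a[names(e1)] <- unclass(e1)
    b[names(e2)] <- unclass(e2)
    out <- if (.Generic == "+") a + b else a - b
    if (any(out < 0))
      stop("negative element count for ",
           paste(els[out < 0], collapse = ", "),
           " after subtraction", call. = FALSE)
    composition(out)
  } else if (.Generic == "*") {
    k <- if (inherits(e1, "element_composition")) e2 else e1
    x <- if (inherits(e1, "element_composition")) e1 else e2
    stopifnot(is.numeric(k), length(k) == 1L, k >= 0, k == round(k))
    composition(unclass(x) * as.integer(k))
  } else if (.Generic == "==") {
    identical(unclass(composition(unclass(e1))), unclass(composition(unclass(e2))))
  } else {
    stop("operation '", .Generic, "' not defined for element compositions",
         call. = FALSE)
  }
}

#' @export
format.element_composition <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  # Hill order: C, H, then alphabetical
  els <- names(x)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(hill, ifelse(x[hill] > 1L, x[hill], ""), collapse = "")
}

#' @export
print.element_composition <- function(x, ...) {
  cat("<composition> ", format(x),
      sprintf("  (monoisotopic %.5f Da)\n", monoisotopic_mass(x)), sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' @param x An `element_composition` (or formula string).
#' @return Mass in Da (sum of the most-abundant-isotope atomic masses).
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  stopifnot(inherits(x, "element_composition"))
  sum(.MONOISOTOPIC_MASS[names(x)] * unclass(x))
}

#' Total atom count of a composition
#' @param x An `element_composition`.
#' @return Integer number of atoms.
#' @export
atom_count <- function(x) {
  stopifnot(inherits(x, "element_composition"))
  sum(unclass(x))
}
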