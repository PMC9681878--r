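# Exact-mass arithmetic for small-molecule (phyto)cannabinoid work.
# All masses are pinned in-source so that theoretical m/z values are
# reproducible without any external lookup.

# Monoisotopic (most abundant isotope) masses, Da.
# D is deuterium, treated as its own "element" for labelled standards.
.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  O = 15.9949146196,
  N = 14.0030740048,
  S = 31.97207100,
  D = 2.0141017778
)

# Electron rest mass, Da.
ELECTRON_MASS <- 0.00054858

# Proton mass (H atom minus one electron), Da.
PROTON_MASS <- 1.00782503207 - 0.00054858

# Per-element isotope tables: mass (Da) and natural abundance (fraction).
# Deuterium-labelled positions are mono-isotopic by construction.
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548378), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.0141017778),
           abundance = c(0.999885, 0.000115)),
  O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
           abundance = c(0.99757, 0.00038, 0.00205)),
  N = list(mass = c(14.0030740048, 15.0001088982),
           abundance = c(0.99636, 0.00364)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  D = list(mass = 2.0141017778, abundance = 1.0)
)

.ELEMENTS <- names(.MONO_MASS)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of element counts over the
#' whitelisted elements C, H, O, N, S and D (deuterium). Formulas can be
#' given as counts (`elemental_formula(C = 21, H = 30, O = 2)`) or parsed
#' from a Hill-notation string with [parse_formula()].
#'
#' @param ... named integer element counts, e.g. `C = 21, H = 30, O = 2`.
#' @return A named integer vector of class `elemental_formula`.
#' @examples
#' elemental_formula(C = 21, H = 30, O = 2)
#' @export
elemental_formula <- function(...) {
  counts <- unlist(list(...))
  if (length(counts) == 0) stop("formula must contain at least one atom")
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("element counts must be named")
  bad <- setdiff(names(counts), .ELEMENTS)
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(counts != round(counts)) || any(counts < 0))
    stop("element counts must be non-negative integers")
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) < 1)
    stop("formula must contain at least one atom")
  ord <- order(match(names(counts), .ELEMENTS))
  out <- as.integer(counts[ord])
  names(out) <- names(counts)[ord]
  structure(out, class = "elemental_formula")
}

#' Parse a Hill-notation formula string
#'
#' @param x a string such as `"C21H30O2"` or `"C21H27D3O2"`.
#' @return An `elemental_formula`.
#' @examples
#' parse_formula("C21H30O2")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(x))
    stop("cannot parse formula string: ", x)
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, el, sum)
  do.call(elemental_formula, as.list(counts))
}

as_formula_counts <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!inherits(formula, "elemental_formula")) {
    if (is.numeric(formula) && !is.null(names(formula)))
      formula <- do.call(elemental_formula, as.list(formula))
    else stop("not an elemental formula")
  }
  formula
}

#' Serialise a formula in Hill notation
#'
#' Carbon first, hydrogen (with deuterium appended after H) second, then
#' remaining elements alphabetically.
#'
#' @param formula an `elemental_formula`, named count vector, or string.
#' @return A single string, e.g. `"C21H30O2"`.
#' @export
format_formula <- function(formula) {
  f <- as_formula_counts(formula)
  v <- as.integer(f); names(v) <- names(f)
  ord <- c("C", "H", "D", sort(setdiff(names(v), c("C", "H", "D"))))
  ord <- ord[ord %in% names(v)]
  paste0(vapply(ord, function(e) {
    n <- v[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a neutral formula
#'
#' Sums the pinned most-abundant-isotope masses (Da) of all atoms.
#'
#' @param formula an `elemental_formula`, named count vector, or string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.0105646
#' monoisotopic_mass("C21H30O2")  # 314.2245802 (CBD)
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula_counts(formula)
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' Rings-plus-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1, with deuterium counted as hydrogen. Half-integer
#' values signal an even-electron ion composition rather than a neutral
#' molecule.
#'
#' @param formula an `elemental_formula`, named count vector, or string.
#' @return RDBE as a double (can be half-integer or negative).
#' @examples
#' rdbe("C21H30O2")  # 7
#' @export
rdbe <- function(formula) {
  f <- as_formula_counts(formula)
  g <- function(e) if (e %in% names(f)) as.numeric(f[[e]]) else 0
  g("C") - (g("H") + g("D")) / 2 + g("N") / 2 + 1
}

#' Relative mass error in parts per million
#'
#' Signed as (observed - theoretical) / theoretical * 1e6, so an observed
#' mass above the theoretical value gives a positive error.
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da), must be > 0.
#' @return Error in ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}
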