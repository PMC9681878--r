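# Adduct handling. An adduct specification records the composition change
# relative to the neutral molecule, the resulting charge, and the atoms the
# neutral must contain for the adduct to be chemically possible (relevant
# for loss adducts such as [M-H2O+H]+).

.ADDUCT_REGISTRY <- list(
  "[M+H]+" = list(
    mass_delta = 1.00782503207, charge = 1L,
    requires = c(H = 0L, O = 0L)
  ),
  "[M-H2O+H]+" = list(
    # lose H2O, gain a proton-carrying H: net -H1 -O1 on composition
    mass_delta = -18.0105646356 + 1.00782503207, charge = 1L,
    requires = c(H = 2L, O = 1L)
  ),
  "[M+Na]+" = list(
    mass_delta = 22.9897692809, charge = 1L,
    requires = c(H = 0L, O = 0L)
  )
)

#' Adduct specification
#'
#' Returns the mass delta (Da, relative to the neutral monoisotopic mass),
#' charge, and composition prerequisites for a named adduct. Known labels:
#' `"[M+H]+"`, `"[M-H2O+H]+"`, `"[M+Na]+"`. A custom adduct can be built by
#' supplying `mass_delta` and `charge` explicitly.
#'
#' @param label adduct label, e.g. `"[M+H]+"`.
#' @param mass_delta optional custom mass delta in Da.
#' @param charge optional custom integer charge (nonzero).
#' @param requires optional named integer vector of minimum atom counts the
#'   neutral formula must contain (used for loss adducts).
#' @return A list of class `adduct_spec` with fields `label`, `mass_delta`,
#'   `charge`, `requires`.
#' @examples
#' adduct_spec("[M+H]+")
#' @export
adduct_spec <- function(label, mass_delta = NULL, charge = NULL,
                        requires = NULL) {
  if (inherits(label, "adduct_spec")) return(label)
  if (is.null(mass_delta)) {
    # normalise spacing variants like "[M + H]+"
    key <- gsub("[[:space:]]", "", label)
    reg <- .ADDUCT_REGISTRY[[key]]
    if (is.null(reg)) stop("unknown adduct label: ", label)
    mass_delta <- reg$mass_delta
    charge <- reg$charge
    requires <- reg$requires
  }
  stopifnot(is.numeric(mass_delta), length(mass_delta) == 1L)
  charge <- as.integer(charge)
  if (is.na(charge) || charge == 0L) stop("adduct charge must be nonzero")
  if (is.null(requires)) requires <- c(H = 0L, O = 0L)
  structure(list(label = label, mass_delta = mass_delta, charge = charge,
                 requires = requires),
            class = "adduct_spec")
}

#' Theoretical m/z of an adduct ion
#'
#' Computes (monoisotopic mass + adduct mass delta - charge * electron mass)
#' / |charge|, i.e. electron-mass corrected.
#'
#' @param neutral neutral `elemental_formula` (or string / named counts).
#' @param adduct an `adduct_spec` or adduct label string.
#' @return m/z in Da.
#' @examples
#' ion_mz("C21H30O2", "[M+H]+")  # 315.2319 at 4 dp (protonated CBD)
#' @export
ion_mz <- function(neutral, adduct = "[M+H]+") {
  f <- as_formula_counts(neutral)
  a <- adduct_spec(adduct)
  req <- a$requires[a$requires > 0]
  if (length(req)) {
    have <- vapply(names(req), function(e)
      if (e %in% names(f)) as.integer(f[[e]]) else 0L, integer(1))
    if (any(have < req))
      stop("adduct ", a$label, " requires atoms the formula ",
           format_formula(f), " does not have")
  }
  (monoisotopic_mass(f) + a$mass_delta - a$charge * ELECTRON_MASS) /
    abs(a$charge)
}
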