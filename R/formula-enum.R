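# CHO(NS) formula enumeration under a ppm tolerance.

#' Default element bounds for formula enumeration
#'
#' C 0-40, H 0-80, O 0-10; N and S disabled by default.
#'
#' @return Named list of `c(min, max)` integer pairs.
#' @export
default_formula_bounds <- function() {
  list(C = c(0L, 40L), H = c(0L, 80L), O = c(0L, 10L))
}

#' Enumerate candidate neutral formulas for an observed ion m/z
#'
#' Finds every neutral formula within the element bounds whose adduct ion
#' m/z lies within `tol_ppm` of the observed value and whose neutral RDBE
#' lies within `rdbe_range`. The search is exhaustive within bounds: C and O
#' (and optionally N, S) are looped and the hydrogen count solved from the
#' residual mass, so no candidate inside the bounds is missed.
#'
#' @param mz observed ion m/z (Da).
#' @param tol_ppm mass tolerance, ppm (>= 0).
#' @param adduct `adduct_spec` or label; default `"[M+H]+"`.
#' @param bounds named list of `c(min,max)` per element, as
#'   [default_formula_bounds()].
#' @param rdbe_range numeric length-2, allowed neutral RDBE range.
#' @return A data.frame with columns `formula` (Hill string), `neutral_mass`,
#'   `ion_mz`, `ppm` — sorted by `abs(ppm)` ascending. Zero rows if nothing
#'   matches.
#' @examples
#' enumerate_formulas(315.2319, tol_ppm = 3)
#' @export
enumerate_formulas <- function(mz, tol_ppm, adduct = "[M+H]+",
                               bounds = default_formula_bounds(),
                               rdbe_range = c(0, 25)) {
  stopifnot(tol_ppm >= 0, length(bounds) > 0, mz > 0)
  a <- adduct_spec(adduct)
  # target neutral monoisotopic mass implied by the observed ion m/z
  target <- mz * abs(a$charge) - a$mass_delta + a$charge * ELECTRON_MASS
  # widened by a fp guard so window pre-selection never drops a boundary
  # candidate that the exact ppm filter below would accept
  tol_da <- mz * tol_ppm * 1e-6 * abs(a$charge) * (1 + 1e-9) + 1e-9

  bnd <- function(e) {
    if (!is.null(bounds[[e]])) as.integer(bounds[[e]]) else c(0L, 0L)
  }
  cb <- bnd("C"); hb <- bnd("H"); ob <- bnd("O")
  nb <- bnd("N"); sb <- bnd("S")

  rows <- list(); k <- 0L
  mh <- .MONO_MASS[["H"]]
  for (nC in cb[1]:cb[2]) {
    for (nO in ob[1]:ob[2]) {
      for (nN in nb[1]:nb[2]) {
        for (nS in sb[1]:sb[2]) {
          base <- nC * .MONO_MASS[["C"]] + nO * .MONO_MASS[["O"]] +
            nN * .MONO_MASS[["N"]] + nS * .MONO_MASS[["S"]]
          resid <- target - base
          # hydrogen counts whose mass falls inside the window
          h_lo <- max(hb[1], as.integer(ceiling((resid - tol_da) / mh)))
          h_hi <- min(hb[2], as.integer(floor((resid + tol_da) / mh)))
          if (h_lo > h_hi) next
          for (nH in h_lo:h_hi) {
            counts <- c(C = nC, H = nH, O = nO, N = nN, S = nS)
            counts <- counts[counts > 0]
            if (length(counts) == 0) next
            f <- do.call(elemental_formula, as.list(counts))
            r <- rdbe(f)
            if (r < rdbe_range[1] || r > rdbe_range[2]) next
            # adduct feasibility (e.g. water loss needs O >= 1)
            imz <- tryCatch(ion_mz(f, a), error = function(e) NA_real_)
            if (is.na(imz)) next
            p <- ppm_error(mz, imz)
            if (abs(p) > tol_ppm + 1e-6) next  # 1e-6 ppm fp guard
            k <- k + 1L
            rows[[k]] <- data.frame(
              formula = format_formula(f),
              neutral_mass = monoisotopic_mass(f),
              ion_mz = imz, ppm = p,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(formula = character(), neutral_mass = double(),
                      ion_mz = double(), ppm = double(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$ppm), out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}
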