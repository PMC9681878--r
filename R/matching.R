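.empty_match_frame <- function() {
  data.frame(abbrev = character(), name = character(),
             level = character(), n_criteria = integer(),
             delta_ppm = double(), delta_rt = double(),
             delta_ccs_pct = double(), isotope_score = double(),
             ms2_score = double(), crit_mass = logical(),
             crit_rt = logical(), crit_isotope = logical(),
             crit_ccs = logical(), crit_ms2 = logical(),
             stringsAsFactors = FALSE)
}

# Five-criterion library matching: retention time, exact mass, isotopic
# pattern, collisional cross section, and MS2 fragmentation. A feature is
# "validated" only when all five criteria pass against a reference entry;
# a partial match is "putative".

#' Percent CCS deviation
#'
#' Absolute deviation of a measured collisional cross section from the
#' reference value, as a percentage of the reference (reference in the
#' denominator, so the comparison is not symmetric).
#'
#' @param measured,reference CCS values in A^2 (> 0).
#' @return Deviation in percent (>= 0).
#' @examples
#' delta_ccs_pct(184.9, 186.0)  # 0.5914
#' @export
delta_ccs_pct <- function(measured, reference) {
  stopifnot(all(measured > 0), all(reference > 0))
  abs(measured - reference) / reference * 100
}

#' Modified cosine similarity of two MS2 spectra
#'
#' Peaks are matched greedily by nearest m/z within `frag_tol`; the score is
#' the cosine of the two intensity vectors over the union of matched and
#' unmatched peaks (unmatched peaks contribute zero on the other side).
#' Symmetric; 1 for identical spectra; 0 when no peaks match.
#'
#' @param a,b `ms2_spectrum` objects.
#' @param frag_tol fragment m/z tolerance in Da (default 0.01).
#' @return Similarity in `[0, 1]`.
#' @export
ms2_cosine <- function(a, b, frag_tol = 0.01) {
  stopifnot(nrow(a$peaks) > 0, nrow(b$peaks) > 0)
  pairs <- .match_peaks(a$peaks$mz, b$peaks$mz, frag_tol)
  if (!length(pairs$i)) return(0)
  ua <- setdiff(seq_len(nrow(a$peaks)), pairs$i)
  ub <- setdiff(seq_len(nrow(b$peaks)), pairs$j)
  va <- c(a$peaks$intensity[pairs$i], a$peaks$intensity[ua],
          rep(0, length(ub)))
  vb <- c(b$peaks$intensity[pairs$j], rep(0, length(ua)),
          b$peaks$intensity[ub])
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Matching tolerances for the five identification criteria
#'
#' Defaults: |mass error| <= 5 ppm, |RT difference| <= 0.2 min,
#' CCS deviation <= 2 %, isotope similarity >= 0.8, MS2 cosine >= 0.7
#' (fragment tolerance 0.01 Da).
#'
#' @param mass_ppm,rt_min,ccs_pct,isotope_min,ms2_min,frag_tol_da thresholds.
#' @return A list of class `match_tolerances`.
#' @export
match_tolerances <- function(mass_ppm = 5, rt_min = 0.2, ccs_pct = 2,
                             isotope_min = 0.8, ms2_min = 0.7,
                             frag_tol_da = 0.01) {
  stopifnot(mass_ppm > 0, rt_min > 0, ccs_pct > 0,
            isotope_min > 0, ms2_min > 0, frag_tol_da > 0)
  structure(list(mass_ppm = mass_ppm, rt_min = rt_min, ccs_pct = ccs_pct,
                 isotope_min = isotope_min, ms2_min = ms2_min,
                 frag_tol_da = frag_tol_da),
            class = "match_tolerances")
}

#' Match one feature against a spectral library
#'
#' Every library entry within the mass tolerance is scored on all five
#' criteria; entries failing the mass criterion are excluded entirely.
#' A feature without a measured CCS fails the CCS criterion, without an
#' observed isotope pattern fails the isotope criterion, and without an MS2
#' spectrum fails the MS2 criterion (absent evidence is a failed criterion,
#' not a skipped one). The identification level is `"validated"` when all
#' five criteria pass, `"putative"` when the mass criterion plus at least
#' one other passes, otherwise `"none"`.
#'
#' @param feature one-row `feature_table` (or a list with fields `mz`,
#'   `rt_min`, `ccs_A2`).
#' @param library named list of `library_entry` (non-empty).
#' @param ms2 optional `ms2_spectrum` observed for the feature.
#' @param isotopes optional observed `isotope_pattern` for the feature.
#' @param tolerances a [match_tolerances()] object.
#' @return data.frame with one row per candidate, columns `abbrev`, `name`,
#'   `level`, `n_criteria`, `delta_ppm`, `delta_rt`, `delta_ccs_pct`,
#'   `isotope_score`, `ms2_score` and the five logical criteria columns
#'   `crit_mass`, `crit_rt`, `crit_isotope`, `crit_ccs`, `crit_ms2` —
#'   ranked by criteria passed (desc), then |delta_ppm|, then |delta_rt|.
#' @export
match_feature <- function(feature, library, ms2 = NULL, isotopes = NULL,
                          tolerances = match_tolerances()) {
  if (length(library) == 0) stop("library is empty")
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1)
    feature <- as.list(feature)
  }
  tol <- tolerances
  rows <- list(); k <- 0L
  for (e in library) {
    dppm <- ppm_error(feature$mz, e$mz)
    if (abs(dppm) > tol$mass_ppm) next   # mass gate: hard exclusion
    drt <- feature$rt_min - e$rt
    crit_rt <- abs(drt) <= tol$rt_min
    if (!is.null(feature$ccs_A2) && !is.na(feature$ccs_A2)) {
      dccs <- delta_ccs_pct(feature$ccs_A2, e$ccs)
      crit_ccs <- dccs <= tol$ccs_pct
    } else { dccs <- NA_real_; crit_ccs <- FALSE }
    if (!is.null(isotopes) && nrow(isotopes) > 0) {
      iso <- isotope_similarity(isotopes,
                                isotope_pattern(e$neutral_formula))
      crit_iso <- iso >= tol$isotope_min
    } else { iso <- NA_real_; crit_iso <- FALSE }
    if (!is.null(ms2) && !is.null(e$ms2)) {
      m2 <- ms2_cosine(ms2, e$ms2, tol$frag_tol_da)
      crit_ms2 <- m2 >= tol$ms2_min
    } else { m2 <- NA_real_; crit_ms2 <- FALSE }
    n_crit <- 1L + crit_rt + crit_iso + crit_ccs + crit_ms2
    level <- if (n_crit == 5L) "validated"
             else if (n_crit >= 2L) "putative"
             else "none"
    k <- k + 1L
    rows[[k]] <- data.frame(
      abbrev = e$abbreviation, name = e$name, level = level,
      n_criteria = n_crit, delta_ppm = dppm, delta_rt = drt,
      delta_ccs_pct = dccs, isotope_score = iso, ms2_score = m2,
      crit_mass = TRUE, crit_rt = crit_rt, crit_isotope = crit_iso,
      crit_ccs = crit_ccs, crit_ms2 = crit_ms2,
      stringsAsFactors = FALSE)
  }
  if (k == 0L) return(.empty_match_frame())
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_criteria, abs(out$delta_ppm), abs(out$delta_rt)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
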