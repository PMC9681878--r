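# Rule-based classification of unidentified features into degradation-
# product classes. The rules mirror how cannabinoid oxidation products are
# recognised from untargeted data: a diagnostic fragment fixes the core
# (the olivetol ion marks a CBD-type core; the 205/135 pair marks a
# CBE-type core), the formula delta relative to the core parent fixes the
# oxidation level (+O hydroxy, +2O dihydroxy, +O-2H quinone), and earlier
# elution than the parent supports hydroxylation (more polar compounds
# elute earlier on a reversed-phase column).

#' Diagnostic fragment rules
#'
#' Published diagnostic ions: the olivetol moiety ion m/z 193.1228
#' (CBD-type core), the pair m/z 205.1224 + m/z 135.0442 (CBE-type core;
#' also quoted as 205.1227 / 135.0448, both inside the default tolerance),
#' and the homologated olivetol-type ion m/z 207.1379 (CBDH/CBDM family).
#' The per-fragment match tolerance is `max(tol_da, tol_ppm * mz * 1e-6)`,
#' wide enough to absorb the spread in the quoted diagnostic masses.
#'
#' @param tol_da absolute fragment tolerance floor in Da (default 0.005).
#' @param tol_ppm relative fragment tolerance in ppm (default 10).
#' @return A list of class `diagnostic_rules`.
#' @export
diagnostic_rules <- function(tol_da = 0.005, tol_ppm = 10) {
  structure(list(
    # checked in order; the more specific fragment sets come first so a
    # CBDH-family spectrum (which also shows the olivetol ion) is not
    # swallowed by the CBD-core rule
    cores = list(
      `CBE-core` = list(required = c(205.1224, 135.0448), parent = "CBE"),
      `CBDH-core` = list(required = c(207.1379), parent = "CBDH"),
      `CBD-core` = list(required = c(193.1228), parent = "CBD")
    ),
    tol_da = tol_da, tol_ppm = tol_ppm),
    class = "diagnostic_rules")
}

.frag_present <- function(peaks, target, tol_da, tol_ppm) {
  tol <- max(tol_da, tol_ppm * target * 1e-6)
  any(abs(peaks$mz - target) <= tol)
}

# mass deltas (Da) between oxidation levels, on the ion m/z scale (adduct
# unchanged, so the neutral delta equals the ion delta)
.DELTA_O <- 15.9949146196
.DELTA_H2 <- 2 * 1.00782503207

.match_delta <- function(dmz, target, mz, tol_ppm = 5) {
  abs(dmz - target) <= mz * tol_ppm * 1e-6 * 2
}

#' Classify an unidentified feature
#'
#' Rules are applied in fixed order: (1) a feature linked as an in-source
#' fragmentation child is labelled `in-source-artifact` and never given a
#' chemical class; (2) composition-only rules: ion composition equal to the
#' HU-331 ion (parent + O - 2H relative to CBD) at a retention time far
#' from the HU-331 reference entry gives `HU-331-like`; (3) a diagnostic
#' fragment fixes the core, and the m/z delta against the core parent fixes
#' the oxidation level (+O hydroxy, +2O dihydroxy, 0 isomer); (4) a
#' hydroxylated label additionally requires elution at least `rt_margin`
#' minutes before the parent, otherwise confidence drops to `"low"`.
#' A hydroxylation label is only emitted when the implied neutral formula
#' is among the formula candidates for the feature m/z at 5 ppm.
#'
#' @param feature one-row `feature_table` or list with `feature_id`, `mz`,
#'   `rt_min`.
#' @param ms2 optional `ms2_spectrum` for the feature.
#' @param artifacts optional artifact-link data.frame from
#'   [detect_insource_artifacts()].
#' @param parents named list of `library_entry` reference compounds; must
#'   contain the core parents (CBD, CBE, CBDH, CBDM, HU-331).
#' @param rules a [diagnostic_rules()] object.
#' @param rt_margin minutes a hydroxylated product must elute before its
#'   parent for high confidence (default 0.3).
#' @param rt_far minutes from a reference entry beyond which an isomer is
#'   considered a distinct compound (default 0.5).
#' @return A list of class `classified_unknown` with fields `feature_id`,
#'   `label`, `parent_compound`, `evidence` (character vector),
#'   `confidence` (`"high"`/`"low"`).
#' @export
classify_unknown <- function(feature, ms2 = NULL, artifacts = NULL,
                             parents = default_library(),
                             rules = diagnostic_rules(),
                             rt_margin = 0.3, rt_far = 0.5) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1)
    feature <- as.list(feature)
  }
  need <- c("CBD", "CBE", "CBDH", "CBDM", "HU-331")
  miss <- setdiff(need, names(parents))
  if (length(miss))
    stop("reference set lacks parent compound(s): ",
         paste(miss, collapse = ", "))

  res <- function(label, parent = NA_character_, evidence = character(),
                  confidence = "high") {
    structure(list(feature_id = feature$feature_id, label = label,
                   parent_compound = parent, evidence = evidence,
                   confidence = confidence),
              class = "classified_unknown")
  }

  # (1) in-source artifact children are artifacts, never compounds
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    hits <- artifacts[artifacts$child_id == feature$feature_id, ,
                      drop = FALSE]
    if (nrow(hits) > 0) {
      ev <- sprintf("in-source %s loss child of %s (rt_delta %.3f min)",
                    hits$loss_name, hits$parent_id, hits$rt_delta)
      if (nrow(hits) > 1) ev <- c(ev, "ambiguous artifact: multiple parents")
      return(res("in-source-artifact",
                 parent = paste(unique(hits$parent_id), collapse = ";"),
                 evidence = ev))
    }
  }
  if (is.null(ms2)) return(res("unclassified"))

  mz <- feature$mz; rt <- feature$rt_min

  # (2) composition-only quinone rule: CBD + O - 2H at RT away from HU-331
  hu <- parents[["HU-331"]]
  dppm_hu <- ppm_error(mz, hu$mz)
  if (abs(dppm_hu) <= 5 && abs(rt - hu$rt) > rt_far) {
    return(res("HU-331-like", parent = "CBD",
               evidence = c(sprintf(
                 "ion composition matches CBD + O - 2H (%.1f ppm)", dppm_hu),
                 sprintf("RT %.2f far from HU-331 reference %.2f", rt,
                         hu$rt))))
  }

  # (3) core from diagnostic fragments
  core <- NULL
  for (nm in names(rules$cores)) {
    cr <- rules$cores[[nm]]
    ok <- all(vapply(cr$required, function(t)
      .frag_present(ms2$peaks, t, rules$tol_da, rules$tol_ppm), logical(1)))
    if (ok) { core <- nm; break }
  }
  if (is.null(core)) return(res("unclassified"))

  parent_ab <- rules$cores[[core]]$parent
  parent <- parents[[parent_ab]]
  frag_ev <- sprintf("diagnostic fragment(s) %s matched (%s)",
                     paste(sprintf("%.4f", rules$cores[[core]]$required),
                           collapse = ", "), core)
  dmz <- mz - parent$mz

  implied_ok <- function(extraO, lessH = 0L) {
    f <- as.integer(parent$neutral_formula)
    names(f) <- names(parent$neutral_formula)
    f[["O"]] <- if ("O" %in% names(f)) f[["O"]] + extraO else extraO
    f[["H"]] <- f[["H"]] - lessH
    cand <- enumerate_formulas(mz, tol_ppm = 5, adduct = parent$adduct)
    target <- format_formula(do.call(elemental_formula, as.list(f)))
    target %in% cand$formula
  }
  rt_check <- function(label) {
    if (rt < parent$rt - rt_margin) {
      list(conf = "high",
           ev = sprintf("RT %.2f < parent %s RT %.2f - %.1f margin",
                        rt, parent_ab, parent$rt, rt_margin))
    } else {
      list(conf = "low",
           ev = sprintf(
             "RT %.2f not earlier than parent %s RT %.2f - %.1f margin",
             rt, parent_ab, parent$rt, rt_margin))
    }
  }

  if (.match_delta(dmz, .DELTA_O, mz)) {            # +O: hydroxylation
    if (!implied_ok(1L)) return(res("unclassified"))
    chk <- rt_check("OH")
    label <- if (core == "CBE-core") "OH-CBE" else "OH-CBD"
    return(res(label, parent = parent_ab,
               evidence = c(frag_ev, "composition delta +O", chk$ev),
               confidence = chk$conf))
  }
  if (.match_delta(dmz, 2 * .DELTA_O, mz)) {        # +2O: dihydroxylation
    if (!implied_ok(2L)) return(res("unclassified"))
    chk <- rt_check("diOH")
    label <- if (core == "CBE-core") "diOH-CBE" else "diOH-CBD"
    return(res(label, parent = parent_ab,
               evidence = c(frag_ev, "composition delta +2O", chk$ev),
               confidence = chk$conf))
  }
  if (.match_delta(dmz, 0, mz)) {                   # same composition: isomer
    if (core == "CBE-core" && abs(rt - parent$rt) > rt_far) {
      return(res("CBE-isomer", parent = "CBE",
                 evidence = c(frag_ev,
                              sprintf("same composition as CBE, RT %.2f vs %.2f",
                                      rt, parent$rt))))
    }
  }
  # CBDH-family isomer: same composition as CBDH/CBDM/THCH but distinct RT
  if (core == "CBDH-core") {
    fam <- parents[names(parents) %in% c("CBDH", "CBDM", "D9-THCH")]
    same_comp <- any(vapply(fam, function(e) abs(ppm_error(mz, e$mz)) <= 5,
                            logical(1)))
    rt_distinct <- all(vapply(fam, function(e) abs(rt - e$rt) > rt_far,
                              logical(1)))
    if (same_comp && rt_distinct) {
      return(res("CBDH-isomer", parent = "CBDH",
                 evidence = c(frag_ev,
                              "CBDH-family composition at distinct RT")))
    }
  }
  res("unclassified")
}

#' Distinguish cannabielsoin from its stereoisomer by pseudo-MS3
#'
#' The two stereoisomers fragment the in-source water-loss ion
#' `[M-H2O+H]+` (m/z ~313.216) differently: the intensity ratio of the ions
#' at m/z 245.1540 and m/z 231.1378 separates them. Which direction of the
#' ratio corresponds to which stereoisomer is configurable metadata
#' (`orientation`), since it is an instrument-calibrated convention rather
#' than a derivable fact.
#'
#' @param pseudo_ms3 `ms2_spectrum` of the water-loss ion.
#' @param threshold ratio threshold (default 2): `ratio > threshold` gives
#'   the `orientation["high"]` class, `ratio < 1/threshold` the
#'   `orientation["low"]` class, otherwise indeterminate.
#' @param orientation named character vector with elements `high` and `low`.
#' @param tol_da,tol_ppm fragment tolerance (as in [diagnostic_rules()]).
#' @return List with `class` (`"CBE"`, `"CBE-isomer"` or `"indeterminate"`)
#'   and `ratio` (I245/I231; `NA` when neither diagnostic ion is present).
#' @export
distinguish_cbe_stereoisomer <- function(pseudo_ms3, threshold = 2,
                                         orientation = c(high = "CBE",
                                                         low = "CBE-isomer"),
                                         tol_da = 0.005, tol_ppm = 10) {
  stopifnot(threshold > 1, all(c("high", "low") %in% names(orientation)))
  grab <- function(target) {
    tol <- max(tol_da, tol_ppm * target * 1e-6)
    sel <- abs(pseudo_ms3$peaks$mz - target) <= tol
    if (!any(sel)) return(0)
    sum(pseudo_ms3$peaks$intensity[sel])
  }
  i245 <- grab(245.1540)
  i231 <- grab(231.1378)
  if (i245 == 0 && i231 == 0)
    return(list(class = "indeterminate", ratio = NA_real_))
  ratio <- if (i231 == 0) Inf else i245 / i231
  cls <- if (ratio > threshold) unname(orientation[["high"]])
         else if (ratio < 1 / threshold) unname(orientation[["low"]])
         else "indeterminate"
  list(class = cls, ratio = ratio)
}

#' Summarise an oxidation series for one parent compound
#'
#' Groups classified unknowns by (core parent, oxidation level), counts
#' members per level, and checks the reversed-phase elution ordering
#' expected for increasing hydroxylation: every dihydroxylated member
#' elutes before every monohydroxylated member, which elutes before the
#' parent.
#'
#' @param classified list of `classified_unknown`, or a data.frame with
#'   columns `feature_id`, `label`, `rt_min`.
#' @param parent parent `library_entry` (e.g. the CBD entry).
#' @return List with `parent`, `counts` (named integer per label) and
#'   `rt_ordering_ok` (logical; `NA` when no hydroxylated members exist).
#' @export
oxidation_series <- function(classified, parent) {
  if (is.data.frame(classified)) {
    df <- classified
  } else {
    df <- data.frame(
      feature_id = vapply(classified, `[[`, "", "feature_id"),
      label = vapply(classified, `[[`, "", "label"),
      rt_min = vapply(classified, function(x)
        if (!is.null(x$rt_min)) x$rt_min else NA_real_, 0),
      parent_compound = vapply(classified, `[[`, "", "parent_compound"),
      stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0)
    return(list(parent = parent$abbreviation, counts = integer(),
                rt_ordering_ok = NA))
  if ("parent_compound" %in% names(df))
    df <- df[!is.na(df$parent_compound) &
               df$parent_compound == parent$abbreviation, , drop = FALSE]
  counts <- table(df$label)
  oh <- df$rt_min[grepl("^OH-", df$label)]
  dioh <- df$rt_min[grepl("^diOH-", df$label)]
  ordering <- NA
  if (length(oh) || length(dioh)) {
    ordering <- TRUE
    if (length(oh)) ordering <- ordering && all(oh < parent$rt)
    if (length(dioh)) ordering <- ordering && all(dioh < parent$rt)
    if (length(oh) && length(dioh))
      ordering <- ordering && max(dioh) < min(oh)
  }
  list(parent = parent$abbreviation,
       counts = stats::setNames(as.integer(counts), names(counts)),
       rt_ordering_ok = ordering)
}
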