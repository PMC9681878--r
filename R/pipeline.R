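# Orchestration: artifact detection -> isotope-companion folding ->
# five-criterion library matching -> rule-based classification of the
# remainder -> trend statistics and source verdict.

# cached theoretical isotope patterns, keyed by Hill formula string
.iso_cache <- new.env(parent = emptyenv())
.cached_pattern <- function(formula) {
  key <- format_formula(formula)
  if (is.null(.iso_cache[[key]]))
    .iso_cache[[key]] <- isotope_pattern(formula)
  .iso_cache[[key]]
}

# shift a pattern so its base peak sits at m/z offset 0, making observed
# (ion) and theoretical (neutral) envelopes comparable by shape
.rel_pattern <- function(p) {
  base <- which.max(p$rel_abundance)
  data.frame(mz = p$mz - p$mz[base], rel_abundance = p$rel_abundance)
}

# identify M+1 isotope companions: a feature whose m/z sits one 13C spacing
# above a co-eluting, more intense feature
.find_isotope_companions <- function(features, mz_tol = 0.01,
                                     rt_tol = 0.03) {
  n <- nrow(features)
  is_iso <- logical(n)
  parent_of <- rep(NA_integer_, n)
  spacing <- 1.0033548378
  for (i in seq_len(n)) {
    d <- features$mz[i] - features$mz - spacing
    cand <- which(abs(d) <= mz_tol &
                    abs(features$rt_min[i] - features$rt_min) <= rt_tol &
                    features$intensity > features$intensity[i])
    if (length(cand)) {
      is_iso[i] <- TRUE
      parent_of[i] <- cand[which.max(features$intensity[cand])]
    }
  }
  list(is_iso = is_iso, parent_of = parent_of)
}

#' Annotate the features of one sample
#'
#' Runs the full identification flow on a single sample's feature table:
#' in-source artifact detection, isotope-companion folding (an M+1 feature
#' is attached to its parent's observed isotope pattern and not annotated
#' as a compound), five-criterion library matching, and rule-based
#' classification of features without a validated match.
#'
#' @param features `feature_table` for one sample.
#' @param ms2 named list of `ms2_spectrum` (names matched to `ms2_ref`).
#' @param library named list of `library_entry`.
#' @param tolerances a [match_tolerances()].
#' @param rules a [diagnostic_rules()].
#' @param loss_list named neutral losses for artifact detection.
#' @return The feature table with appended columns `role`
#'   (`analyte`/`isotope`/`artifact`), `compound`, `match_level`,
#'   `confidence`, `evidence`.
#' @export
annotate_sample <- function(features, ms2 = list(),
                            library = default_library(),
                            tolerances = match_tolerances(),
                            rules = diagnostic_rules(),
                            loss_list = c(H2O = 18.0105646)) {
  features <- validate_feature_table(as.data.frame(features))
  n <- nrow(features)
  out <- features
  out$role <- rep("analyte", n)
  out$compound <- rep(NA_character_, n)
  out$match_level <- rep("none", n)
  out$confidence <- rep(NA_character_, n)
  out$evidence <- rep("", n)
  if (n == 0) return(out)

  artifacts <- detect_insource_artifacts(features, losses = loss_list)
  iso <- .find_isotope_companions(features)
  out$role[iso$is_iso] <- "isotope"
  out$role[features$feature_id %in% artifacts$child_id] <- "artifact"

  for (i in seq_len(n)) {
    if (iso$is_iso[i]) {
      out$compound[i] <- "isotope"
      out$evidence[i] <- paste0("M+1 companion of ",
                                features$feature_id[iso$parent_of[i]])
      next
    }
    fid <- features$feature_id[i]
    spec <- NULL
    if (!is.na(features$ms2_ref[i]) && features$ms2_ref[i] %in% names(ms2))
      spec <- ms2[[features$ms2_ref[i]]]

    if (fid %in% artifacts$child_id) {
      cls <- classify_unknown(features[i, ], ms2 = spec,
                              artifacts = artifacts, parents = library,
                              rules = rules)
      out$compound[i] <- cls$label
      out$confidence[i] <- cls$confidence
      out$evidence[i] <- paste(cls$evidence, collapse = "; ")
      next
    }

    # observed isotope envelope: the feature plus its M+1 companions
    kids <- which(iso$parent_of == i)
    obs_iso <- NULL
    if (length(kids)) {
      obs_iso <- data.frame(
        mz = c(features$mz[i], features$mz[kids]),
        rel_abundance = c(1, features$intensity[kids] /
                            features$intensity[i]))
      obs_iso <- .rel_pattern(obs_iso[order(obs_iso$mz), ])
    }

    matches <- match_feature_shape(features[i, ], library, ms2 = spec,
                                   isotopes = obs_iso,
                                   tolerances = tolerances)
    if (nrow(matches) && matches$level[1] == "validated") {
      out$compound[i] <- matches$abbrev[1]
      out$match_level[i] <- "validated"
      out$confidence[i] <- "high"
      out$evidence[i] <- sprintf(
        "library match %s: %.2f ppm, dRT %.3f, dCCS %.2f%%",
        matches$abbrev[1], matches$delta_ppm[1], matches$delta_rt[1],
        matches$delta_ccs_pct[1])
      next
    }
    cls <- classify_unknown(features[i, ], ms2 = spec,
                            artifacts = artifacts, parents = library,
                            rules = rules)
    out$compound[i] <- cls$label
    out$match_level[i] <- if (nrow(matches)) matches$level[1] else "none"
    out$confidence[i] <- cls$confidence
    out$evidence[i] <- paste(cls$evidence, collapse = "; ")
  }
  out
}

#' Library matching with shape-aligned isotope envelopes
#'
#' Identical to [match_feature()] except that the observed isotope pattern
#' is compared to theory after shifting both envelopes so their base peaks
#' coincide: the observed envelope is on the ion m/z scale while the
#' theoretical one is computed from the neutral formula, and the criterion
#' scores envelope shape, not absolute mass (which the mass criterion
#' already scores).
#'
#' @inheritParams match_feature
#' @return As [match_feature()].
#' @export
match_feature_shape <- function(feature, library, ms2 = NULL,
                                isotopes = NULL,
                                tolerances = match_tolerances()) {
  lib2 <- library
  if (!is.null(isotopes)) {
    isotopes <- .rel_pattern(isotopes)
    # pre-shift cached theoretical patterns by swapping them in
    for (k in seq_along(lib2)) {
      pat <- .rel_pattern(.cached_pattern(lib2[[k]]$neutral_formula))
      attr(lib2[[k]], "rel_pattern") <- pat
    }
  }
  if (length(lib2) == 0) stop("library is empty")
  if (is.data.frame(feature)) feature <- as.list(feature)
  tol <- tolerances
  rows <- list(); k <- 0L
  for (e in lib2) {
    dppm <- ppm_error(feature$mz, e$mz)
    if (abs(dppm) > tol$mass_ppm) next
    drt <- feature$rt_min - e$rt
    crit_rt <- abs(drt) <= tol$rt_min
    if (!is.null(feature$ccs_A2) && !is.na(feature$ccs_A2)) {
      dccs <- delta_ccs_pct(feature$ccs_A2, e$ccs)
      crit_ccs <- dccs <= tol$ccs_pct
    } else { dccs <- NA_real_; crit_ccs <- FALSE }
    if (!is.null(isotopes)) {
      iso_score <- isotope_similarity(isotopes, attr(e, "rel_pattern"))
      crit_iso <- iso_score >= tol$isotope_min
    } else { iso_score <- NA_real_; crit_iso <- FALSE }
    if (!is.null(ms2) && !is.null(e$ms2)) {
      m2 <- ms2_cosine(ms2, e$ms2, tol$frag_tol_da)
      crit_ms2 <- m2 >= tol$ms2_min
    } else { m2 <- NA_real_; crit_ms2 <- FALSE }
    n_crit <- 1L + crit_rt + crit_iso + crit_ccs + crit_ms2
    level <- if (n_crit == 5L) "validated"
             else if (n_crit >= 2L) "putative" else "none"
    k <- k + 1L
    rows[[k]] <- data.frame(
      abbrev = e$abbreviation, name = e$name, level = level,
      n_criteria = n_crit, delta_ppm = dppm, delta_rt = drt,
      delta_ccs_pct = dccs, isotope_score = iso_score, ms2_score = m2,
      crit_mass = TRUE, crit_rt = crit_rt, crit_isotope = crit_iso,
      crit_ccs = crit_ccs, crit_ms2 = crit_ms2, stringsAsFactors = FALSE)
  }
  if (k == 0L) return(.empty_match_frame())
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_criteria, abs(out$delta_ppm), abs(out$delta_rt)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a multi-sample feature table
#'
#' @param features `feature_table` covering one or more samples.
#' @param ms2 named list of `ms2_spectrum`.
#' @param ... passed to [annotate_sample()].
#' @return Row-bound annotated tables for every sample.
#' @export
run_annotate <- function(features, ms2 = list(), ...) {
  features <- validate_feature_table(as.data.frame(features))
  parts <- split(features, features$sample_id)
  out <- do.call(rbind, lapply(parts, annotate_sample, ms2 = ms2, ...))
  rownames(out) <- NULL
  out
}

# parse condition/day/replicate from generator sample ids
.parse_sample_design <- function(sample_id) {
  m <- regmatches(sample_id,
                  regexec("^(plant|synthetic)_(.+)_d([0-9]+)_r([0-9]+)$",
                          sample_id))
  ok <- lengths(m) == 5
  data.frame(
    sample_id = sample_id,
    source = ifelse(ok, vapply(m, function(x)
      if (length(x) == 5) x[2] else NA_character_, ""), NA),
    condition = ifelse(ok, vapply(m, function(x)
      if (length(x) == 5) x[3] else NA_character_, ""), NA),
    day = ifelse(ok, vapply(m, function(x)
      if (length(x) == 5) as.numeric(x[4]) else NA_real_, 0), NA),
    replicate = ifelse(ok, vapply(m, function(x)
      if (length(x) == 5) as.numeric(x[5]) else NA_real_, 0), NA),
    stringsAsFactors = FALSE)
}

#' Trend analysis over an annotated stability study
#'
#' Normalises each sample to its internal standard, aggregates per
#' (sample, compound) by summing the quantifiable features of that
#' compound (isomeric peaks of the same class are summed; isotope
#' companions and in-source artifacts are excluded), builds the trend
#' table, and fits per-(compound, condition) slopes with Mann-Kendall
#' monotonicity verdicts.
#'
#' @param annotated output of [run_annotate()] on stability-study samples
#'   whose sample ids encode `source_condition_dDD_rR`, or any table with
#'   added `condition`, `day`, `replicate` columns.
#' @param design optional data.frame `sample_id, condition, day, replicate`
#'   overriding the id-encoded design.
#' @param is_rt internal-standard retention time (default the packaged
#'   library's D3-THC entry RT).
#' @param snr_min LOQ threshold (default 10).
#' @param alpha significance level for monotonicity (default 0.05).
#' @return List with `trend_table`, `slopes` (compound x condition OLS
#'   slopes + monotonicity), and `source_report` from [source_markers()].
#' @export
run_trends <- function(annotated, design = NULL,
                       is_rt = default_library()[["D3-D9-THC"]]$rt,
                       snr_min = 10, alpha = 0.05) {
  if (is.null(design))
    design <- .parse_sample_design(unique(annotated$sample_id))
  if (anyNA(design$condition))
    stop("cannot infer condition/day/replicate for sample(s): ",
         paste(design$sample_id[is.na(design$condition)], collapse = ", "))

  parts <- split(annotated, annotated$sample_id)
  rows <- lapply(parts, function(s) {
    s <- normalize_to_is(s, is_rt = is_rt)
    s <- s[s$role == "analyte" & !is.na(s$compound) &
             !(s$compound %in% c("unclassified", "isotope",
                                 "in-source-artifact", "D3-D9-THC")), ,
           drop = FALSE]
    if (!nrow(s)) return(NULL)
    agg <- lapply(split(s, s$compound), function(g) {
      q <- loq_gate(g$snr, snr_min) == "quantifiable"
      data.frame(sample_id = g$sample_id[1], compound = g$compound[1],
                 norm_intensity = if (any(q)) sum(g$norm_intensity[q])
                                  else sum(g$norm_intensity),
                 snr = max(g$snr), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  per_sample <- do.call(rbind, rows)
  per_sample <- merge(per_sample, design, by = "sample_id")

  trend <- build_trend_table(per_sample, snr_min = snr_min)

  slope_rows <- list(); k <- 0L
  for (cmp in unique(trend$compound)) {
    for (cond in unique(trend$condition)) {
      cell <- trend[trend$compound == cmp & trend$condition == cond &
                      !is.na(trend$mean_norm_abundance), , drop = FALSE]
      if (nrow(cell) < 3) next
      ts <- trend_stat(cell$day, cell$mean_norm_abundance, alpha = alpha)
      k <- k + 1L
      slope_rows[[k]] <- data.frame(
        compound = cmp, condition = cond, slope = ts$slope,
        mk_s = ts$mk_s, mk_p = ts$mk_p, monotonicity = ts$monotonicity,
        n_days = nrow(cell), stringsAsFactors = FALSE)
    }
  }
  slopes <- if (k) do.call(rbind, slope_rows) else
    data.frame(compound = character(), condition = character(),
               slope = double(), mk_s = double(), mk_p = double(),
               monotonicity = character(), n_days = integer())

  report <- source_markers(unique(per_sample$compound))
  list(trend_table = trend, slopes = slopes, source_report = report)
}

#' Generate a fixture directory
#'
#' Writes day-1 feature tables and MGF spectra for both sources, the
#' packaged library, a full stability study per source, and a planted-truth
#' JSON manifest.
#'
#' @param out_dir destination directory.
#' @param cfg a [generator_config()].
#' @param force overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
run_generate <- function(out_dir, cfg = generator_config(), force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  generate_library_fixture(file.path(out_dir, "library.msp"))
  truth <- list(seed = cfg$seed)
  for (src in c("plant", "synthetic")) {
    d1 <- generate_day1(src, cfg)
    write_feature_table(d1$features,
                        file.path(out_dir, paste0("day1_", src, ".csv")))
    write_ms2_mgf(d1$ms2, file.path(out_dir, paste0("day1_", src, ".mgf")))
    st <- generate_stability_study(src, cfg)
    write_feature_table(st$features,
                        file.path(out_dir, paste0("stability_", src, ".csv")))
    write_ms2_mgf(st$ms2,
                  file.path(out_dir, paste0("stability_", src, ".mgf")))
    truth[[src]] <- list(day1 = d1$truth, stability = st$truth,
                         links = st$links, slopes = st$slopes)
  }
  jsonlite::write_json(truth, file.path(out_dir, "planted_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
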