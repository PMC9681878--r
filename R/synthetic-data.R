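# Seeded generator emulating the study's UHPLC-TIMS-TOF feature data:
# day-1 impurity profiles for plant-derived and synthetic CBD e-liquids,
# and four-condition stability studies (5 sampling days x 5 replicates)
# with linear-with-floor degradation kinetics, Gaussian mass/RT noise,
# lognormal intensity noise, M+1 isotope companion features, and planted
# in-source water-loss artifacts. Planted truth is returned alongside the
# data so recall/precision and parameter recovery are computable.

# Study compound catalogue. day1_plant/day1_synth transcribe the day-1
# presence matrix; day29 columns the stressed-condition end-point set.
# base = day-1 intensity (arbitrary units); class = planted truth label
# ("library" = expected validated library match).
.STUDY_COMPOUNDS <- local({
  s <- function(label, formula, rt, ccs, base, class, ms2,
                d1p, d1s, d29p, d29s, kin)
    data.frame(label = label, formula = formula, rt = rt, ccs = ccs,
               base = base, class = class, ms2 = ms2,
               day1_plant = d1p, day1_synth = d1s,
               day29_plant = d29p, day29_synth = d29s,
               kinetics = kin, stringsAsFactors = FALSE)
  rbind(
    s("CBD",         "C21H30O2", 4.99, 185.3, 5e6, "library", "CBD",  TRUE,  TRUE,  TRUE,  TRUE,  "none"),
    s("IS",          "C21H27D3O2", 8.20, 184.5, 1e6, "internal-standard", "generic", TRUE, TRUE, TRUE, TRUE, "none"),
    s("6a-OH-CBD",   "C21H30O3", 1.84, 183.0, 4e4, "library", "OHCBD6a", TRUE, FALSE, TRUE, FALSE, "none"),
    s("7-OH-CBD",    "C21H30O3", 2.03, 188.0, 4e4, "library", "OHCBD7",  TRUE, FALSE, TRUE, FALSE, "none"),
    s("CBDV",        "C19H26O2", 3.20, 174.0, 6e4, "library", "CBD",   TRUE, FALSE, TRUE, FALSE, "none"),
    s("CBDB",        "C20H28O2", 3.92, 180.5, 5e4, "library", "CBD",   TRUE,  TRUE,  TRUE,  TRUE,  "none"),
    s("CBDH",        "C22H32O2", 6.56, 190.5, 3e4, "library", "CBDH",  TRUE, FALSE, TRUE, FALSE, "none"),
    s("CBDP",        "C23H34O2", 8.95, 196.0, 2.5e4, "library", "CBD", TRUE, FALSE, TRUE, FALSE, "none"),
    s("HU-331",      "C21H28O3", 9.92, 185.0, 2e4, "library", "generic", TRUE, TRUE, TRUE, TRUE, "HU-331"),
    s("CBDH-isomer", "C22H32O2", 9.65, 189.9, 2e4, "CBDH-isomer", "CBDH", FALSE, TRUE, FALSE, TRUE, "none"),
    s("HU-331-like", "C21H28O3", 2.42, 187.0, 1e4, "HU-331-like", "generic", TRUE, TRUE, FALSE, TRUE, "HU-331-like"),
    s("OH-CBE@2.76", "C21H30O4", 2.76, 192.0, 1.5e4, "OH-CBE", "CBE", TRUE, TRUE, TRUE, TRUE, "OH-CBE"),
    s("OH-CBE@4.75", "C21H30O4", 4.75, 193.5, 1.2e4, "OH-CBE", "CBE", TRUE, TRUE, TRUE, TRUE, "OH-CBE"),
    # degradants absent on day 1 (base 0), formed during storage
    s("CBE",         "C21H30O3", 4.17, 186.0, 0, "library", "CBE",    FALSE, FALSE, TRUE, TRUE, "CBE"),
    s("CBE-isomer",  "C21H30O3", 2.85, 184.9, 0, "CBE-isomer", "CBE", FALSE, FALSE, TRUE, TRUE, "CBE"),
    s("OH-CBD@3.22", "C21H30O3", 3.22, 189.5, 0, "OH-CBD", "CBD",     FALSE, FALSE, TRUE, TRUE, "OH-CBD"),
    s("OH-CBD@3.67", "C21H30O3", 3.67, 190.5, 0, "OH-CBD", "CBD",     FALSE, FALSE, FALSE, TRUE, "OH-CBD"),
    s("diOH-CBD@2.13", "C21H30O4", 2.13, 194.0, 0, "diOH-CBD", "CBD", FALSE, FALSE, TRUE, TRUE, "diOH-CBD"),
    s("diOH-CBD@2.52", "C21H30O4", 2.52, 195.0, 0, "diOH-CBD", "CBD", FALSE, FALSE, TRUE, TRUE, "diOH-CBD"),
    s("OH-CBE@3.61", "C21H30O4", 3.61, 192.8, 0, "OH-CBE", "CBE",     FALSE, FALSE, TRUE, TRUE, "OH-CBE"),
    s("OH-CBE@4.21", "C21H30O4", 4.21, 193.0, 0, "OH-CBE", "CBE",     FALSE, FALSE, TRUE, TRUE, "OH-CBE")
  )
})

# Planted degradation slopes (intensity units per day) by kinetics group and
# condition. Orderings encode the qualitative findings: CBE-type products
# grow fastest under stress/light and barely at 4 C; HU-331 accumulates
# most when refrigerated in the dark and is lost under light
# (photodegradation); OH-CBE accumulates most at ambient temperature in
# the dark.
.DEFAULT_KINETICS <- list(
  none          = c(light_ambient_25C_60RH = 0, dark_ambient_25C_60RH = 0,
                    stressed_40C_75RH = 0, refrigerated_4C = 0),
  CBE           = c(light_ambient_25C_60RH = 3.5e4, dark_ambient_25C_60RH = 1e4,
                    stressed_40C_75RH = 4e4, refrigerated_4C = 500),
  `HU-331`      = c(light_ambient_25C_60RH = -500, dark_ambient_25C_60RH = 5e3,
                    stressed_40C_75RH = 3e3, refrigerated_4C = 8e3),
  `HU-331-like` = c(light_ambient_25C_60RH = 5e3, dark_ambient_25C_60RH = 2e3,
                    stressed_40C_75RH = 6e3, refrigerated_4C = 300),
  `OH-CBE`      = c(light_ambient_25C_60RH = 6e3, dark_ambient_25C_60RH = 1.2e4,
                    stressed_40C_75RH = 8e3, refrigerated_4C = 1e3),
  `OH-CBD`      = c(light_ambient_25C_60RH = 1.5e4, dark_ambient_25C_60RH = 5e3,
                    stressed_40C_75RH = 2e4, refrigerated_4C = 500),
  `diOH-CBD`    = c(light_ambient_25C_60RH = 1e4, dark_ambient_25C_60RH = 4e3,
                    stressed_40C_75RH = 1.5e4, refrigerated_4C = 400)
)

#' Generator configuration
#'
#' @param seed integer RNG seed.
#' @param mass_noise_ppm_sd Gaussian m/z noise sd, ppm (default 0.5).
#' @param rt_jitter_sd Gaussian RT jitter sd, minutes (default 0.02).
#' @param ccs_noise_pct_sd Gaussian CCS noise sd, percent (default 0.2).
#' @param intensity_cv lognormal intensity coefficient of variation
#'   (default 0.10; the distribution is mean-1 so noise is unbiased).
#' @param kinetics named list: kinetics group -> named condition slopes
#'   (intensity units/day); defaults encode the qualitative condition
#'   orderings of the study.
#' @param artifact_parents compound labels whose features emit an in-source
#'   water-loss child (default the diOH-CBD and OH-CBE species).
#' @param artifact_fraction child intensity as a fraction of the parent
#'   (default 0.2).
#' @param noise_floor intensity corresponding to S/N 1 (default 200); S/N
#'   is intensity / noise_floor.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, mass_noise_ppm_sd = 0.5,
                             rt_jitter_sd = 0.02, ccs_noise_pct_sd = 0.2,
                             intensity_cv = 0.10,
                             kinetics = .DEFAULT_KINETICS,
                             artifact_parents = c("diOH-CBD@2.13",
                                                  "diOH-CBD@2.52",
                                                  "OH-CBE@2.76",
                                                  "OH-CBE@3.61",
                                                  "OH-CBE@4.21",
                                                  "OH-CBE@4.75"),
                             artifact_fraction = 0.2,
                             noise_floor = 200) {
  stopifnot(mass_noise_ppm_sd >= 0, rt_jitter_sd >= 0, intensity_cv >= 0,
            ccs_noise_pct_sd >= 0, artifact_fraction > 0, noise_floor > 0)
  structure(list(seed = as.integer(seed),
                 mass_noise_ppm_sd = mass_noise_ppm_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 ccs_noise_pct_sd = ccs_noise_pct_sd,
                 intensity_cv = intensity_cv, kinetics = kinetics,
                 artifact_parents = artifact_parents,
                 artifact_fraction = artifact_fraction,
                 noise_floor = noise_floor),
            class = "generator_config")
}

.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

# theoretical ion m/z and M+1 relative abundance for a compound row
.compound_theory <- local({
  cache <- new.env(parent = emptyenv())
  function(formula) {
    if (!is.null(cache[[formula]])) return(cache[[formula]])
    mz <- ion_mz(formula, "[M+H]+")
    pat <- isotope_pattern(formula)
    m1 <- if (nrow(pat) >= 2) pat$rel_abundance[2] else 0
    m1_dmz <- if (nrow(pat) >= 2) pat$mz[2] - pat$mz[1] else 1.003355
    val <- list(mz = mz, m1 = m1, m1_dmz = m1_dmz)
    cache[[formula]] <- val
    val
  }
})

# MS2 spectrum for a generated feature, from the diagnostic templates
.generated_ms2 <- function(label, ms2_type, precursor, spectrum_id) {
  pk <- switch(ms2_type,
    CBD     = .MS2_TEMPLATES$CBD,
    OHCBD6a = rbind(.MS2_TEMPLATES$CBD,
                    data.frame(mz = precursor - 18.0105646, intensity = 80)),
    OHCBD7  = rbind(.MS2_TEMPLATES$CBD,
                    data.frame(mz = precursor - 18.0105646, intensity = 50)),
    CBE     = .MS2_TEMPLATES$CBE,
    CBDH    = .MS2_TEMPLATES$CBDH,
    generic = data.frame(mz = c(precursor - 18.0105646, 119.0855),
                         intensity = c(100, 40))
  )
  ms2_spectrum(spectrum_id, precursor, pk$mz, pk$intensity, "25-50 eV")
}

# Emit one sample's features from a catalogue subset with intensities.
.emit_sample <- function(rows, intensity, sample_id, cfg) {
  n <- nrow(rows)
  keep <- intensity > 0
  rows <- rows[keep, , drop = FALSE]
  intensity <- intensity[keep]
  n <- nrow(rows)
  theory <- lapply(rows$formula, .compound_theory)
  mz0 <- vapply(theory, `[[`, 0, "mz")
  m1 <- vapply(theory, `[[`, 0, "m1")
  m1_dmz <- vapply(theory, `[[`, 0, "m1_dmz")

  mz <- mz0 * (1 + stats::rnorm(n, 0, cfg$mass_noise_ppm_sd) * 1e-6)
  rt <- pmax(0, rows$rt + stats::rnorm(n, 0, cfg$rt_jitter_sd))
  ccs <- rows$ccs * (1 + stats::rnorm(n, 0, cfg$ccs_noise_pct_sd / 100))
  intensity <- intensity * .lognoise(n, cfg$intensity_cv)

  fid <- sprintf("%s_F%02d", sample_id, seq_len(n))
  ms2_ids <- paste0(fid, "_MS2")
  main <- feature_table(
    feature_id = fid, sample_id = sample_id, mz = mz, rt_min = rt,
    ccs_A2 = ccs, mobility_1k0 = NA_real_, intensity = intensity,
    snr = intensity / cfg$noise_floor, ms2_ref = ms2_ids)

  spectra <- stats::setNames(lapply(seq_len(n), function(i)
    .generated_ms2(rows$label[i], rows$ms2[i], mz0[i], ms2_ids[i])), ms2_ids)

  truth <- data.frame(feature_id = fid, sample_id = sample_id,
                      compound = rows$label, class = rows$class,
                      role = "analyte", stringsAsFactors = FALSE)

  # M+1 isotope companion features (same RT, no MS2 of their own)
  iso <- feature_table(
    feature_id = paste0(fid, "_M1"), sample_id = sample_id,
    mz = mz + m1_dmz, rt_min = rt, ccs_A2 = ccs, mobility_1k0 = NA_real_,
    intensity = intensity * m1, snr = intensity * m1 / cfg$noise_floor,
    ms2_ref = NA_character_)
  iso_truth <- data.frame(feature_id = paste0(fid, "_M1"),
                          sample_id = sample_id, compound = rows$label,
                          class = "isotope", role = "isotope",
                          stringsAsFactors = FALSE)

  # planted in-source water-loss children for configured parents
  art_sel <- which(rows$label %in% cfg$artifact_parents)
  links <- data.frame(child_id = character(), parent_id = character(),
                      stringsAsFactors = FALSE)
  art <- NULL
  if (length(art_sel)) {
    ai <- art_sel
    child_int <- intensity[ai] * cfg$artifact_fraction
    art <- feature_table(
      feature_id = paste0(fid[ai], "_WL"), sample_id = sample_id,
      mz = mz[ai] - 18.0105646, rt_min = rt[ai], ccs_A2 = ccs[ai] * 0.97,
      mobility_1k0 = NA_real_, intensity = child_int,
      snr = child_int / cfg$noise_floor,
      ms2_ref = NA_character_)
    links <- data.frame(child_id = paste0(fid[ai], "_WL"),
                        parent_id = fid[ai], stringsAsFactors = FALSE)
    art_truth <- data.frame(feature_id = paste0(fid[ai], "_WL"),
                            sample_id = sample_id,
                            compound = rows$label[ai],
                            class = "in-source-artifact",
                            role = "artifact", stringsAsFactors = FALSE)
    truth <- rbind(truth, art_truth)
  }
  features <- rbind(main, iso, if (!is.null(art)) art)
  features <- validate_feature_table(features[order(features$mz), ])
  list(features = features, ms2 = spectra,
       truth = rbind(truth, iso_truth), links = links)
}

#' Generate a day-1 profiling sample
#'
#' Emits one feature per catalogue compound present on day 1 for the given
#' source (plus CBD and the internal standard, always present), at
#' theoretical m/z with Gaussian ppm noise, catalogue RT with jitter,
#' catalogue CCS with noise, M+1 isotope companions, in-source water-loss
#' children for the configured parents, and MS2 spectra built from the
#' diagnostic-fragment templates.
#'
#' @param source `"plant"` or `"synthetic"`.
#' @param cfg a [generator_config()].
#' @param sample_id sample identifier (default derived from source).
#' @return List with `features` (a `feature_table`), `ms2` (named list of
#'   `ms2_spectrum`), `truth` (planted feature-level truth) and `links`
#'   (planted artifact links).
#' @export
generate_day1 <- function(source = c("plant", "synthetic"),
                          cfg = generator_config(),
                          sample_id = paste0("day1_", source)) {
  source <- match.arg(source)
  set.seed(cfg$seed)
  col <- if (source == "plant") "day1_plant" else "day1_synth"
  rows <- .STUDY_COMPOUNDS[.STUDY_COMPOUNDS[[col]], , drop = FALSE]
  .emit_sample(rows, rows$base, sample_id, cfg)
}

#' Generate a four-condition stability study
#'
#' For every condition x day x replicate sample, each catalogue compound
#' present for the source evolves as
#' `intensity(t) = max(0, base + slope(condition) * (t - 1))` with
#' multiplicative lognormal noise; S/N scales with intensity, so slowly
#' formed degradants start below the LOQ. In-source water-loss children and
#' M+1 companions are emitted as on day 1.
#'
#' @param source `"plant"` or `"synthetic"`.
#' @param cfg a [generator_config()].
#' @param conditions,days,replicates design; defaults are the full study
#'   (4 conditions x days 1,8,15,22,29 x 5 replicates).
#' @return List with `features` (all samples in one `feature_table`),
#'   `ms2`, `truth`, `links`, and `slopes` — the planted per-compound,
#'   per-condition aggregate slopes (variants of the same compound label
#'   summed), the reference for parameter-recovery checks.
#' @export
generate_stability_study <- function(source = c("plant", "synthetic"),
                                     cfg = generator_config(),
                                     conditions = study_conditions(),
                                     days = study_days(),
                                     replicates = 1:5) {
  source <- match.arg(source)
  set.seed(cfg$seed)
  day1_col <- if (source == "plant") "day1_plant" else "day1_synth"
  d29_col <- if (source == "plant") "day29_plant" else "day29_synth"
  cat_rows <- .STUDY_COMPOUNDS[.STUDY_COMPOUNDS[[day1_col]] |
                                 .STUDY_COMPOUNDS[[d29_col]], , drop = FALSE]
  feats <- list(); spectra <- list(); truths <- list(); links <- list()
  k <- 0L
  for (cond in conditions) {
    for (d in days) {
      for (rep in replicates) {
        sample_id <- sprintf("%s_%s_d%02d_r%d", source, cond, d, rep)
        slope <- vapply(cat_rows$kinetics, function(g)
          cfg$kinetics[[g]][[cond]], 0)
        base <- ifelse(cat_rows[[day1_col]], cat_rows$base, 0)
        intensity <- pmax(0, base + slope * (d - 1))
        out <- .emit_sample(cat_rows, intensity, sample_id, cfg)
        k <- k + 1L
        feats[[k]] <- out$features
        spectra <- c(spectra, out$ms2)
        truths[[k]] <- out$truth
        out$links$sample_id <- rep(sample_id, nrow(out$links))
        links[[k]] <- out$links
        truths[[k]]$condition <- cond
        truths[[k]]$day <- d
        truths[[k]]$replicate <- rep
      }
    }
  }
  # planted aggregate slope per compound label x condition; isomeric
  # variants ("X@rt") of one compound sum, matching the trend aggregation
  agg_label <- sub("@.*$", "", cat_rows$label)
  slopes <- do.call(rbind, lapply(unique(agg_label), function(lb) {
    sel <- agg_label == lb
    do.call(rbind, lapply(conditions, function(cond) {
      sl <- sum(vapply(cat_rows$kinetics[sel], function(g)
        cfg$kinetics[[g]][[cond]], 0))
      data.frame(compound = lb, condition = cond, slope = sl,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(features = validate_feature_table(do.call(rbind, feats)),
       ms2 = spectra, truth = do.call(rbind, truths),
       links = do.call(rbind, links), slopes = slopes)
}

#' Write the packaged reference library as a fixture file
#'
#' @param path destination path.
#' @param cfg unused, accepted for interface symmetry.
#' @return The path, invisibly.
#' @export
generate_library_fixture <- function(path, cfg = generator_config()) {
  write_library(default_library(), path)
}
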