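# Internal-standard normalisation, LOQ gating, storage-condition trend
# statistics, calibration-based quantitation and source-marker calls.

#' Storage conditions of the stability design
#'
#' @return Character vector of the four condition codes.
#' @export
study_conditions <- function() {
  c("light_ambient_25C_60RH", "dark_ambient_25C_60RH",
    "stressed_40C_75RH", "refrigerated_4C")
}

#' Study sampling days
#'
#' @return Integer vector `c(1, 8, 15, 22, 29)`.
#' @export
study_days <- function() c(1L, 8L, 15L, 22L, 29L)

#' Theoretical m/z of the deuterated internal standard
#'
#' Protonated D3-delta9-THC, computed from its composition (C21H27D3O2)
#' rather than hard-coded.
#'
#' @return m/z in Da.
#' @export
is_mz <- function() ion_mz("C21H27D3O2", "[M+H]+")

#' Normalise feature intensities to the internal standard
#'
#' Each analyte intensity in a sample is divided by the intensity of that
#' sample's internal-standard feature. Exactly one feature must match the
#' IS within the tolerances; zero or multiple candidates is a per-sample
#' error.
#'
#' @param features `feature_table` for one sample.
#' @param is_mz IS ion m/z (default computed from the D3-THC composition).
#' @param is_rt IS retention time, minutes.
#' @param mz_tol_ppm,rt_tol_min matching tolerances (defaults 5 ppm,
#'   0.1 min).
#' @return The feature table with an added `norm_intensity` column; the IS
#'   feature row is retained (normalised to 1).
#' @export
normalize_to_is <- function(features, is_mz = cannastab::is_mz(),
                            is_rt, mz_tol_ppm = 5, rt_tol_min = 0.1) {
  features <- validate_feature_table(as.data.frame(features))
  hit <- abs(ppm_error(features$mz, is_mz)) <= mz_tol_ppm &
    abs(features$rt_min - is_rt) <= rt_tol_min
  n_hit <- sum(hit)
  if (n_hit == 0L)
    stop("internal standard not found in sample ",
         unique(features$sample_id)[1])
  if (n_hit > 1L)
    stop("multiple internal-standard candidates in sample ",
         unique(features$sample_id)[1])
  is_intensity <- features$intensity[hit]
  if (is_intensity <= 0) stop("internal standard has zero intensity")
  features$norm_intensity <- features$intensity / is_intensity
  features
}

#' LOQ gate on signal-to-noise
#'
#' A feature is quantifiable when its signal-to-noise ratio is at least
#' `snr_min` (default 10, the S/N at the limit of quantification); the
#' boundary is inclusive. A missing S/N gates to below-LOQ with a warning.
#'
#' @param snr numeric vector of signal-to-noise ratios (NA allowed).
#' @param snr_min threshold (default 10).
#' @return Character vector: `"quantifiable"` or `"below_loq"`.
#' @export
loq_gate <- function(snr, snr_min = 10) {
  if (anyNA(snr)) warning("missing S/N gated to below_loq")
  ifelse(!is.na(snr) & snr >= snr_min, "quantifiable", "below_loq")
}

#' Build a compound x condition x day trend table
#'
#' Summarises normalised abundances per (compound, condition, day) cell:
#' mean and sd over the quantifiable replicates only (below-LOQ replicates
#' are counted, not imputed).
#'
#' @param df data.frame with columns `compound`, `condition`, `day`,
#'   `replicate`, `norm_intensity`, `snr`.
#' @param snr_min LOQ threshold passed to [loq_gate()].
#' @return data.frame `compound, condition, day, mean_norm_abundance, sd,
#'   n, below_loq_count`, ordered by compound, condition, day.
#' @export
build_trend_table <- function(df, snr_min = 10) {
  need <- c("compound", "condition", "day", "norm_intensity", "snr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    return(data.frame(compound = character(), condition = character(),
                      day = integer(), mean_norm_abundance = double(),
                      sd = double(), n = integer(),
                      below_loq_count = integer()))
  df$gate <- loq_gate(df$snr, snr_min)
  key <- interaction(df$compound, df$condition, df$day, drop = TRUE)
  cells <- split(df, key)
  out <- do.call(rbind, lapply(cells, function(cell) {
    q <- cell$norm_intensity[cell$gate == "quantifiable"]
    data.frame(compound = cell$compound[1], condition = cell$condition[1],
               day = cell$day[1],
               mean_norm_abundance = if (length(q)) mean(q) else NA_real_,
               sd = if (length(q) > 1) stats::sd(q)
                    else if (length(q) == 1) 0 else NA_real_,
               n = nrow(cell),
               below_loq_count = sum(cell$gate == "below_loq"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$compound, out$condition, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact null distribution of the Mann-Kendall S statistic for n <= 10
# (no ties): counts of permutations with a given number of inversions,
# built by the classical recursion, cached per n.
.mk_s_null <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # counts[k+1] = number of permutations of 1..n with k inversions
    counts <- 1
    for (m in 2:n) {
      new <- numeric(length(counts) + m - 1)
      for (k in 0:(m - 1)) new[(k + 1):(k + length(counts))] <-
          new[(k + 1):(k + length(counts))] + counts
      counts <- new
    }
    # S = concordant - discordant = n(n-1)/2 - 2 * inversions
    total <- n * (n - 1) / 2
    s_values <- total - 2 * (seq_along(counts) - 1)
    d <- list(s = s_values, prob = counts / sum(counts))
    cache[[key]] <<- d
    d
  }
})

#' Mann-Kendall trend test
#'
#' Computes the Mann-Kendall S statistic
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}. For n <= 10 without ties
#' the p-value is taken from the exact null distribution of S (two-sided:
#' \eqn{2 P(S \ge |s|)}, capped at 1); otherwise the normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x numeric series in time order (length >= 3).
#' @return List with `s`, `p_value`, `method`.
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 3) stop("Mann-Kendall test needs at least 3 points")
  s <- 0
  for (i in 1:(n - 1)) s <- s + sum(sign(x[(i + 1):n] - x[i]))
  ties <- any(duplicated(x))
  if (n <= 10 && !ties) {
    null <- .mk_s_null(n)
    p <- if (s == 0) 1 else min(1, 2 * sum(null$prob[null$s >= abs(s)]))
    return(list(s = s, p_value = p, method = "exact"))
  }
  tie_counts <- table(x)
  tie_counts <- tie_counts[tie_counts > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  if (var_s <= 0) return(list(s = s, p_value = 1, method = "normal"))
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s) else 0
  list(s = s, p_value = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Trend statistics for one time series
#'
#' Ordinary-least-squares slope of abundance vs day, plus a Mann-Kendall
#' monotonicity verdict at level `alpha`.
#'
#' @param day numeric vector of days (>= 3 points).
#' @param value abundances at those days.
#' @param alpha significance level for the monotonicity verdict
#'   (default 0.05).
#' @return List with `slope` (per day), `intercept`, `mk_s`, `mk_p`,
#'   `monotonicity` (`"increasing"`, `"decreasing"` or `"none"`).
#' @export
trend_stat <- function(day, value, alpha = 0.05) {
  stopifnot(length(day) == length(value))
  if (length(day) < 3) stop("trend statistics need at least 3 time points")
  fit <- stats::lm(value ~ day)
  mk <- mann_kendall(value[order(day)])
  verdict <- if (mk$p_value <= alpha && mk$s > 0) "increasing"
             else if (mk$p_value <= alpha && mk$s < 0) "decreasing"
             else "none"
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       mk_s = mk$s, mk_p = mk$p_value, monotonicity = verdict)
}

#' Fit a calibration curve by ordinary least squares
#'
#' @param concentration,response numeric vectors (>= 2 distinct
#'   concentrations).
#' @return List of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `points`.
#' @export
fit_calibration <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 2)
    stop("calibration needs at least 2 distinct concentrations")
  fit <- stats::lm(response ~ concentration)
  # computed directly (not via summary.lm, which warns on perfect fits)
  sst <- sum((response - mean(response))^2)
  r2 <- if (sst == 0) NA_real_
        else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = data.frame(concentration = concentration,
                                     response = response)),
            class = "calibration_curve")
}

#' Invert a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param response numeric response value(s).
#' @return data.frame with `concentration` and `below_range` (TRUE when the
#'   inverted concentration is negative, in which case `concentration` is
#'   NA).
#' @export
quantify <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (response - curve$intercept) / curve$slope
  below <- conc < 0
  data.frame(concentration = ifelse(below, NA_real_, conc),
             below_range = below)
}

#' Source-marker sets and verdict
#'
#' Compounds detected only in plant-derived CBD (CBDV, CBDP, CBDH,
#' 6a-OH-CBD, 7-OH-CBD) mark a plant source; the CBDH isomer marks a
#' synthetic source; CBDB, OH-CBE, HU-331 and HU-331-like occur in both and
#' are never used as discriminators.
#'
#' @param detected character vector of compound labels detected in the
#'   sample set (abbreviations / classifier labels).
#' @return List with `verdict` (`"plant"`, `"synthetic"` or
#'   `"indeterminate"`), `plant_markers_detected`,
#'   `synthetic_markers_detected`, `shared_detected`.
#' @export
source_markers <- function(detected) {
  plant_set <- c("CBDV", "CBDP", "CBDH", "6a-OH-CBD", "7-OH-CBD")
  synth_set <- c("CBDH-isomer")
  shared_set <- c("CBDB", "OH-CBE", "HU-331", "HU-331-like")
  p <- intersect(plant_set, detected)
  s <- intersect(synth_set, detected)
  verdict <- if (length(p) && !length(s)) "plant"
             else if (length(s) && !length(p)) "synthetic"
             else "indeterminate"
  list(verdict = verdict, plant_markers_detected = p,
       synthetic_markers_detected = s,
       shared_detected = intersect(shared_set, detected))
}
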