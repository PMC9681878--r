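# Independent brute-force enumeration oracle for [M+H]+ CHO formulas over
# the default bounds (C 0-40, H 0-80, O 0-10, RDBE 0-25): fully vectorised
# over the complete grid, sharing no code with enumerate_formulas().
brute_formulas_mh <- function(mz, tol_ppm = 5) {
  g <- expand.grid(C = 0:40, H = 0:80, O = 0:10)
  mass <- g$C * 12 + g$H * 1.00782503207 + g$O * 15.9949146196
  imz <- mass + 1.00782503207 - 0.00054858
  ppm <- (mz - imz) / imz * 1e6
  rd <- g$C - g$H / 2 + 1
  keep <- abs(ppm) <= tol_ppm & rd >= 0 & rd <= 25 & (g$C + g$H + g$O) > 0
  g <- g[keep, , drop = FALSE]
  part <- function(e, n) ifelse(n == 0, "", ifelse(n == 1, e, paste0(e, n)))
  sort(paste0(part("C", g$C), part("H", g$H), part("O", g$O)))
}

# A generator configuration with every noise source switched off; the
# emitted values are then exactly the catalogue / kinetics values.
zero_noise_config <- function(seed = 1L) {
  generator_config(seed = seed, mass_noise_ppm_sd = 0, rt_jitter_sd = 0,
                   ccs_noise_pct_sd = 0, intensity_cv = 0)
}

# Expected annotation label for each planted-truth row.
expected_labels <- function(truth) {
  ifelse(truth$role == "isotope", "isotope",
  ifelse(truth$role == "artifact", "in-source-artifact",
  ifelse(truth$class == "internal-standard", "D3-D9-THC",
  ifelse(truth$class == "library", truth$compound, truth$class))))
}

# Fraction of planted truth rows whose annotation label is recovered by the
# full annotate pipeline on the two day-1 samples.
day1_recovery_rate <- function(cfg) {
  total <- 0L; good <- 0L
  for (src in c("plant", "synthetic")) {
    d1 <- generate_day1(src, cfg)
    ann <- annotate_sample(d1$features, ms2 = d1$ms2)
    got <- ann$compound[match(d1$truth$feature_id, ann$feature_id)]
    want <- expected_labels(d1$truth)
    total <- total + nrow(d1$truth)
    good <- good + sum(got == want, na.rm = TRUE)
  }
  good / total
}

# Trend analysis of a generated stability study using the planted truth
# labels in place of the annotation step, so trend recovery is tested
# independently of classifier performance.
truth_trends <- function(study, ...) {
  ann <- merge(as.data.frame(study$features),
               study$truth[, c("feature_id", "compound", "class", "role")],
               by = "feature_id")
  ann$compound <- ifelse(ann$role == "isotope", "isotope",
                  ifelse(ann$role == "artifact", "in-source-artifact",
                  ifelse(ann$class == "internal-standard", "D3-D9-THC",
                  ifelse(ann$class == "library",
                         sub("@.*$", "", ann$compound), ann$class))))
  run_trends(ann, ...)
}

# One recovered slope from a run_trends() slope table (NA when absent).
slope_of <- function(slopes, compound, condition) {
  v <- slopes$slope[slopes$compound == compound &
                      slopes$condition == condition]
  if (length(v) == 1) v else NA_real_
}
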