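sample_with_is <- function(scale = 1) {
  feature_table(
    feature_id = c("A", "B", "IS"),
    sample_id = "s1",
    mz = c(315.2319, 347.2217, is_mz()),
    rt_min = c(4.99, 2.76, 8.20),
    intensity = c(4e6, 2e4, 1e6) * scale,
    snr = c(20000, 100, 5000))
}

test_that("study design constants are fixed", {
  expect_identical(length(study_conditions()), 4L)
  expect_identical(study_days(), c(1L, 8L, 15L, 22L, 29L))
  expect_equal(round(is_mz(), 4), 318.2507)  # protonated D3-THC
})

test_that("IS normalisation is scale invariant and strict about the IS", {
  a <- normalize_to_is(sample_with_is(1), is_rt = 8.20)
  b <- normalize_to_is(sample_with_is(3.7), is_rt = 8.20)
  expect_equal(a$norm_intensity, b$norm_intensity)
  expect_equal(a$norm_intensity[a$feature_id == "IS"], 1)
  expect_equal(a$norm_intensity[a$feature_id == "A"], 4)
  # missing IS
  no_is <- sample_with_is()[1:2, ]
  expect_error(normalize_to_is(no_is, is_rt = 8.20), "not found")
  # ambiguous IS
  dup <- sample_with_is()
  dup$mz[1] <- is_mz(); dup$rt_min[1] <- 8.21
  expect_error(normalize_to_is(dup, is_rt = 8.20), "multiple")
})

test_that("the LOQ gate is inclusive at S/N 10 and warns on NA", {
  expect_identical(loq_gate(c(10, 9.999, 10.001, 200)),
                   c("quantifiable", "below_loq", "quantifiable",
                     "quantifiable"))
  expect_warning(g <- loq_gate(c(50, NA)), "below_loq")
  expect_identical(g, c("quantifiable", "below_loq"))
  expect_identical(loq_gate(5, snr_min = 3), "quantifiable")
})

test_that("build_trend_table summarises quantifiable replicates only", {
  df <- data.frame(
    compound = "CBE", condition = "stressed_40C_75RH",
    day = c(8, 8, 8, 1, 1), replicate = c(1, 2, 3, 1, 2),
    norm_intensity = c(0.10, 0.12, 0.50, 0.01, 0.02),
    snr = c(100, 100, 9, 100, 4))
  tt <- build_trend_table(df)
  expect_identical(nrow(tt), 2L)
  d8 <- tt[tt$day == 8, ]
  expect_equal(d8$mean_norm_abundance, mean(c(0.10, 0.12)))
  expect_equal(d8$sd, stats::sd(c(0.10, 0.12)))
  expect_identical(d8$n, 3L)
  expect_identical(d8$below_loq_count, 1L)
  d1 <- tt[tt$day == 1, ]
  expect_equal(d1$mean_norm_abundance, 0.01)
  expect_equal(d1$sd, 0)            # a single quantifiable replicate
  # a cell that is entirely below the LOQ keeps NA, not an imputed zero
  df$snr <- 2
  tt2 <- build_trend_table(df)
  expect_true(all(is.na(tt2$mean_norm_abundance)))
  expect_error(build_trend_table(df[, -1]), "missing column")
})

test_that("the exact Mann-Kendall null matches full enumeration at n = 4", {
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  s_brute <- apply(perms, 1, function(x) {
    s <- 0
    for (i in 1:3) s <- s + sum(sign(x[(i + 1):4] - x[i]))
    s
  })
  brute <- table(s_brute) / nrow(perms)
  brute_s <- as.numeric(names(brute))
  brute_p <- as.numeric(brute)[order(brute_s)]
  null <- cannastab:::.mk_s_null(4)
  o <- order(null$s)
  expect_equal(null$s[o], sort(brute_s))
  expect_equal(null$prob[o], brute_p, tolerance = 1e-12)
})

test_that("mann_kendall gives the exact p for short monotone series", {
  mk <- mann_kendall(c(1, 3, 4, 7, 9))
  expect_identical(mk$s, 10)          # fully concordant, n = 5
  expect_identical(mk$method, "exact")
  expect_equal(mk$p_value, 2 * 1 / 120)  # 2 * P(S >= 10) = 2/5!
  dec <- mann_kendall(c(9, 7, 4, 3, 1))
  expect_identical(dec$s, -10)
  expect_equal(dec$p_value, mk$p_value)
  flat <- mann_kendall(c(1, 1, 1, 1))
  expect_identical(flat$s, 0)
  expect_equal(flat$p_value, 1)
  expect_error(mann_kendall(1:2), "at least 3")
  long <- mann_kendall(1:30)
  expect_identical(long$method, "normal")
  expect_lt(long$p_value, 1e-6)
})

test_that("trend_stat recovers slope and monotonicity verdicts", {
  day <- study_days()
  up <- trend_stat(day, 2 + 3 * day)
  expect_equal(up$slope, 3, tolerance = 1e-9)
  expect_equal(up$intercept, 2, tolerance = 1e-9)
  expect_identical(up$monotonicity, "increasing")
  down <- trend_stat(day, 100 - 0.5 * day)
  expect_identical(down$monotonicity, "decreasing")
  set.seed(3)
  none <- trend_stat(day, c(5, 4, 6, 5, 5.5))
  expect_identical(none$monotonicity, "none")
  expect_error(trend_stat(c(1, 8), c(1, 2)), "at least 3")
})

test_that("calibration fits invert correctly and flag below-range", {
  cal <- fit_calibration(c(0, 1, 2, 4), c(0, 10, 20, 40))
  expect_equal(cal$slope, 10, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  q <- quantify(cal, c(59, -5))
  expect_equal(q$concentration[1], 5.9, tolerance = 1e-9)
  expect_false(q$below_range[1])
  expect_true(q$below_range[2])
  expect_true(is.na(q$concentration[2]))
  expect_error(fit_calibration(c(1, 1), c(2, 3)), "distinct")
})

test_that("source markers give plant / synthetic / indeterminate verdicts", {
  p <- source_markers(c("CBDV", "CBDP", "CBDB", "HU-331", "OH-CBE"))
  expect_identical(p$verdict, "plant")
  expect_setequal(p$plant_markers_detected, c("CBDV", "CBDP"))
  expect_setequal(p$shared_detected, c("CBDB", "HU-331", "OH-CBE"))
  s <- source_markers(c("CBDH-isomer", "CBDB"))
  expect_identical(s$verdict, "synthetic")
  both <- source_markers(c("CBDV", "CBDH-isomer"))
  expect_identical(both$verdict, "indeterminate")
  # shared compounds alone never discriminate
  shared <- source_markers(c("CBDB", "HU-331", "HU-331-like", "OH-CBE"))
  expect_identical(shared$verdict, "indeterminate")
  expect_identical(length(shared$plant_markers_detected), 0L)
})
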