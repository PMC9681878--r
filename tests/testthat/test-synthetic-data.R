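test_that("day-1 samples carry the source-specific compound sets", {
  plant <- generate_day1("plant", zero_noise_config())
  synth <- generate_day1("synthetic", zero_noise_config())
  p_cmp <- plant$truth$compound[plant$truth$role == "analyte"]
  s_cmp <- synth$truth$compound[synth$truth$role == "analyte"]
  expect_identical(length(p_cmp), 12L)  # CBD + IS + 10 impurity peaks
  expect_identical(length(s_cmp), 8L)   # CBD + IS + 6 impurity peaks
  expect_true(all(c("CBDV", "CBDP", "CBDH", "6a-OH-CBD", "7-OH-CBD")
                  %in% p_cmp))
  expect_false("CBDV" %in% s_cmp)
  expect_true("CBDH-isomer" %in% s_cmp)
  expect_false("CBDH-isomer" %in% p_cmp)
  shared <- intersect(p_cmp, s_cmp)
  expect_true(all(c("CBDB", "HU-331", "HU-331-like") %in% shared))
})

test_that("zero-noise emission reproduces catalogue values exactly", {
  d1 <- generate_day1("plant", zero_noise_config())
  ft <- d1$features
  cbd <- ft[ft$feature_id ==
              d1$truth$feature_id[d1$truth$compound == "CBD" &
                                    d1$truth$role == "analyte"], ]
  expect_equal(cbd$mz, ion_mz("C21H30O2"), tolerance = 1e-9)
  expect_equal(cbd$rt_min, 4.99)
  expect_equal(cbd$intensity, 5e6)
  expect_equal(cbd$snr, 5e6 / 200)   # S/N = intensity / noise floor
  # the M+1 companion sits one isotope spacing up at the M+1 abundance
  m1 <- ft[ft$feature_id == paste0(cbd$feature_id, "_M1"), ]
  expect_equal(m1$mz - cbd$mz, 1.00336, tolerance = 1e-3)
  expect_equal(m1$intensity / cbd$intensity, 0.2313425, tolerance = 1e-5)
  expect_identical(m1$ms2_ref, NA_character_)
})

test_that("planted water-loss children follow their parents", {
  d1 <- generate_day1("plant", zero_noise_config())
  expect_gt(nrow(d1$links), 0)
  ft <- d1$features
  for (r in seq_len(nrow(d1$links))) {
    child <- ft[ft$feature_id == d1$links$child_id[r], ]
    parent <- ft[ft$feature_id == d1$links$parent_id[r], ]
    expect_equal(parent$mz - child$mz, 18.0105646, tolerance = 1e-6)
    expect_equal(child$rt_min, parent$rt_min)
    expect_equal(child$intensity, 0.2 * parent$intensity)
  }
  # every link endpoint exists in the feature table
  expect_true(all(c(d1$links$child_id, d1$links$parent_id) %in%
                    ft$feature_id))
})

test_that("generation is deterministic in the seed", {
  a <- generate_day1("plant", generator_config(seed = 11))
  b <- generate_day1("plant", generator_config(seed = 11))
  expect_equal(as.data.frame(a$features), as.data.frame(b$features))
  c3 <- generate_day1("plant", generator_config(seed = 12))
  expect_false(isTRUE(all.equal(a$features$mz, c3$features$mz)))
  s1 <- generate_stability_study("plant", generator_config(seed = 5),
                                 conditions = "stressed_40C_75RH",
                                 replicates = 1:2)
  s2 <- generate_stability_study("plant", generator_config(seed = 5),
                                 conditions = "stressed_40C_75RH",
                                 replicates = 1:2)
  expect_equal(as.data.frame(s1$features), as.data.frame(s2$features))
})

test_that("stability kinetics follow the linear-with-floor model", {
  st <- generate_stability_study("plant", zero_noise_config())
  tr <- st$truth
  ft <- st$features
  val <- function(compound, cond, day, rep = 1) {
    id <- tr$feature_id[tr$compound == compound & tr$condition == cond &
                          tr$day == day & tr$replicate == rep &
                          tr$role == "analyte"]
    if (!length(id)) return(0)
    ft$intensity[ft$feature_id == id]
  }
  # degradant formed from zero: intensity = slope * (day - 1)
  expect_equal(val("CBE", "stressed_40C_75RH", 29), 4e4 * 28)
  expect_equal(val("CBE", "stressed_40C_75RH", 8), 4e4 * 7)
  expect_equal(val("CBE", "refrigerated_4C", 29), 500 * 28)
  # day 1 degradants are absent entirely (floor at zero)
  expect_identical(val("CBE", "stressed_40C_75RH", 1), 0)
  # compounds present on day 1 keep their base when the slope is zero
  expect_equal(val("CBD", "dark_ambient_25C_60RH", 29), 5e6)
  # HU-331 photodegrades (negative slope under light)
  expect_equal(val("HU-331", "light_ambient_25C_60RH", 29),
               2e4 - 500 * 28)
})

test_that("planted aggregate slopes sum isomeric variants", {
  st <- generate_stability_study("plant", zero_noise_config())
  sl <- st$slopes
  get <- function(cmp, cond) sl$slope[sl$compound == cmp &
                                        sl$condition == cond]
  # four OH-CBE variants in the plant study share one kinetics group
  expect_equal(get("OH-CBE", "dark_ambient_25C_60RH"), 4 * 1.2e4)
  expect_equal(get("diOH-CBD", "stressed_40C_75RH"), 2 * 1.5e4)
  expect_equal(get("CBE", "stressed_40C_75RH"), 4e4)
  expect_equal(get("CBD", "stressed_40C_75RH"), 0)
  expect_false("OH-CBE@2.76" %in% sl$compound)
})

test_that("mass noise is Gaussian in ppm with the configured sd", {
  st <- generate_stability_study("plant", generator_config(seed = 2))
  tr <- st$truth[st$truth$role == "analyte", ]
  cat <- cannastab:::.STUDY_COMPOUNDS
  theo <- vapply(cat$label, function(l)
    ion_mz(cat$formula[cat$label == l]), 0)
  obs <- st$features$mz[match(tr$feature_id, st$features$feature_id)]
  ppm <- ppm_error(obs, theo[tr$compound])
  expect_gt(length(ppm), 1000)
  expect_equal(mean(ppm), 0, tolerance = 0.05)
  expect_equal(stats::sd(ppm), 0.5, tolerance = 0.1)  # within 20 %
})

test_that("generator_config validates its arguments", {
  expect_error(generator_config(mass_noise_ppm_sd = -1))
  expect_error(generator_config(noise_floor = 0))
  cfg <- generator_config(seed = 3)
  expect_s3_class(cfg, "generator_config")
  expect_identical(cfg$seed, 3L)
})
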