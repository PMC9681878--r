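make_features <- function() {
  feature_table(
    feature_id = c("F1", "F2", "F3"),
    sample_id = "s1",
    mz = c(315.2319, 347.2217, 329.2111),
    rt_min = c(4.99, 2.76, 2.76),
    ccs_A2 = c(185.3, 192.0, NA),
    mobility_1k0 = NA_real_,
    intensity = c(5e6, 1.5e4, 3e3),
    snr = c(25000, 75, 15),
    ms2_ref = c("S1", NA, NA))
}

test_that("feature_table constructs and validates", {
  ft <- make_features()
  expect_s3_class(ft, "feature_table")
  expect_identical(nrow(ft), 3L)
  expect_error(feature_table("F1", "s1", mz = -1, rt_min = 1),
               "mz must be finite")
  expect_error(feature_table("F1", "s1", mz = 100, rt_min = -1),
               "rt_min")
  expect_error(feature_table("F1", "s1", mz = 100, rt_min = 1,
                             intensity = -5), "intensity")
  expect_error(feature_table("F1", "s1", mz = 100, rt_min = 1,
                             ccs_A2 = 0), "ccs_A2")
  expect_error(validate_feature_table(data.frame(mz = 1)),
               "missing column")
})

test_that("feature tables round-trip through CSV with NA handling", {
  ft <- make_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$mz, ft$mz, tolerance = 1e-9)
  expect_equal(back$rt_min, ft$rt_min)
  expect_identical(back$ms2_ref, ft$ms2_ref)
  expect_true(is.na(back$ccs_A2[3]))
  expect_true(all(is.na(back$mobility_1k0)))
})

test_that("read_feature_table reports structural problems precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,sample_id,mz", "F1,s1,100"), path)
  expect_error(read_feature_table(path), "missing column")
  writeLines(c(paste("feature_id,sample_id,mz,rt_min,ccs_A2,mobility_1k0",
                     "intensity,snr,ms2_ref", sep = ","),
               "F1,s1,100.1,1.0,,,5,2,",
               "F2,s1,abc,1.0,,,5,2,"), path)
  expect_error(read_feature_table(path), "column 'mz' at data row 2")
  expect_error(read_feature_table("/nonexistent/file.csv"), "no such file")
})

test_that("the packaged stressed-endpoint fixture parses", {
  path <- system.file("extdata", "stressed_day29_features.csv",
                      package = "cannastab")
  ft <- read_feature_table(path)
  expect_identical(nrow(ft), 20L)
  expect_true(315.2319 %in% ft$mz)   # CBD
  expect_true(all(ft$snr > 0))
})

test_that("in-source water-loss pairs are detected from co-elution", {
  ft <- make_features()
  links <- detect_insource_artifacts(ft)
  expect_identical(nrow(links), 1L)
  expect_identical(links$child_id, "F3")
  expect_identical(links$parent_id, "F2")
  expect_identical(links$loss_name, "H2O")
  expect_equal(links$neutral_loss, 18.0105646, tolerance = 1e-4)
})

test_that("artifact linking requires both the mass delta and co-elution", {
  ft <- make_features()
  ft$rt_min[3] <- 2.90  # same masses, elutes 0.14 min away
  expect_identical(nrow(detect_insource_artifacts(ft)), 0L)
  ft$rt_min[3] <- 2.76
  ft$mz[3] <- 329.30    # co-elutes, wrong mass delta
  expect_identical(nrow(detect_insource_artifacts(ft)), 0L)
})

test_that("artifact detection is row-order independent and multi-parent", {
  ft <- make_features()
  # second co-eluting parent for the same child
  extra <- make_features()[2, ]
  extra$feature_id <- "F4"
  extra$rt_min <- 2.77
  ft <- validate_feature_table(rbind(ft, extra))
  links <- detect_insource_artifacts(ft)
  expect_setequal(links$parent_id[links$child_id == "F3"], c("F2", "F4"))
  shuffled <- validate_feature_table(ft[c(3, 1, 4, 2), ])
  links2 <- detect_insource_artifacts(shuffled)
  expect_setequal(paste(links$child_id, links$parent_id),
                  paste(links2$child_id, links2$parent_id))
})

test_that("planted pairs among decoys are recovered exactly", {
  set.seed(7)
  n_true <- 5; n_decoy <- 20
  parent_mz <- runif(n_true, 300, 400)
  parent_rt <- runif(n_true, 2, 10)
  decoy_mz <- runif(n_decoy, 100, 290)    # below every child mass
  decoy_rt <- runif(n_decoy, 2, 10)
  ft <- feature_table(
    feature_id = c(sprintf("P%d", 1:n_true), sprintf("C%d", 1:n_true),
                   sprintf("D%d", 1:n_decoy)),
    sample_id = "s1",
    mz = c(parent_mz, parent_mz - 18.0105646, decoy_mz),
    rt_min = c(parent_rt, parent_rt + 0.01, decoy_rt),
    intensity = 1e5, snr = 500)
  links <- detect_insource_artifacts(ft)
  got <- paste(links$child_id, links$parent_id)
  want <- paste(sprintf("C%d", 1:n_true), sprintf("P%d", 1:n_true))
  expect_setequal(got, want)  # precision = recall = 1
})

test_that("losses must be a named vector", {
  ft <- make_features()
  expect_error(detect_insource_artifacts(ft, losses = numeric()),
               "at least one")
  expect_error(detect_insource_artifacts(ft, losses = c(18.01)),
               "named")
})
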