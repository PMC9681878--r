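frag_ms2 <- function(mz, intensity = rep(100, length(mz)),
                     precursor = 331.23) {
  ms2_spectrum("S", precursor, mz, intensity)
}

unknown <- function(mz, rt) {
  list(feature_id = "U1", mz = mz, rt_min = rt)
}

test_that("the olivetol fragment plus +O labels a hydroxylated product", {
  f <- unknown(ion_mz("C21H30O3"), 3.22)
  cls <- classify_unknown(f, ms2 = frag_ms2(c(193.1228, 135.1169)))
  expect_s3_class(cls, "classified_unknown")
  expect_identical(cls$label, "OH-CBD")
  expect_identical(cls$parent_compound, "CBD")
  expect_identical(cls$confidence, "high")  # elutes well before CBD (4.99)
})

test_that("hydroxylation without earlier elution drops confidence", {
  f <- unknown(ion_mz("C21H30O3"), 4.90)  # inside the 0.3 min RT margin
  cls <- classify_unknown(f, ms2 = frag_ms2(193.1228))
  expect_identical(cls$label, "OH-CBD")
  expect_identical(cls$confidence, "low")
})

test_that("the 205/135 fragment pair labels CBE-type products", {
  f <- unknown(ion_mz("C21H30O4"), 2.76)
  cls <- classify_unknown(f, ms2 = frag_ms2(c(205.1224, 135.0448)))
  expect_identical(cls$label, "OH-CBE")
  expect_identical(cls$parent_compound, "CBE")
  # both published fragments are required, not just one
  half <- classify_unknown(f, ms2 = frag_ms2(205.1224))
  expect_identical(half$label, "unclassified")
})

test_that("the same composition resolves by fragments: diOH-CBD vs OH-CBE", {
  # C21H30O4 is CBD + 2O and also CBE + O; the core fragments decide
  mz <- ion_mz("C21H30O4")
  dioh <- classify_unknown(unknown(mz, 2.13), ms2 = frag_ms2(193.1228))
  expect_identical(dioh$label, "diOH-CBD")
  expect_identical(dioh$parent_compound, "CBD")
  ohcbe <- classify_unknown(unknown(mz, 2.13),
                            ms2 = frag_ms2(c(205.1224, 135.0448)))
  expect_identical(ohcbe$label, "OH-CBE")
})

test_that("CBDH-family spectra are not swallowed by the CBD-core rule", {
  f <- unknown(ion_mz("C22H32O2"), 9.65)
  # CBDH-type spectra contain both the homolog ion and the olivetol ion
  cls <- classify_unknown(f, ms2 = frag_ms2(c(207.1379, 193.1228)))
  expect_identical(cls$label, "CBDH-isomer")
  expect_identical(cls$parent_compound, "CBDH")
})

test_that("same composition as CBE at a distant RT is a CBE isomer", {
  f <- unknown(ion_mz("C21H30O3"), 2.85)
  cls <- classify_unknown(f, ms2 = frag_ms2(c(205.1224, 135.0448)))
  expect_identical(cls$label, "CBE-isomer")
})

test_that("the quinone composition far from HU-331 is HU-331-like", {
  f <- unknown(ion_mz("C21H28O3"), 2.42)
  cls <- classify_unknown(f, ms2 = frag_ms2(311.20, precursor = 329.21))
  expect_identical(cls$label, "HU-331-like")
  expect_identical(cls$parent_compound, "CBD")
  # near the HU-331 reference RT the rule does not fire
  near <- classify_unknown(unknown(ion_mz("C21H28O3"), 9.95),
                           ms2 = frag_ms2(311.20, precursor = 329.21))
  expect_false(identical(near$label, "HU-331-like"))
})

test_that("artifact links take precedence over every chemical rule", {
  links <- data.frame(child_id = "U1", parent_id = "P9",
                      loss_name = "H2O", neutral_loss = 18.0106,
                      rt_delta = 0.01, stringsAsFactors = FALSE)
  f <- unknown(ion_mz("C21H30O3"), 3.22)
  cls <- classify_unknown(f, ms2 = frag_ms2(193.1228), artifacts = links)
  expect_identical(cls$label, "in-source-artifact")
  expect_identical(cls$parent_compound, "P9")
  # multiple co-eluting parents are reported as ambiguous, not resolved
  links2 <- rbind(links, transform(links, parent_id = "P10"))
  cls2 <- classify_unknown(f, ms2 = frag_ms2(193.1228), artifacts = links2)
  expect_identical(cls2$label, "in-source-artifact")
  expect_true(any(grepl("ambiguous", cls2$evidence)))
})

test_that("features without usable evidence stay unclassified", {
  f <- unknown(ion_mz("C21H30O3"), 3.22)
  expect_identical(classify_unknown(f, ms2 = NULL)$label, "unclassified")
  expect_identical(classify_unknown(f, ms2 = frag_ms2(150.0))$label,
                   "unclassified")
  # diagnostic core but a mass delta matching no oxidation level
  odd <- unknown(ion_mz("C21H30O2") + 7, 3.0)
  expect_identical(classify_unknown(odd, ms2 = frag_ms2(193.1228))$label,
                   "unclassified")
})

test_that("the reference set must contain the core parents", {
  f <- unknown(ion_mz("C21H30O3"), 3.22)
  parents <- default_library()
  parents$CBE <- NULL
  expect_error(classify_unknown(f, ms2 = frag_ms2(193.1228),
                                parents = parents), "CBE")
})

test_that("CBE stereoisomers separate by the pseudo-MS3 ion ratio", {
  high <- ms2_spectrum("p", 313.216, c(245.1540, 231.1378), c(100, 20))
  low <- ms2_spectrum("p", 313.216, c(245.1540, 231.1378), c(20, 100))
  even <- ms2_spectrum("p", 313.216, c(245.1540, 231.1378), c(100, 100))
  none <- ms2_spectrum("p", 313.216, 150.0, 100)
  r <- distinguish_cbe_stereoisomer(high)
  expect_identical(r$class, "CBE")
  expect_equal(r$ratio, 5)
  expect_identical(distinguish_cbe_stereoisomer(low)$class, "CBE-isomer")
  expect_identical(distinguish_cbe_stereoisomer(even)$class,
                   "indeterminate")
  n <- distinguish_cbe_stereoisomer(none)
  expect_identical(n$class, "indeterminate")
  expect_true(is.na(n$ratio))
  # the direction of the convention is configurable metadata
  flipped <- distinguish_cbe_stereoisomer(
    high, orientation = c(high = "CBE-isomer", low = "CBE"))
  expect_identical(flipped$class, "CBE-isomer")
  # a missing denominator ion gives an infinite ratio, classified high
  only245 <- ms2_spectrum("p", 313.216, 245.1540, 50)
  expect_identical(distinguish_cbe_stereoisomer(only245)$class, "CBE")
})

test_that("oxidation_series counts levels and checks elution ordering", {
  parent <- default_library()$CBD
  df <- data.frame(
    feature_id = sprintf("F%d", 1:5),
    label = c("diOH-CBD", "diOH-CBD", "OH-CBD", "OH-CBD", "HU-331-like"),
    rt_min = c(2.13, 2.52, 3.22, 3.67, 2.42),
    parent_compound = "CBD", stringsAsFactors = FALSE)
  s <- oxidation_series(df, parent)
  expect_identical(s$parent, "CBD")
  expect_identical(s$counts[["diOH-CBD"]], 2L)
  expect_identical(s$counts[["OH-CBD"]], 2L)
  expect_true(s$rt_ordering_ok)  # all diOH < all OH < parent RT 4.99
  # violate the ordering: one diOH eluting after an OH member
  df$rt_min[2] <- 3.50
  expect_false(oxidation_series(df, parent)$rt_ordering_ok)
  # a series with no hydroxylated members has no ordering to check
  s0 <- oxidation_series(df[5, ], parent)
  expect_true(is.na(s0$rt_ordering_ok))
  # rows belonging to other parents are excluded
  df2 <- df
  df2$parent_compound <- "CBE"
  expect_identical(length(oxidation_series(df2, parent)$counts), 0L)
})
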