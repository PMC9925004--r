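# Biomarkers: activation markers, apparent conduction velocity, ECG
# intervals, difference tables and the Welch comparison.

test_that("activation markers match closed forms", {
  r0 <- fake_result(lat = rep(25, 50))
  am <- activation_markers(r0)
  expect_equal(am$TAT, 25); expect_equal(am$TAT10, 25)
  expect_equal(am$TAT90, 25); expect_equal(am$EDI, 0)

  # linear ramp over uniform volume: uniform LAT distribution
  lat <- seq(0, 100, length.out = 2001)
  am2 <- activation_markers(fake_result(lat))
  expect_equal(am2$TAT, 100)
  expect_equal(am2$TAT10, 10, tolerance = 0.2)
  expect_equal(am2$TAT90, 90, tolerance = 0.2)
  expect_equal(am2$EDI, 100 / sqrt(12), tolerance = 0.05)

  # incomplete activation flags markers undefined
  lat[5] <- NA
  am3 <- activation_markers(fake_result(lat))
  expect_false(am3$complete)
  expect_true(is.na(am3$TAT))

  # volume weighting: concentrating mass at late nodes shifts TAT10/90
  lat4 <- c(rep(0, 10), rep(100, 10))
  w4 <- c(rep(1, 10), rep(9, 10))
  am4 <- activation_markers(fake_result(lat4, mass = w4))
  expect_equal(am4$TAT10, 0)   # 10% of volume reached among early nodes
  expect_equal(am4$TAT90, 100)
})

test_that("apparent CV recovers a planar wave and scales correctly", {
  # flat triangulated sheet with an exact planar activation at 60 cm/s
  g <- expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1))
  nodes <- cbind(g$x, g$y, 0)
  nx <- 11
  faces <- NULL
  for (j in 0:9) for (i in 1:10) {
    a <- i + j * nx; b <- a + 1; cc <- a + nx; dd <- cc + 1
    faces <- rbind(faces, c(a, b, dd), c(a, dd, cc))
  }
  lat <- nodes[, 1] / 60 * 1000 # ms
  res <- fake_result(lat, mesh = list(nodes = nodes, surfaces = NULL))
  res$mesh <- list(nodes = nodes)
  cv <- apparent_cv(res, faces = faces)
  expect_equal(cv, 60, tolerance = 2) # within one bin width
  res2 <- res; res2$lat <- 2 * lat
  expect_equal(apparent_cv(res2, faces = faces), 30, tolerance = 2)
  flat <- res; flat$lat <- rep(5, length(lat))
  expect_error(apparent_cv(flat, faces = faces), "unusable")
})

test_that("ECG interval markers recover constructed landmarks", {
  ecg <- synth_ecg(qrs_end = 95, t_end = 350)
  expect_equal(qrs_duration(ecg, 0), 95, tolerance = 1)
  expect_equal(qt_interval(ecg, 0), 350, tolerance = 2)
  expect_gte(qt_interval(ecg, 0), qrs_duration(ecg, 0))

  flatl <- synth_ecg()
  for (ld in c("LI", "LII", "LIII")) flatl[[ld]] <- 0
  expect_true(is.na(qrs_duration(flatl, 0)))
  expect_true(is.na(qt_interval(flatl, 0)))

  # interval markers are invariant to a global time shift and lead offset
  shifted <- synth_ecg()
  shifted$t_ms <- shifted$t_ms + 40
  for (ld in c("RA", "LA", "LL", "LI", "LII", "LIII"))
    shifted[[ld]] <- shifted[[ld]] + 0.7
  expect_equal(qrs_duration(shifted, 40), 95, tolerance = 1)
  expect_equal(qt_interval(shifted, 40), 350, tolerance = 2)
})

test_that("difference markers reproduce the reference aggregates", {
  tabs <- load_reference_tables()
  mk <- tabs$markers
  diffs <- difference_markers(mk)
  # recomputed female-minus-male QT matches the printed per-heart values
  # on the detailed geometries, averaging 35.00 ms
  det <- diffs$sex_diff[diffs$sex_diff$geometry == "detailed", ]
  expect_equal(mean(det$QT_diff), 35.00, tolerance = 1e-9)
  # the printed smoothed-geometry column averages 40.25 ms
  printed <- mk$QT_diff[!is.na(mk$QT_diff)]
  smoothed_printed <- mk$QT_diff[mk$geometry == "smoothed" & !is.na(mk$QT_diff)]
  expect_equal(mean(smoothed_printed), 40.25)
  # geometry differences recomputed from the marker table
  gd <- diffs$geometry_diff
  expect_equal(mean(gd$TAT_Gdiff),
               mean(tabs$geometry_diffs$TAT_Gdiff), tolerance = 0.11)
  # unmatched pairs are excluded with a message
  expect_message(difference_markers(mk[-1, ]), "unmatched")
})

test_that("Welch comparison matches the closed-form oracle", {
  a <- c(349, 339, 337, 357) # detailed QT, male
  b <- c(391, 376, 364, 391) # detailed QT, female
  w <- welch_ttest(b, a)
  # frozen closed-form Welch values for these groups
  expect_equal(w$t, 4.3637, tolerance = 1e-4)
  expect_equal(w$df, 5.4139, tolerance = 1e-3)
  expect_lt(w$p, 0.05)
  # symmetry and degenerate cases
  w2 <- welch_ttest(a, b)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  same <- welch_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(welch_ttest(1, c(1, 2)))
})
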