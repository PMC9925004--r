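# Reference-table ingestion, the experiment-matrix driver, VTK round
# trips and configuration echoing.

test_that("reference tables ingest with typed schemas", {
  tabs <- load_reference_tables()
  expect_named(tabs, c("models", "hearts", "markers", "ecg_rmsd",
                       "vt_events", "geometry_diffs"))
  expect_equal(tabs$hearts$trabecular_volume_pct, c(16.3, 9.6, 8.7, 10.4))
  # trabecular percentages recompute from the printed pair volumes
  mv <- tabs$models
  for (h in unique(mv$heart)) {
    vd <- mv$myocardial_volume_cm3[mv$heart == h & mv$geometry == "detailed"]
    vs <- mv$myocardial_volume_cm3[mv$heart == h & mv$geometry == "smoothed"]
    expect_equal(round(trabecular_volume_pct(vd, vs), 1),
                 tabs$hearts$trabecular_volume_pct[tabs$hearts$heart == h])
  }
  # per-lead RMSD means
  expect_equal(round(colMeans(tabs$ecg_rmsd[, c("LI", "LII", "LIII")]), 1),
               c(LI = 2.0, LII = 4.9, LIII = 4.3))
  # schema violations name the missing column
  bad <- tempfile()
  dir.create(bad)
  file.copy(list.files(system.file("extdata", package = "cardiosim"),
                       full.names = TRUE), bad)
  mk <- read.csv(file.path(bad, "reference_markers.csv"))
  mk$QT <- NULL
  write.csv(mk, file.path(bad, "reference_markers.csv"), row.names = FALSE)
  expect_error(load_reference_tables(bad), "QT")
})

test_that("a one-cell matrix on the cable yields a complete record", {
  m <- make_cable(2, 0.04)
  out <- run_matrix(list(cable = m), sexes = "male", cycle_length_ms = 340,
                    init_beats = 40)
  expect_equal(nrow(out$records), 1)
  rec <- out$records[1, ]
  expect_equal(rec$activated, 1)
  expect_false(is.na(rec$QRS))
  expect_false(is.na(rec$QT))
  expect_false(is.na(rec$TAT))
  expect_gt(rec$QT, rec$QRS)

  # deterministic stages: an identical re-run reproduces the records
  out2 <- run_matrix(list(cable = m), sexes = "male", cycle_length_ms = 340,
                     init_beats = 40)
  expect_identical(out$records, out2$records)
})

test_that("meshes round-trip through legacy VTK", {
  m <- make_slab(0.4, 0.3, 0.2, dx_cm = 0.1)
  m$region[1:10] <- "border_zone"
  f <- tempfile(fileext = ".vtk")
  write_vtk(m, f, point_data = list(speed = seq_len(nrow(m$nodes)) / 10))
  back <- read_vtk(f)
  expect_equal(back$nodes, m$nodes, tolerance = 1e-12)
  expect_equal(back$elems, m$elems)
  expect_equal(as.character(back$region), as.character(m$region))
  expect_equal(back$phi, m$phi, tolerance = 1e-9)
  expect_equal(back$meta$fields$speed, seq_len(nrow(m$nodes)) / 10,
               tolerance = 1e-9)
})

test_that("run configurations echo through YAML with a mandatory seed", {
  cfg <- list(seed = 7, dx_cm = 0.04, diffusion = list(fiber = 5.8e-3))
  f <- tempfile(fileext = ".yaml")
  save_run_config(cfg, f)
  back <- load_run_config(f)
  expect_equal(back$seed, 7)
  expect_equal(back$diffusion$fiber, 5.8e-3)
  expect_error(save_run_config(list(dx = 1), f), "seed")
})
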