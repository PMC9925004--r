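# Pseudo-ECG: electrode placement, lead closure, linearity, far-field
# scaling and RMSD arithmetic.

test_that("electrode placement is deterministic and outside the tissue", {
  pair <- fx_pair()
  e1 <- electrode_positions(pair$detailed)
  e2 <- electrode_positions(pair$smoothed)
  expect_identical(e1, e2) # shared epicardial outline, same offsets
  for (k in 1:3) {
    dmin <- min(sqrt(colSums((t(pair$detailed$nodes) - e1[k, ])^2)))
    expect_gt(dmin, 1) # comfortably outside the hull
  }
  ovr <- rbind(RA = c(5, 0, 0), LA = c(-5, 0, 0), LL = c(0, -5, 0))
  eo <- electrode_positions(pair$detailed, offsets = ovr)
  expect_equal(rownames(eo), c("RA", "LA", "LL"))
  inside <- rbind(RA = c(0, 0, 0), LA = c(-5, 0, 0), LL = c(0, -5, 0))
  expect_error(electrode_positions(pair$detailed, offsets = inside / 10),
               "inside")
})

test_that("lead closure holds and uniform potentials give zero signal", {
  ecg <- fx_ecg("detailed_male")
  amp <- max(abs(ecg$LII))
  expect_lt(max(abs(ecg$LII - ecg$LI - ecg$LIII)), 1e-9 * amp)

  sr <- fx_slab_run()
  res <- sr$res
  flat <- res
  flat$snapshots <- matrix(42, nrow(sr$mesh$nodes), 3)
  flat$snapshot_times <- 0:2
  e0 <- compute_pseudo_ecg(flat, sr$fib)
  expect_lt(max(abs(as.matrix(e0[, c("RA", "LA", "LL")]))), 1e-9)
})

test_that("the pseudo-ECG is linear in the voltage deviations", {
  sr <- fx_slab_run()
  res <- sr$res
  base <- res$snapshots[, 1]
  scaled <- res
  scaled$snapshots <- base + 3 * (res$snapshots - base)
  resting <- res
  resting$snapshots <- matrix(base, length(base), ncol(res$snapshots))
  e1 <- compute_pseudo_ecg(res, sr$fib)
  e3 <- compute_pseudo_ecg(scaled, sr$fib)
  e0 <- compute_pseudo_ecg(resting, sr$fib)
  # deviations from the resting field scale linearly
  expect_equal(3 * (e1$LII - e0$LII), e3$LII - e0$LII, tolerance = 1e-9)
})

test_that("a compact dipole shows inverse-square far-field decay", {
  m <- make_cable(0.8, 0.04)
  fib <- uniform_fibers(m)
  v <- rep(-85, nrow(m$nodes))
  v[m$nodes[, 1] < 0.4] <- 20 # step front in the middle: compact dipole
  res <- structure(list(mesh = m, snapshots = cbind(v, v),
                        snapshot_times = c(0, 1)),
                   class = "simulation_result")
  amp_at <- function(dist) {
    el <- rbind(RA = c(0.4 + dist, 0.02, 0.02), LA = c(0.4, dist, 0.02),
                LL = c(0.4, 0, dist))
    e <- compute_pseudo_ecg(res, fib, electrodes = el)
    abs(e$RA[1])
  }
  ratio <- amp_at(6) / amp_at(12)
  expect_equal(ratio, 4, tolerance = 0.1)
})

test_that("RMSD arithmetic matches closed forms", {
  ecg <- fx_ecg("detailed_male")
  expect_equal(unname(ecg_rmsd(ecg, ecg)), c(0, 0, 0))
  shifted <- ecg
  for (ld in c("LI", "LII", "LIII")) shifted[[ld]] <- shifted[[ld]] + 0.25
  expect_equal(unname(ecg_rmsd(ecg, shifted)), rep(0.25, 3),
               tolerance = 1e-12)
  other <- ecg
  other$t_ms <- other$t_ms + 1e4
  expect_error(ecg_rmsd(ecg, other), "overlap")
})
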