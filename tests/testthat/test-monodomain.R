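# Monodomain solver: operator assembly, conservation, resting stability,
# causality and region handling.

test_that("diffusion specification validates its entries", {
  spec <- diffusion_spec()
  expect_equal(unname(spec$D["myocardium", ]), c(5.8e-3, 1.9e-3, 1.9e-3))
  expect_equal(unname(spec$D["fast_endo", ]), c(1.7e-2, 5.8e-3, 5.8e-3))
  expect_false(spec$excitable["dense_scar"])
  expect_error(diffusion_spec(myocardium = c(-1, 1, 1) * 1e-3),
               "non-negative")
  expect_error(diffusion_spec(excitable = c(myocardium = TRUE,
                                            fast_endo = TRUE,
                                            trabecula = TRUE,
                                            false_tendon = TRUE,
                                            border_zone = TRUE,
                                            dense_scar = TRUE)),
               "non-excitable")
})

test_that("assembled operators are symmetric, conservative and consistent", {
  m <- make_slab(0.6, 0.4, 0.2, dx_cm = 0.1)
  fib <- uniform_fibers(m)
  ops <- assemble_operators(m, fib)
  expect_true(Matrix::isSymmetric(ops$K))
  expect_lt(max(abs(Matrix::rowSums(ops$K))), 1e-12) # zero-flux null space
  v <- rep(3.7, nrow(m$nodes))
  expect_lt(max(abs(ops$K %*% v)), 1e-10)
  expect_equal(sum(ops$mass), mesh_volume(m), tolerance = 1e-12)

  # isotropic tensor equals the scalar Laplacian regardless of fiber frame
  iso <- diffusion_spec(myocardium = c(2e-3, 2e-3, 2e-3))
  k1 <- assemble_operators(m, fib, iso)$K
  rot <- uniform_fibers(m, axis = c(1, 2, 3))
  k2 <- assemble_operators(m, rot, iso)$K
  expect_lt(max(abs(k1 - k2)), 1e-15)

  bad <- fib
  bad$elem_s <- bad$elem_f
  expect_error(assemble_operators(m, bad), "orthonormal")
})

test_that("resting tissue stays at rest", {
  m <- make_slab(0.6, 0.4, 0.12, dx_cm = 0.06)
  fib <- uniform_fibers(m)
  r <- run_simulation(m, fib, stimuli = list(), n_beats = 1,
                      cycle_length_ms = 600, duration_ms = 100,
                      init_beats = 40)
  v0 <- r$snapshots[, 1]
  drift <- abs(r$snapshots[, ncol(r$snapshots)] - v0)
  expect_lt(max(drift), 0.5)
  expect_equal(nrow(r$events), 0)
})

test_that("cable propagation is causal with a single crossing per node", {
  sr <- fx_slab_run()
  r <- sr$res
  m <- sr$mesh
  expect_equal(activated_fraction(r), 1)
  # local activation time increases monotonically with distance
  x <- m$nodes[, 1]
  ord <- order(x)
  xs <- unique(round(x[ord], 6))
  lat_by_x <- vapply(xs, function(xx) mean(r$lat[abs(x - xx) < 1e-9]), 1.0)
  expect_true(all(diff(lat_by_x) > 0))
  # one upstroke per node within the beat
  expect_lte(max(table(r$events$node)), 1)
  # repolarization follows activation
  both <- !is.na(r$lat) & !is.na(r$rt90)
  expect_true(all(r$rt90[both] > r$lat[both]))
})

test_that("dense scar never produces an upstroke", {
  m <- make_slab(1.6, 1.2, 0.04, dx_cm = 0.04)
  m <- insert_scar(m, c(0.8, 0.6, 0.02), radius_cm = 0.3,
                   border_width_cm = 0.15, channel_width_cm = 0.1)
  fib <- uniform_fibers(m)
  stim <- stimulus_site("edge", which(m$nodes[, 1] <= 0.08), 0, -80, 2)
  r <- run_simulation(m, fib, stimuli = stim, n_beats = 1,
                      cycle_length_ms = 400, duration_ms = 150,
                      init_beats = 40, snapshot_dt_ms = 1)
  # the passive core may drift toward its depolarized boundaries by pure
  # diffusion, but it never produces a regenerative upstroke: its rate of
  # rise stays an order of magnitude below the excitable upstroke rate
  scar_elems <- which(m$region == "dense_scar")
  exc_elems <- which(m$region != "dense_scar")
  exc_nodes <- unique(as.vector(m$elems[exc_elems, ]))
  core_nodes <- setdiff(unique(as.vector(m$elems[scar_elems, ])), exc_nodes)
  expect_gt(length(core_nodes), 0)
  dvdt_max <- function(nodes)
    max(abs(t(diff(t(r$snapshots[nodes, , drop = FALSE])))))
  expect_lt(dvdt_max(core_nodes), 25)       # passive drift (mV/ms)
  expect_gt(dvdt_max(exc_nodes), 80)        # regenerative upstrokes
  # while the surrounding tissue fully activates
  expect_gt(activated_fraction(r), 0.99)
})

test_that("the fast-endocardial layer accelerates endocardial conduction", {
  # 2 cm strip of wall with a one-element endocardial sheet at its base;
  # the far-end arrival time drops when the sheet carries fast diffusion
  m <- make_slab(2, 0.2, 0.12, dx_cm = 0.04)
  bottom <- which((m$nodes[m$elems[, 1], 3] + m$nodes[m$elems[, 2], 3] +
                     m$nodes[m$elems[, 3], 3] + m$nodes[m$elems[, 4], 3]) / 4
                  < 0.04)
  m$region[bottom] <- "fast_endo"
  fib <- uniform_fibers(m)
  stim <- stimulus_site("edge", which(m$nodes[, 1] <= 0.08), 0, -80, 2)
  arrival <- function(spec) {
    r <- run_simulation(m, fib, spec, stimuli = stim, n_beats = 1,
                        cycle_length_ms = 400, duration_ms = 60,
                        init_beats = 40, snapshot_dt_ms = 0)
    max(r$lat, na.rm = TRUE)
  }
  fast <- arrival(diffusion_spec())
  slow <- arrival(diffusion_spec(fast_endo = c(5.8e-3, 1.9e-3, 1.9e-3)))
  expect_gt(slow, fast)
})
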