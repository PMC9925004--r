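# Myocyte model: parameter construction, resting behavior, action
# potential morphology, limit-cycle pacing and APD measurement.

test_that("parameter construction applies cell type, sex and apex-base scaling", {
  base <- cell_parameters("endo", "male", preset = "baseline")
  # male with unit scaling reproduces the published baseline conductances
  expect_equal(unname(base$conductances["GNa"]), 75)
  expect_equal(unname(base$conductances["GKs"]), 0.0034)
  expect_equal(unname(base$conductances["GKr"]), 0.046)

  m <- cell_parameters("epi", "male", 0)
  f <- cell_parameters("epi", "female", 0)
  expect_lt(f$conductances["GKr"], m$conductances["GKr"])
  expect_lt(f$conductances["GKs"], m$conductances["GKs"])
  expect_lt(f$conductances["Gto"], m$conductances["Gto"])

  apex <- cell_parameters("mid", "male", 0)
  bse <- cell_parameters("mid", "male", 1)
  expect_gt(apex$conductances["GKs"], bse$conductances["GKs"])
  same <- setdiff(names(apex$conductances), "GKs")
  expect_equal(apex$conductances[same], bse$conductances[same])

  expect_error(cell_parameters("purkinje"), "cell_type")
  expect_error(cell_parameters("endo", "other"), "sex")
})

test_that("resting state is stable and the paced AP has physiological shape", {
  p <- cell_parameters("endo", "male")
  r <- run_cell_unstimulated(p, 1000)
  drift <- abs(r$trace$V_mV - r$trace$V_mV[1])
  expect_lt(max(drift), 1)

  beat <- pace_cell(p, 600, 1)
  tr <- beat$trace
  expect_gt(max(tr$V_mV), 20)       # overshooting upstroke
  expect_lt(abs(tr$V_mV[1] + 88), 2) # resting potential near -88 mV
  a <- apd(tr$t_ms, tr$V_mV, 0.9)
  expect_gt(a, 150)
  expect_lt(a, 350)
})

test_that("gates stay in [0,1] and concentrations positive over 1e6 steps", {
  p <- cell_parameters("mid", "female")
  r <- pace_cell(p, 500, 10, dt_ms = 5e-3) # 1e6 integration steps
  st <- r$state
  gates <- st[10:38]
  expect_true(all(gates >= 0 & gates <= 1))
  conc <- st[c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")]
  expect_true(all(conc > 0))
})

test_that("ionic_rhs validates its input and balances at rest", {
  p <- cell_parameters("endo", "male")
  st <- cell_initial_state()
  d <- ionic_rhs(st, p, 0)
  expect_length(d, 41)
  expect_lt(abs(d["v"]), 1) # published state is near equilibrium
  bad <- st; bad["cai"] <- NaN
  expect_error(ionic_rhs(bad, p), "cai")
})

test_that("limit-cycle pacing honours its convergence contract", {
  p <- cell_parameters("endo", "male")
  # vacuous tolerance: returns after a single beat
  one <- pace_to_limit_cycle(p, 600, tol_mmol = Inf, max_beats = 10)
  expect_equal(one$n_beats, 1)

  lc <- fx("lc_endo_male", pace_to_limit_cycle(p, 600, tol_mmol = 1e-7,
                                               max_beats = 1500))
  expect_lt(tail(lc$rmse_history, 1), 1e-7)
  # fixed point: restarting from the converged state stays converged
  again <- pace_to_limit_cycle(p, 600, tol_mmol = 1e-7, max_beats = 5,
                               state = lc$state)
  expect_lt(tail(again$rmse_history, 1), 1e-7)
  # the RMSE sequence is eventually decreasing
  h <- lc$rmse_history
  late <- tail(h, 20)
  expect_true(all(diff(late) < 0) || mean(diff(late) < 0) > 0.8)

  expect_error(pace_to_limit_cycle(p, 600, tol_mmol = 1e-30, max_beats = 3),
               class = "cardiosim_convergence_error")
})

test_that("apd recovers constructed durations and rejects flat traces", {
  t <- 0:300
  v <- ifelse(t >= 10 & t < 210, 1, 0) # square pulse, width 200
  expect_equal(apd(t, v, 0.9), 200)
  expect_equal(apd(t, v, 0), 0)
  expect_error(apd(t, rep(0, length(t))), "upstroke")
})
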