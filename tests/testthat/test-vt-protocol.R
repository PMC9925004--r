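# Programmed stimulation: reentry detection and classification on
# constructed activation histories, site localization, capture failure and
# event tallies.

# constructed activation history: n nodes, a direct beat after the last
# stimulus and `k` full re-activations at the given cycle length
synth_history <- function(n = 100, k = 3, cl = 300, last_stim = 1000,
                          frac = 1) {
  ev <- data.frame(node = 1:n, time = last_stim + 10 + seq(0, 5, length.out = n))
  if (k > 0) for (b in 1:k) {
    nb <- round(frac * n)
    ev <- rbind(ev, data.frame(node = 1:nb,
                               time = last_stim + 10 + b * cl +
                                 seq(0, 5, length.out = nb)))
  }
  structure(list(events = ev, excitable = rep(TRUE, n),
                 stim_log = data.frame(onset = last_stim),
                 mesh = NULL),
            class = "simulation_result")
}

test_that("reentry classification follows the three-reactivation rule", {
  # activity extinguishing after the stimulus: no events
  r0 <- synth_history(k = 0)
  expect_length(detect_reentry(r0, ref_nodes = 1:5), 0)

  # exactly three full re-activations classify as sustained
  r3 <- synth_history(k = 3)
  ev3 <- detect_reentry(r3, ref_nodes = 1:5)
  expect_length(ev3, 1)
  expect_equal(ev3[[1]]$kind, "sustained_VT")
  expect_equal(ev3[[1]]$count, 3)
  expect_equal(ev3[[1]]$cycle_lengths_ms, rep(300, 3), tolerance = 1e-6)

  # two re-activations stay nonsustained
  r2 <- synth_history(k = 2)
  ev2 <- detect_reentry(r2, ref_nodes = 1:5)
  expect_equal(ev2[[1]]$kind, "nonsustained_reentry")
  expect_equal(ev2[[1]]$count, 2)

  # variable cycle lengths are reported per beat
  rv <- synth_history(k = 0)
  extra <- do.call(rbind, lapply(cumsum(c(300, 350, 280)), function(off)
    data.frame(node = 1:100, time = 1010 + off + seq(0, 5, length.out = 100))))
  rv$events <- rbind(rv$events, extra)
  evv <- detect_reentry(rv, ref_nodes = 1:5)
  expect_equal(evv[[1]]$cycle_lengths_ms, c(300, 350, 280), tolerance = 1e-6)

  # partial re-activations are wavelets, not events
  rw <- synth_history(k = 1, frac = 0.4)
  expect_message(evw <- detect_reentry(rw, ref_nodes = 1:5), "wavelet")
  expect_length(evw, 0)
})

test_that("reentry sites localize to the earliest-activating region", {
  m <- make_slab(1.0, 0.6, 0.04, dx_cm = 0.04)
  n <- nrow(m$nodes)
  src <- c(0.7, 0.3, 0.02) # known re-activation origin
  dists <- sqrt(colSums((t(m$nodes) - src)^2))
  ev <- rbind(data.frame(node = 1:n, time = 10 + dists),             # direct
              data.frame(node = 1:n, time = 300 + dists / 0.03))    # reentry
  res <- structure(list(events = ev, excitable = rep(TRUE, n),
                        stim_log = data.frame(onset = 0), mesh = m),
                   class = "simulation_result")
  evs <- detect_reentry(res, last_stim_onset_ms = 0, ref_nodes = 1:20)
  expect_length(evs, 1)
  sites <- locate_reentry_sites(res, evs, last_stim_onset_ms = 0)
  expect_equal(nrow(sites), 1)
  expect_lt(sqrt(sum((c(sites$x, sites$y) - src[1:2])^2)), 0.15)
  expect_equal(sites$region, "myocardium")
  # a site in dense scar is impossible: scar nodes never carry events
  expect_false(sites$region == "dense_scar")
})

test_that("an extrastimulus below the refractory period fails to capture", {
  m <- make_slab(0.8, 0.4, 0.04, dx_cm = 0.04)
  fib <- uniform_fibers(m)
  site <- stimulus_site("edge", which(m$nodes[, 1] <= 0.08), 0, -80, 2)
  plan <- stimulation_plan(site = "edge", s1_cycle_length_ms = 400,
                           n_s1 = 1, s2_start_ms = 140, decrement_ms = 20,
                           min_coupling_ms = 140, max_extrastimuli = 1,
                           observe_ms = 250)
  scan <- run_programmed_stimulation(m, site, fib, plan = plan,
                                     init_beats = 40)
  expect_equal(scan$n_trials, 1)
  tr <- scan$trials[[1]]
  expect_false(tail(tr$captured, 1))
  expect_length(tr$events, 0)
  expect_false(scan$sustained)
})

test_that("event tallies reproduce the reference percentages", {
  mk <- function(geometry, sex, site, E, S)
    data.frame(geometry = geometry, sex = sex, site = site,
               event = c(rep(TRUE, E), rep(FALSE, S - E)))
  tt <- rbind(mk("smoothed", "M", "RV_apex", 2, 10),
              mk("smoothed", "M", "RVOT", 1, 9),
              mk("smoothed", "M", "LV_apex", 1, 10),
              mk("detailed", "F", "RV_apex", 2, 13),
              mk("detailed", "F", "RVOT", 0, 12),
              mk("detailed", "F", "LV_apex", 0, 8))
  tab <- tally_events(tt)
  sm <- tab[tab$geometry == "smoothed" & tab$site == "Total", ]
  expect_equal(sm$E, 4); expect_equal(sm$S, 29); expect_equal(sm$percent, 14)
  df <- tab[tab$geometry == "detailed" & tab$site == "Total", ]
  expect_equal(df$E, 2); expect_equal(df$S, 33); expect_equal(df$percent, 6)
  zero <- tab[tab$geometry == "detailed" & tab$site == "RVOT", ]
  expect_equal(zero$percent, 0)
})
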