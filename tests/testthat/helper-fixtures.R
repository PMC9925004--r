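# Shared fixtures, memoised so expensive simulations run once per suite.

.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# default biventricular pair (study conditions: 12% trabecular fraction,
# two false tendons, seed 1)
fx_pair <- function() fx("pair", make_biventricular_pair(0.12, 2, seed = 1))

fx_fibers <- function(which = c("detailed", "smoothed")) {
  which <- match.arg(which)
  fx(paste0("fib_", which), assign_fibers(fx_pair()[[which]]))
}

# sinus runs on the pair (one beat from the paced state; the analysis beat)
fx_sinus <- function(which = c("detailed_male", "smoothed_male",
                               "detailed_female")) {
  which <- match.arg(which)
  fx(paste0("sinus_", which), {
    parts <- strsplit(which, "_")[[1]]
    mesh <- fx_pair()[[parts[1]]]
    fib <- fx_fibers(parts[1])
    run_simulation(mesh, fib, stimuli = place_iars(mesh), sex = parts[2],
                   n_beats = 1, cycle_length_ms = 600, duration_ms = 450,
                   init_beats = 60)
  })
}

fx_ecg <- function(which = "detailed_male") {
  fx(paste0("ecg_", which), {
    parts <- strsplit(which, "_")[[1]]
    compute_pseudo_ecg(fx_sinus(which), fx_fibers(parts[1]))
  })
}

# cable conduction velocities for the diffusion checks
fx_cv <- function(D, dx) {
  fx(sprintf("cv_%g_%g", D, dx), cable_conduction_velocity(D, dx))
}

# a small excitable slab shared by solver and ECG tests
fx_slab_run <- function() {
  fx("slab_run", {
    m <- make_slab(1.2, 0.6, 0.04, dx_cm = 0.04)
    fib <- uniform_fibers(m)
    stim <- stimulus_site("edge", which(m$nodes[, 1] <= 0.08), 0, -80, 2)
    list(mesh = m, fib = fib,
         res = run_simulation(m, fib, stimuli = stim, n_beats = 1,
                              cycle_length_ms = 400, duration_ms = 320,
                              init_beats = 40))
  })
}

# synthetic three-lead trace with a triphasic complex ending exactly at
# `qrs_end` and a T wave ending exactly at `t_end` (1 ms grid)
synth_ecg <- function(qrs_end = 95, t_end = 350, total = 420) {
  t <- 0:total
  mk <- function(scale) {
    v <- numeric(length(t))
    seg <- t >= 5 & t < qrs_end
    v[seg] <- scale * sin(2 * pi * (t[seg] - 5) / 45)
    tw <- t >= 250 & t < t_end
    v[tw] <- 0.3 * scale * sin(pi * (t[tw] - 250) / (t_end - 250))
    v
  }
  ra <- mk(1); la <- mk(1.8); ll <- mk(0.6)
  data.frame(t_ms = t, RA = ra, LA = la, LL = ll,
             LI = la - ra, LII = ll - ra, LIII = ll - la)
}

# minimal simulation-result stand-in for marker unit tests
fake_result <- function(lat, mass = rep(1, length(lat)),
                        excitable = rep(TRUE, length(lat)), mesh = NULL) {
  structure(list(lat = lat, mass = mass, excitable = excitable, mesh = mesh),
            class = "simulation_result")
}
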