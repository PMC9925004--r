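# Anisotropic monodomain solver interface: region-wise diffusion
# specification, P1 finite-element operator assembly, cell-type assignment,
# and the operator-splitting simulation driver (compiled time loop).

#' Region-wise diffusion specification
#'
#' Diffusivities in cm^2/ms along the fiber, sheet (transverse) and normal
#' directions, per region, with excitability flags. Defaults: working
#' myocardium (and trabecular/false-tendon tissue) 5.8e-3 / 1.9e-3 / 1.9e-3;
#' fast-endocardial layer 1.7e-2 / 5.8e-3 / 5.8e-3; border zone isotropic at
#' the normal transverse value (excitable, unmodified ionic parameters);
#' dense scar passive with isotropic diffusion at 10% of the transverse
#' value.
#'
#' @param myocardium,fast_endo,trabecula,false_tendon,border_zone,dense_scar
#'   length-3 numeric vectors `(D_fiber, D_transverse, D_normal)`.
#' @param excitable named logical vector of per-region excitability.
#' @return object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(myocardium = c(5.8e-3, 1.9e-3, 1.9e-3),
                           fast_endo = c(1.7e-2, 5.8e-3, 5.8e-3),
                           trabecula = myocardium,
                           false_tendon = myocardium,
                           border_zone = c(1.9e-3, 1.9e-3, 1.9e-3),
                           dense_scar = rep(0.1 * 1.9e-3, 3),
                           excitable = c(myocardium = TRUE, fast_endo = TRUE,
                                         trabecula = TRUE,
                                         false_tendon = TRUE,
                                         border_zone = TRUE,
                                         dense_scar = FALSE)) {
  D <- rbind(myocardium = myocardium, fast_endo = fast_endo,
             trabecula = trabecula, false_tendon = false_tendon,
             border_zone = border_zone, dense_scar = dense_scar)
  colnames(D) <- c("fiber", "transverse", "normal")
  if (any(D < 0)) stop("diffusivities must be non-negative")
  if (excitable["dense_scar"])
    stop("dense scar must be flagged non-excitable")
  structure(list(D = D, excitable = excitable), class = "diffusion_spec")
}

#' Assemble the discrete diffusion operator and lumped mass
#'
#' Builds the per-element diffusion tensor
#' `D = D_f f f' + D_t s s' + D_n n n'` from the fiber field and the
#' region-wise diffusivities, and assembles the symmetric P1 stiffness
#' matrix (zero-flux boundaries are natural) and the lumped mass vector.
#'
#' @param mesh a `cardiac_mesh`.
#' @param fibers a `fiber_field`.
#' @param diffusion a [diffusion_spec()].
#' @return list with sparse `K` (dgCMatrix), `mass` (node volumes, cm^3)
#'   and element volumes `vol`.
#' @export
assemble_operators <- function(mesh, fibers, diffusion = diffusion_spec()) {
  f <- fibers$elem_f; s <- fibers$elem_s; nn <- fibers$elem_n
  dot <- function(a, b) abs(rowSums(a * b))
  nrm <- function(a) abs(sqrt(rowSums(a^2)) - 1)
  if (max(dot(f, s), dot(f, nn), dot(s, nn)) > 1e-6 ||
      max(nrm(f), nrm(s), nrm(nn)) > 1e-6)
    stop("fiber triads are not orthonormal")
  reg <- as.character(mesh$region)
  Dv <- diffusion$D[reg, , drop = FALSE]
  tens <- function(a) cbind(a[, 1]^2, a[, 2]^2, a[, 3]^2,
                            a[, 1] * a[, 2], a[, 1] * a[, 3], a[, 2] * a[, 3])
  D6 <- Dv[, 1] * tens(f) + Dv[, 2] * tens(s) + Dv[, 3] * tens(nn)
  out <- .fem_assemble(mesh, D6)
  structure(list(K = out$K, mass = out$mass, vol = out$vol),
            class = "monodomain_operators")
}

# per-node cell-type assignment and per-group parameter matrix
.cell_assignment <- function(mesh, sex, preset = "dutta",
                             iks_base_scale = 0.8) {
  n <- nrow(mesh$nodes)
  layer <- as.character(mesh$layer)
  if (is.null(layer)) layer <- rep("endo", n)
  types <- c("endo", "mid", "epi")
  present <- types[types %in% unique(layer)]
  plist <- lapply(present, function(ct)
    cell_parameters(ct, sex, apicobasal_position = 0, preset = preset))
  pmat <- do.call(rbind, lapply(plist, .ord_pvec))
  group <- match(layer, present) - 1L
  # passive nodes: touching only non-excitable elements
  gks <- if (is.null(mesh$z_ab)) rep(1, n) else
    1 - (1 - iks_base_scale) * mesh$z_ab
  list(group = group, pmat = pmat, params = plist, gks_scale = gks,
       types = present)
}

# nodes of excitable tissue (touching at least one excitable element)
.excitable_nodes <- function(mesh, diffusion) {
  exc_reg <- names(diffusion$excitable)[diffusion$excitable]
  exc_elems <- mesh$region %in% exc_reg
  sort(unique(as.vector(mesh$elems[exc_elems, ])))
}

#' Run a monodomain simulation
#'
#' Operator-splitting integration (reaction via Rush-Larsen at every
#' excitable node, explicit lumped-mass FEM diffusion) with stimuli
#' repeated over `n_beats` pacing cycles. Nodes are initialized from the
#' single-cell paced state of their transmural cell type and sex. Local
#' activation times (first upward crossing of 0 mV) and 90% repolarization
#' times are extracted for the analysis beat (the last one).
#'
#' @param mesh a `cardiac_mesh`.
#' @param fibers a `fiber_field`; defaults to [uniform_fibers()] for cable
#'   and slab meshes and [assign_fibers()] for biventricular meshes.
#' @param diffusion a [diffusion_spec()].
#' @param stimuli list of [stimulus_site()] objects (onsets relative to each
#'   beat).
#' @param sex `"male"` or `"female"`.
#' @param n_beats number of pacing cycles; the last is analyzed.
#' @param cycle_length_ms pacing cycle length.
#' @param duration_ms total simulated time (default `n_beats * cycle_length`).
#' @param dt_ms operator-splitting timestep (ms).
#' @param snapshot_dt_ms V_m snapshot cadence (ms); 0 disables snapshots.
#' @param preset cell-model conductance preset.
#' @param init_beats single-cell pre-pacing beats used to initialize tissue
#'   nodes.
#' @param quiesce_stop stop early once the tissue is fully repolarized after
#'   the last stimulus (used by the tachycardia protocol).
#' @return object of class `simulation_result` with fields `lat`, `rt90`,
#'   `events`, `snapshots`, `snapshot_times`, `excitable`, `mass`,
#'   `stim_log`, `mesh`, `config`.
#' @export
run_simulation <- function(mesh, fibers = NULL, diffusion = diffusion_spec(),
                           stimuli, sex = c("male", "female"), n_beats = 1,
                           cycle_length_ms = 600, duration_ms = NULL,
                           dt_ms = 0.01, snapshot_dt_ms = 1,
                           preset = "dutta", init_beats = 150,
                           quiesce_stop = FALSE) {
  sex <- match.arg(sex)
  if (is.null(fibers)) {
    fibers <- if (!is.null(mesh$meta$kind) && mesh$meta$kind == "biventricular")
      assign_fibers(mesh) else uniform_fibers(mesh)
  }
  if (is.null(duration_ms)) duration_ms <- n_beats * cycle_length_ms
  ops <- assemble_operators(mesh, fibers, diffusion)
  ca <- .cell_assignment(mesh, sex, preset)
  n <- nrow(mesh$nodes)

  exc <- .excitable_nodes(mesh, diffusion)
  group <- ca$group
  passive <- setdiff(seq_len(n), exc)
  group[passive] <- -1L

  # initial states from the paced single-cell limit cycle of each type
  states <- matrix(0, n, 41)
  for (gi in seq_along(ca$params)) {
    st <- limit_cycle_state(ca$params[[gi]], cycle_length_ms,
                            n_beats = init_beats)
    rows <- which(group == gi - 1L)
    states[rows, ] <- matrix(rep(st, length(rows)), ncol = 41, byrow = TRUE)
  }
  if (length(passive))
    states[passive, ] <- matrix(rep(cell_initial_state(), length(passive)),
                                ncol = 41, byrow = TRUE)

  # stimulus trains: each site repeated every cycle
  if (inherits(stimuli, "stimulus_site")) stimuli <- list(stimuli)
  trains <- list()
  for (b in seq_len(n_beats)) {
    off <- (b - 1) * cycle_length_ms
    for (stim in stimuli) {
      trains[[length(trains) + 1]] <-
        list(nodes = stim$nodes, onset = stim$onset + off,
             dur = stim$duration, amp = stim$amplitude, label = stim$label)
    }
  }
  .run_tissue(mesh, ops, group, ca, states, trains, duration_ms, dt_ms,
              snapshot_dt_ms, quiesce_stop,
              analysis_start = (n_beats - 1) * cycle_length_ms,
              config = list(sex = sex, n_beats = n_beats,
                            cycle_length_ms = cycle_length_ms,
                            dt_ms = dt_ms, preset = preset,
                            diffusion = diffusion))
}

# shared driver used by run_simulation and the programmed-stimulation scans
.run_tissue <- function(mesh, ops, group, ca, states, trains, duration_ms,
                        dt_ms, snapshot_dt_ms, quiesce_stop, analysis_start,
                        config) {
  Kc <- methods::as(ops$K, "CsparseMatrix") # symmetric: CSC == CSR
  stim_ptr <- c(0L, cumsum(vapply(trains, function(s) length(s$nodes), 1L)))
  stim_node <- unlist(lapply(trains, function(s) s$nodes)) - 1L
  if (is.null(stim_node)) stim_node <- integer(0)
  onsets <- vapply(trains, function(s) s$onset, 1)
  durs <- vapply(trains, function(s) s$dur, 1)
  amps <- vapply(trains, function(s) s$amp, 1)
  last_stim_end <- if (length(onsets)) max(onsets + durs) else 0

  out <- monodomain_run_cpp(
    ia = Kc@p, ja = Kc@i, ka = Kc@x, mass = ops$mass,
    group = as.integer(group), pmat = ca$pmat, gks_scale = ca$gks_scale,
    states = states,
    stim_ptr = as.integer(stim_ptr), stim_node = as.integer(stim_node),
    stim_onset = onsets, stim_dur = durs, stim_amp = amps,
    dt = dt_ms, duration = duration_ms, snapshot_dt = snapshot_dt_ms,
    quiesce_stop = quiesce_stop, last_stim_end = last_stim_end)

  events <- data.frame(node = out$event_node, time = out$event_time)
  n <- nrow(mesh$nodes)
  lat <- rep(NA_real_, n)
  win <- events$time >= analysis_start
  if (any(win)) {
    ev <- events[win, ]
    ev <- ev[order(ev$time), ]
    first <- !duplicated(ev$node)
    lat[ev$node[first]] <- ev$time[first] - analysis_start
  }
  snaps <- out$snapshots
  stimes <- out$snapshot_times
  rt90 <- .rt90_from_snapshots(snaps, stimes, lat, analysis_start)

  structure(list(
    lat = lat, rt90 = rt90, events = events,
    snapshots = snaps, snapshot_times = stimes,
    final_states = out$states,
    excitable = group >= 0L, mass = ops$mass,
    stim_log = data.frame(
      label = vapply(trains, function(s) as.character(s$label), ""),
      onset = vapply(trains, function(s) s$onset, 1),
      duration = vapply(trains, function(s) s$dur, 1),
      amplitude = vapply(trains, function(s) s$amp, 1),
      n_nodes = vapply(trains, function(s) length(s$nodes), 1L)),
    analysis_start = analysis_start,
    stopped_early = out$stopped_early, t_end = out$t_end,
    n_substeps = out$n_substeps,
    mesh = mesh, config = config
  ), class = "simulation_result")
}

# 90% repolarization time per node from the snapshot history
.rt90_from_snapshots <- function(snaps, stimes, lat, analysis_start) {
  n <- length(lat)
  rt90 <- rep(NA_real_, n)
  if (is.null(snaps) || !length(stimes)) return(rt90)
  w <- which(stimes >= analysis_start)
  if (!length(w)) return(rt90)
  S <- snaps[, w, drop = FALSE]
  ts <- stimes[w]
  base <- S[, 1]
  act <- which(!is.na(lat))
  for (i in act) {
    row <- S[i, ]
    ip <- which.max(row)
    thr <- row[ip] - 0.9 * (row[ip] - base[i])
    rec <- which(seq_along(row) > ip & row <= thr)
    if (length(rec)) rt90[i] <- ts[rec[1]] - analysis_start
  }
  rt90
}

#' @export
print.simulation_result <- function(x, ...) {
  act <- mean(!is.na(x$lat[x$excitable]))
  cat("<simulation_result> ", length(x$lat), " nodes, t_end = ", x$t_end,
      " ms; ", round(100 * act, 1), "% of excitable nodes activated\n",
      sep = "")
  invisible(x)
}

#' Planar conduction velocity on a cable
#'
#' Stimulates one end of a pseudo-1D cable and measures the conduction
#' velocity between the points at 25% and 75% of its length, using the
#' baseline male endocardial myocyte model. The workhorse of the diffusion
#' parameterization checks.
#'
#' @param D_cm2_ms diffusivity along the cable (cm^2/ms).
#' @param dx_cm element size.
#' @param length_cm cable length.
#' @param sex phenotype.
#' @param init_beats single-cell pre-pacing beats for the initial state.
#' @param duration_ms simulated time (must cover the transit).
#' @return conduction velocity in cm/s (`NA` if the wave fails to reach
#'   the distal measurement point).
#' @export
cable_conduction_velocity <- function(D_cm2_ms = 5.8e-3, dx_cm = 0.04,
                                      length_cm = 2, sex = "male",
                                      init_beats = 60, duration_ms = 80) {
  mesh <- make_cable(length_cm, dx_cm)
  fib <- uniform_fibers(mesh)
  spec <- diffusion_spec(myocardium = rep(D_cm2_ms, 3))
  stim <- stimulus_site("end", which(mesh$nodes[, 1] <= 0.1 + 1e-9),
                        0, -80, 2)
  r <- run_simulation(mesh, fib, spec, stim, sex = sex, n_beats = 1,
                      cycle_length_ms = 600,
                      duration_ms = duration_ms, init_beats = init_beats,
                      snapshot_dt_ms = 0)
  x <- mesh$nodes[, 1]
  i25 <- which.min(abs(x - 0.25 * length_cm))
  i75 <- which.min(abs(x - 0.75 * length_cm))
  lat <- r$lat
  if (is.na(lat[i25]) || is.na(lat[i75])) return(NA_real_)
  (x[i75] - x[i25]) / (lat[i75] - lat[i25]) * 1000
}

#' Fraction of excitable nodes activated in the analysis window
#' @param result a `simulation_result`.
#' @return fraction in `[0, 1]`.
#' @export
activated_fraction <- function(result) {
  mean(!is.na(result$lat[result$excitable]))
}
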