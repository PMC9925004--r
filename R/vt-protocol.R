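# Programmed electrical stimulation (Josephson-style S1-S2-S3-S4 scan),
# reentry detection and classification, reentry-site localization, and
# event tallies.
#
# The drive train is simulated once per site and the tissue state after the
# last S1 is reused across extrastimulus trials, which makes the
# decremental scan affordable at desk scale.

#' Programmed-stimulation plan
#'
#' @param site pacing-site label (`"LV_apex"`, `"RV_apex"`, `"RVOT"`, or any
#'   label when the site nodes are supplied directly).
#' @param s1_cycle_length_ms basic drive cycle length (default 400 ms).
#' @param n_s1 number of drive beats.
#' @param s2_start_ms initial S2 coupling interval.
#' @param decrement_ms coupling-interval decrement.
#' @param min_coupling_ms shortest coupling interval scanned.
#' @param max_extrastimuli up to S4 (3 extrastimuli).
#' @param restart_offset_ms when a new extrastimulus level opens, its first
#'   coupling interval is the previous level's fixed interval plus this
#'   offset.
#' @param amplitude,duration_ms stimulus strength.
#' @param observe_ms observation window after the last extrastimulus.
#' @return object of class `stimulation_plan`.
#' @export
stimulation_plan <- function(site = "RV_apex", s1_cycle_length_ms = 400,
                             n_s1 = 6, s2_start_ms = 340, decrement_ms = 10,
                             min_coupling_ms = 180, max_extrastimuli = 3,
                             restart_offset_ms = 20, amplitude = -80,
                             duration_ms = 1, observe_ms = 1500) {
  stopifnot(s2_start_ms > 0, min_coupling_ms > 0,
            s2_start_ms >= min_coupling_ms,
            s1_cycle_length_ms > duration_ms)
  structure(list(site = site, s1_cycle_length_ms = s1_cycle_length_ms,
                 n_s1 = n_s1, s2_start_ms = s2_start_ms,
                 decrement_ms = decrement_ms,
                 min_coupling_ms = min_coupling_ms,
                 max_extrastimuli = max_extrastimuli,
                 restart_offset_ms = restart_offset_ms,
                 amplitude = amplitude, duration_ms = duration_ms,
                 observe_ms = observe_ms),
            class = "stimulation_plan")
}

# reference patch for cycle-length measurement: surface nodes around the
# point farthest from the stimulus site
.reference_patch <- function(mesh, stim_nodes, radius = 0.15) {
  cand <- if (!is.null(mesh$surfaces))
    unique(as.vector(mesh$surfaces$epi$faces)) else seq_len(nrow(mesh$nodes))
  ctr <- colMeans(mesh$nodes[stim_nodes, , drop = FALSE])
  d <- sqrt(colSums((t(mesh$nodes[cand, , drop = FALSE]) - ctr)^2))
  far <- mesh$nodes[cand[which.max(d)], ]
  cand[sqrt(colSums((t(mesh$nodes[cand, , drop = FALSE]) - far)^2)) <= radius]
}

#' Detect reentrant activations after programmed stimulation
#'
#' Full-tissue re-activations occurring after the final stimulus with no
#' external source. A re-activation counts as full when at least
#' `min_fraction` of the excitable nodes activate in that cycle; partial
#' re-activations between `wavelet_fraction` and `min_fraction` are logged
#' as wavelets and not counted. Three or more full reentrant activations
#' classify as sustained ventricular tachycardia.
#'
#' @param result a `simulation_result`.
#' @param last_stim_onset_ms onset of the final stimulus (default: from the
#'   stimulus log).
#' @param ref_nodes node set used to measure per-beat cycle lengths.
#' @param min_fraction threshold for a full re-activation (default 0.9).
#' @param wavelet_fraction lower threshold for logging wavelets.
#' @return list of arrhythmia events (length 0 or 1): each has `kind`
#'   (`"sustained_VT"` or `"nonsustained_reentry"`), `count`,
#'   `cycle_lengths_ms`, `beat_times_ms` and `n_wavelets`.
#' @export
detect_reentry <- function(result, last_stim_onset_ms = NULL,
                           ref_nodes = NULL, min_fraction = 0.9,
                           wavelet_fraction = 0.3) {
  if (is.null(last_stim_onset_ms))
    last_stim_onset_ms <- max(result$stim_log$onset)
  ev <- result$events
  ev <- ev[ev$time > last_stim_onset_ms & ev$node %in%
             which(result$excitable), , drop = FALSE]
  n_exc <- sum(result$excitable)
  if (!nrow(ev)) return(list())
  ev <- ev[order(ev$node, ev$time), ]
  rank <- sequence(rle(ev$node)$lengths)
  kmax <- max(rank)
  frac <- vapply(seq_len(kmax), function(k) sum(rank == k) / n_exc, 1.0)
  # beat 1 is the direct response to the final stimulus
  full <- which(frac >= min_fraction)
  reentrant <- full[full >= 2L]
  n_wavelets <- sum(frac >= wavelet_fraction & frac < min_fraction &
                      seq_len(kmax) >= 2L)
  if (!length(reentrant)) {
    if (n_wavelets > 0)
      message("detect_reentry: ", n_wavelets,
              " partial re-activation(s) logged as wavelets")
    return(list())
  }
  # consecutive full re-activations starting at beat 2
  count <- 0L
  for (k in 2L:kmax) {
    if (k %in% reentrant) count <- count + 1L else break
  }
  if (is.null(ref_nodes)) {
    stim_nodes <- which(result$excitable)[1]
    ref_nodes <- .reference_patch(result$mesh, stim_nodes)
  }
  beat_times <- vapply(seq_len(count + 1L), function(k) {
    sel <- ev$node %in% ref_nodes & rank == k
    if (any(sel)) mean(ev$time[sel]) else NA_real_
  }, 1.0)
  cls <- diff(beat_times)
  list(list(
    kind = if (count >= 3L) "sustained_VT" else "nonsustained_reentry",
    count = count,
    cycle_lengths_ms = unname(cls[is.finite(cls)]),
    beat_times_ms = beat_times,
    n_wavelets = n_wavelets))
}

# node adjacency list from the tetrahedral connectivity
.node_adjacency <- function(mesh) {
  el <- mesh$elems
  pairs <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                 el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  pairs <- rbind(pairs, pairs[, 2:1])
  split(pairs[, 2], pairs[, 1])
}

#' Locate the earliest-activating region of each reentrant beat
#'
#' For each reentrant cycle, the centroid of the earliest-activating
#' connected node set initiating that cycle, classified by region label and
#' by transmural position (endocardial, epicardial or transmural via the
#' transmural coordinate).
#'
#' @param result a `simulation_result`.
#' @param events output of [detect_reentry()].
#' @param last_stim_onset_ms onset of the final stimulus.
#' @param window_ms width of the "earliest" window within a cycle.
#' @return data.frame with one row per reentrant beat: centroid coordinates,
#'   majority region, and surface classification.
#' @export
locate_reentry_sites <- function(result, events, last_stim_onset_ms = NULL,
                                 window_ms = 10) {
  if (!length(events)) return(NULL)
  if (is.null(last_stim_onset_ms))
    last_stim_onset_ms <- max(result$stim_log$onset)
  mesh <- result$mesh
  ev <- result$events
  ev <- ev[ev$time > last_stim_onset_ms & ev$node %in%
             which(result$excitable), , drop = FALSE]
  ev <- ev[order(ev$node, ev$time), ]
  rank <- sequence(rle(ev$node)$lengths)
  adj <- .node_adjacency(mesh)
  node_region <- rep(NA_character_, nrow(mesh$nodes))
  for (rg in levels(mesh$region)) {
    nds <- unique(as.vector(mesh$elems[mesh$region == rg, ]))
    node_region[nds] <- rg # later regions override; scar labels win
  }
  out <- NULL
  for (k in seq_len(events[[1]]$count) + 1L) {
    sel <- rank == k
    if (!any(sel)) next
    nodes_k <- ev$node[sel]
    times_k <- ev$time[sel]
    t0 <- min(times_k)
    early <- nodes_k[times_k <= t0 + window_ms]
    # connected component containing the earliest node
    seedn <- nodes_k[which.min(times_k)]
    inset <- rep(FALSE, nrow(mesh$nodes)); inset[early] <- TRUE
    comp <- integer(0); queue <- seedn; seen <- rep(FALSE, nrow(mesh$nodes))
    seen[seedn] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      nb <- adj[[as.character(cur)]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    ctr <- colMeans(mesh$nodes[comp, , drop = FALSE])
    regs <- node_region[comp]
    reg <- names(sort(table(regs), decreasing = TRUE))[1]
    mphi <- mean(mesh$phi[comp])
    surf <- if (mphi < 0.3) "endo" else if (mphi > 0.7) "epi" else
      "transmural"
    out <- rbind(out, data.frame(beat = k - 1L, x = ctr[1], y = ctr[2],
                                 z = ctr[3], region = reg, surface = surf,
                                 onset_ms = t0))
  }
  out
}

#' Run the programmed electrical stimulation scan
#'
#' Simulates the S1 drive train once, then scans decremental S2 (adding S3
#' and S4 levels when the scan reaches refractoriness or the minimum
#' coupling interval without induction), restarting each trial from the
#' saved post-drive tissue state. A branch stops at the first sustained
#' ventricular tachycardia, mirroring clinical practice.
#'
#' @param mesh a `cardiac_mesh` carrying the scar substrate.
#' @param site a [stimulus_site()]; or a site label resolvable by
#'   [place_pacing_site()] on biventricular meshes.
#' @param fibers a `fiber_field` (defaults as in [run_simulation()]).
#' @param diffusion a [diffusion_spec()].
#' @param sex phenotype.
#' @param plan a [stimulation_plan()].
#' @param dt_ms timestep.
#' @param init_beats single-cell pre-pacing beats at the S1 cycle length.
#' @param capture_fraction minimal activated fraction for an extrastimulus
#'   to count as captured.
#' @return object of class `pes_scan`: list with `trials` (one entry per
#'   trial: couplings, capture flags, events, sustained), `site`, `plan`,
#'   and `drive` information.
#' @export
run_programmed_stimulation <- function(mesh, site, fibers = NULL,
                                       diffusion = diffusion_spec(),
                                       sex = c("male", "female"),
                                       plan = stimulation_plan(),
                                       dt_ms = 0.01, init_beats = 150,
                                       capture_fraction = 0.3) {
  sex <- match.arg(sex)
  if (is.character(site)) site <- place_pacing_site(mesh, site)
  if (is.null(fibers)) {
    fibers <- if (!is.null(mesh$meta$kind) && mesh$meta$kind == "biventricular")
      assign_fibers(mesh) else uniform_fibers(mesh)
  }
  ops <- assemble_operators(mesh, fibers, diffusion)
  ca <- .cell_assignment(mesh, sex)
  n <- nrow(mesh$nodes)
  group <- ca$group
  exc <- .excitable_nodes(mesh, diffusion)
  passive <- setdiff(seq_len(n), exc)
  group[passive] <- -1L

  cl <- plan$s1_cycle_length_ms
  states <- matrix(0, n, 41)
  for (gi in seq_along(ca$params)) {
    st <- limit_cycle_state(ca$params[[gi]], cl, n_beats = init_beats)
    rows <- which(group == gi - 1L)
    states[rows, ] <- matrix(rep(st, length(rows)), ncol = 41, byrow = TRUE)
  }
  if (length(passive))
    states[passive, ] <- matrix(rep(cell_initial_state(), length(passive)),
                                ncol = 41, byrow = TRUE)

  mkstim <- function(onset) list(nodes = site$nodes, onset = onset,
                                 dur = plan$duration_ms,
                                 amp = plan$amplitude, label = site$label)
  # drive phase: n_s1 beats, state saved just after the last S1
  pad <- 2
  drive_trains <- lapply((seq_len(plan$n_s1) - 1) * cl, mkstim)
  drive <- .run_tissue(mesh, ops, group, ca, states, drive_trains,
                       duration_ms = (plan$n_s1 - 1) * cl + pad,
                       dt_ms = dt_ms, snapshot_dt_ms = 0,
                       quiesce_stop = FALSE, analysis_start = 0,
                       config = list(stage = "drive"))
  # verify S1 capture on the last beat
  last_s1 <- (plan$n_s1 - 1) * cl
  s1_resp <- drive$events[drive$events$time > last_s1 - cl / 2, ]
  drive_states <- .last_states(drive)
  ref_nodes <- .reference_patch(mesh, site$nodes)

  trial_fn <- function(couplings) {
    onsets <- cumsum(couplings) - pad
    trains <- lapply(onsets, mkstim)
    res <- .run_tissue(mesh, ops, group, ca, drive_states, trains,
                       duration_ms = max(onsets) + plan$observe_ms,
                       dt_ms = dt_ms, snapshot_dt_ms = 0,
                       quiesce_stop = TRUE, analysis_start = 0,
                       config = list(stage = "trial", couplings = couplings))
    captured <- vapply(seq_along(onsets), function(k) {
      resp <- res$events$time > onsets[k] &
        res$events$time <= onsets[k] + min(couplings[k], 200)
      sum(resp) / length(exc) >= capture_fraction
    }, TRUE)
    evs <- if (captured[length(captured)])
      detect_reentry(res, last_stim_onset_ms = max(onsets),
                     ref_nodes = ref_nodes) else list()
    list(couplings = couplings, captured = captured, events = evs,
         sustained = length(evs) > 0 && evs[[1]]$kind == "sustained_VT",
         n_events = length(evs), result = res)
  }

  trials <- list()
  fixed <- numeric(0)
  ci <- plan$s2_start_ms
  level <- 1L
  sustained_found <- FALSE
  while (!sustained_found && level <= plan$max_extrastimuli) {
    tr <- trial_fn(c(fixed, ci))
    tr$result <- NULL # keep the scan light; events are retained
    trials[[length(trials) + 1]] <- tr
    if (tr$sustained) { sustained_found <- TRUE; break }
    lastcap <- tr$captured[length(tr$captured)]
    if (!lastcap || ci - plan$decrement_ms < plan$min_coupling_ms) {
      # refractoriness (ERP) or floor reached: fix this level, open the next
      fixed_ci <- if (!lastcap) ci + plan$decrement_ms else ci
      fixed <- c(fixed, fixed_ci)
      level <- level + 1L
      ci <- min(fixed_ci + plan$restart_offset_ms, plan$s2_start_ms)
    } else {
      ci <- ci - plan$decrement_ms
    }
  }
  structure(list(trials = trials, site = site$label, plan = plan, sex = sex,
                 n_trials = length(trials),
                 sustained = sustained_found,
                 s1_captured = nrow(s1_resp) / length(exc) > 0.5),
            class = "pes_scan")
}

# reconstruct the state matrix from a tissue run
.last_states <- function(result) {
  # .run_tissue stores the final state matrix via the compiled driver
  result$final_states
}

#' @export
print.pes_scan <- function(x, ...) {
  cat("<pes_scan> site ", x$site, ", ", x$n_trials, " trials, sustained VT: ",
      x$sustained, "\n", sep = "")
  invisible(x)
}

#' Tally arrhythmic events across programmed-stimulation trials
#'
#' @param trial_table data.frame with one row per trial and columns
#'   `geometry`, `sex`, `site`, and logical `event`.
#' @return data.frame of E (events), S (simulations) and integer
#'   percentages per (geometry, sex, site), plus per-(geometry, sex) totals.
#' @export
tally_events <- function(trial_table) {
  stopifnot(all(c("geometry", "sex", "site", "event") %in%
                  names(trial_table)))
  agg <- aggregate(event ~ geometry + sex + site, data = trial_table,
                   FUN = function(x) c(E = sum(x), S = length(x)))
  out <- data.frame(geometry = agg$geometry, sex = agg$sex, site = agg$site,
                    E = agg$event[, "E"], S = agg$event[, "S"])
  tot <- aggregate(cbind(E, S) ~ geometry + sex, data = out, FUN = sum)
  tot$site <- "Total"
  out <- rbind(out, tot[, names(out)])
  out$percent <- round(100 * out$E / out$S)
  out
}
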