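# Pseudo-ECG forward computation: extracellular potential estimates at
# distant field points from the volume integral of the diffusion-weighted
# transmembrane-voltage gradient (infinite homogeneous medium, no torso
# conductivity), and limb-lead synthesis.

#' Limb electrode positions for a mesh
#'
#' Places right-arm (RA), left-arm (LA) and left-leg (LL) field points at
#' configurable offsets relative to the heart's bounding box (offsets are in
#' units of the largest bounding-box extent). The same offsets produce
#' identical coordinates for both members of a detailed/smoothed pair since
#' the pair shares the epicardial outline.
#'
#' @param mesh a `cardiac_mesh`.
#' @param offsets 3 x 3 matrix (rows RA, LA, LL) of relative offsets.
#' @return 3 x 3 matrix of electrode coordinates (cm), rows RA, LA, LL.
#' @export
electrode_positions <- function(mesh,
                                offsets = rbind(RA = c(1.6, 0.9, 1.2),
                                                LA = c(-1.6, 0.9, 1.2),
                                                LL = c(-1.1, -0.6, -1.8))) {
  stopifnot(is.matrix(offsets), nrow(offsets) == 3, ncol(offsets) == 3)
  bb_min <- apply(mesh$nodes, 2, min)
  bb_max <- apply(mesh$nodes, 2, max)
  ctr <- (bb_min + bb_max) / 2
  L <- max(bb_max - bb_min)
  pos <- sweep(offsets * L, 2, ctr, "+")
  rownames(pos) <- c("RA", "LA", "LL")
  # electrodes must lie outside the tissue
  for (k in 1:3) {
    d <- sqrt(colSums((t(mesh$nodes) - pos[k, ])^2))
    if (min(d) < mesh$dx)
      stop("electrode ", rownames(pos)[k], " lies inside the myocardium")
  }
  pos
}

# per-electrode linear weight vector w such that phi_e(t) = w . V(t)
.ecg_weights <- function(mesh, fibers, diffusion, electrodes) {
  eg <- .elem_gradients(mesh)
  reg <- as.character(mesh$region)
  Dv <- diffusion$D[reg, , drop = FALSE]
  f <- fibers$elem_f; s <- fibers$elem_s; nn <- fibers$elem_n
  tens <- function(a) cbind(a[, 1]^2, a[, 2]^2, a[, 3]^2,
                            a[, 1] * a[, 2], a[, 1] * a[, 3], a[, 2] * a[, 3])
  D6 <- Dv[, 1] * tens(f) + Dv[, 2] * tens(s) + Dv[, 3] * tens(nn)
  cent <- .elem_centroids(mesh)
  n <- nrow(mesh$nodes)
  W <- matrix(0, nrow(electrodes), n)
  for (e in seq_len(nrow(electrodes))) {
    rel <- sweep(cent, 2, electrodes[e, ])
    r <- sqrt(rowSums(rel^2))
    r <- pmax(r, mesh$dx / 2) # guard against electrode-on-centroid
    ginv <- -rel / r^3 # gradient of 1/r at the centroid
    for (i in 1:4) {
      gi <- eg$g[[i]]
      Dg <- cbind(D6[, 1] * gi[, 1] + D6[, 4] * gi[, 2] + D6[, 5] * gi[, 3],
                  D6[, 4] * gi[, 1] + D6[, 2] * gi[, 2] + D6[, 6] * gi[, 3],
                  D6[, 5] * gi[, 1] + D6[, 6] * gi[, 2] + D6[, 3] * gi[, 3])
      contrib <- -eg$vol * rowSums(Dg * ginv)
      acc <- tapply(contrib, mesh$elems[, i], sum)
      idx <- as.integer(names(acc))
      W[e, idx] <- W[e, idx] + as.numeric(acc)
    }
  }
  W
}

#' Compute the pseudo-ECG of a simulation
#'
#' For each electrode x' and snapshot time,
#' `phi_e(x') = -sum_elements [D grad(V_m)] . grad(1/||x - x'||) vol`,
#' evaluated at element centroids, followed by limb-lead synthesis
#' (LI = LA - RA, LII = LL - RA, LIII = LL - LA). Amplitudes carry an
#' arbitrary global scale (no torso conductivity) and are reported in
#' mV-equivalent model units.
#'
#' @param result a `simulation_result` with V_m snapshots at <= 1 ms cadence.
#' @param fibers the `fiber_field` used in the simulation.
#' @param diffusion the [diffusion_spec()] used in the simulation.
#' @param electrodes electrode matrix from [electrode_positions()].
#' @return object of class `ecg_trace`: data.frame with columns `t_ms`,
#'   `RA`, `LA`, `LL`, `LI`, `LII`, `LIII`.
#' @export
compute_pseudo_ecg <- function(result, fibers, diffusion = diffusion_spec(),
                               electrodes = electrode_positions(result$mesh)) {
  if (is.null(result$snapshots)) stop("simulation carries no V_m snapshots")
  W <- .ecg_weights(result$mesh, fibers, diffusion, electrodes)
  phi <- W %*% result$snapshots
  tr <- data.frame(t_ms = result$snapshot_times,
                   RA = phi[1, ], LA = phi[2, ], LL = phi[3, ])
  tr$LI <- tr$LA - tr$RA
  tr$LII <- tr$LL - tr$RA
  tr$LIII <- tr$LL - tr$LA
  structure(tr, class = c("ecg_trace", "data.frame"),
            electrodes = electrodes)
}

#' Root-mean-squared difference between two pseudo-ECG traces
#'
#' Traces are resampled onto the common part of their time grids before the
#' per-lead RMSD is computed.
#'
#' @param a,b `ecg_trace` objects (or data.frames with `t_ms` and lead
#'   columns).
#' @param leads lead columns to compare.
#' @return named vector of per-lead RMSD values (mV).
#' @export
ecg_rmsd <- function(a, b, leads = c("LI", "LII", "LIII")) {
  t0 <- max(min(a$t_ms), min(b$t_ms))
  t1 <- min(max(a$t_ms), max(b$t_ms))
  if (t1 <= t0) stop("ECG traces have non-overlapping time windows")
  grid <- a$t_ms[a$t_ms >= t0 & a$t_ms <= t1]
  out <- vapply(leads, function(ld) {
    va <- approx(a$t_ms, a[[ld]], grid)$y
    vb <- approx(b$t_ms, b[[ld]], grid)$y
    sqrt(mean((va - vb)^2))
  }, 1.0)
  names(out) <- leads
  out
}

#' Write an ECG trace to CSV
#' @param ecg an `ecg_trace`.
#' @param file output path.
#' @export
write_ecg <- function(ecg, file) {
  write.csv(as.data.frame(ecg), file, row.names = FALSE)
  meta <- attr(ecg, "electrodes")
  if (!is.null(meta))
    jsonlite::write_json(list(electrodes = as.data.frame(meta)),
                         paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
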