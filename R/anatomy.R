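# Synthetic biventricular anatomy: paired detailed/smoothed truncated-
# ellipsoid two-cavity shells with endocardial trabecular ridges and
# free-running false-tendon bridges, Laplace transmural/apicobasal
# coordinates, transmural layering, a one-element fast-endocardial layer
# over the apical two-thirds, scar + border-zone channel insertion, and
# placement of the five sinus initial-activation regions.

# Desk-scale miniature biventricular shell (about 1/2.5 the linear size of
# an adult human heart). The element size matches the conduction-validated
# resolution, so the node count stays workstation-sized while transverse
# propagation remains faithful.
.bv_default_geometry <- function() {
  list(
    lv_center = c(0, 0, 0),
    lv_semi_out = c(0.40, 0.40, 0.62),
    lv_wall = 0.15,
    rv_center = c(0.30, 0, 0),
    rv_semi_out = c(0.62, 0.42, 0.52),
    rv_wall = 0.10
  )
}

.in_halfellipsoid <- function(p, c0, s) {
  ((p[, 1] - c0[1]) / s[1])^2 + ((p[, 2] - c0[2]) / s[2])^2 +
    ((p[, 3] - c0[3]) / s[3])^2 <= 1 & p[, 3] <= 0
}

# region predicates used both for meshing and boundary classification
.bv_masks <- function(p, geo) {
  lv_in_s <- geo$lv_semi_out - geo$lv_wall
  rv_in_s <- geo$rv_semi_out - geo$rv_wall
  in_lv_out <- .in_halfellipsoid(p, geo$lv_center, geo$lv_semi_out)
  in_lv_in <- .in_halfellipsoid(p, geo$lv_center, lv_in_s)
  in_rv_out <- .in_halfellipsoid(p, geo$rv_center, geo$rv_semi_out)
  in_rv_in <- .in_halfellipsoid(p, geo$rv_center, rv_in_s)
  list(
    myo = (in_lv_out & !in_lv_in) | (in_rv_out & !in_rv_in & !in_lv_in),
    lv_cavity = in_lv_in,
    rv_cavity = in_rv_in & !in_lv_out
  )
}

#' Percentage trabecular volume
#'
#' Volume fraction occupied by the endocardial sub-structures, computed as
#' the percentage change between the myocardial volume of the detailed and
#' the smoothed geometry: `100 * (V_d - V_s) / V_d`.
#'
#' @param v_detailed_cm3 myocardial volume of the detailed geometry (cm^3).
#' @param v_smoothed_cm3 myocardial volume of the smoothed geometry (cm^3).
#' @return percentage (0-100).
#' @export
trabecular_volume_pct <- function(v_detailed_cm3, v_smoothed_cm3) {
  if (any(v_smoothed_cm3 <= 0)) stop("smoothed volume must be positive")
  if (any(v_smoothed_cm3 > v_detailed_cm3))
    stop("smoothed volume exceeds detailed volume")
  100 * (v_detailed_cm3 - v_smoothed_cm3) / v_detailed_cm3
}

# grow one trabecular ridge: a short 2x2-voxel column hugging the
# endocardium, running predominantly along the long axis (cross-section
# about 0.64 mm^2 at the default resolution, matching the scale of the
# sub-structures the reference models resolve)
.grow_trabecula <- function(seed_idx, arr_cav, dims) {
  len <- sample(3:7, 1)
  dir_xy <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
  dz <- sample(c(-1L, 1L), 1)
  cur <- seed_idx
  spine <- matrix(cur, 1)
  for (k in seq_len(len - 1)) {
    step <- c(if (k %% 3 == 0) dir_xy[1] else 0L,
              if (k %% 3 == 1) dir_xy[2] else 0L, dz)
    nxt <- cur + step
    if (any(nxt < 1L) || any(nxt > dims)) break
    if (!arr_cav[nxt[1], nxt[2], nxt[3]]) break
    spine <- rbind(spine, nxt)
    cur <- nxt
  }
  .dilate_voxels(spine, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(1, 1, 0)), arr_cav, dims)
}

# thicken a voxel path by a fixed offset stencil, clipped to the cavity
.dilate_voxels <- function(vx, offsets, arr_cav, dims) {
  out <- NULL
  for (o in seq_len(nrow(offsets)))
    out <- rbind(out, sweep(vx, 2, offsets[o, ], "+"))
  keep <- out[, 1] >= 1 & out[, 1] <= dims[1] & out[, 2] >= 1 &
    out[, 2] <= dims[2] & out[, 3] >= 1 & out[, 3] <= dims[3]
  out <- out[keep, , drop = FALSE]
  out <- unique(out)
  out[arr_cav[out], , drop = FALSE]
}

#' Generate a paired detailed/smoothed biventricular geometry
#'
#' The smoothed member is a truncated-ellipsoid two-cavity shell; the
#' detailed member shares the identical epicardial outline and adds
#' endocardial trabecular ridges and free-running false-tendon bridges
#' (>= 1 cm) until the added volume matches `trabecular_fraction_target`
#' within 2 percentage points. Both members carry Laplace transmural (phi)
#' and apicobasal coordinates, transmural layer labels, and a one-element
#' fast-endocardial layer over the apical two-thirds of each cavity.
#'
#' @param trabecular_fraction_target target `100*(Vd-Vs)/Vd` expressed as a
#'   fraction in `[0, 0.25]`.
#' @param n_false_tendons number of false-tendon bridges.
#' @param seed integer seed; generation is reproducible given
#'   `(configuration, seed)`.
#' @param dx_cm voxel/element size (cm).
#' @param geometry list of shell parameters, see the package vignette.
#' @return list with elements `detailed` and `smoothed` (both
#'   `cardiac_mesh`).
#' @export
make_biventricular_pair <- function(trabecular_fraction_target = 0.12,
                                    n_false_tendons = 2, seed = 1,
                                    dx_cm = 0.04,
                                    geometry = .bv_default_geometry()) {
  stopifnot(trabecular_fraction_target >= 0,
            trabecular_fraction_target <= 0.25)
  set.seed(seed)
  geo <- geometry
  # voxel grid covering both shells
  xmin <- min(geo$lv_center[1] - geo$lv_semi_out[1],
              geo$rv_center[1] - geo$rv_semi_out[1]) - dx_cm
  xmax <- max(geo$lv_center[1] + geo$lv_semi_out[1],
              geo$rv_center[1] + geo$rv_semi_out[1]) + dx_cm
  ymin <- min(-geo$lv_semi_out[2], geo$rv_center[2] - geo$rv_semi_out[2]) - dx_cm
  ymax <- -ymin
  zmin <- -max(geo$lv_semi_out[3], geo$rv_semi_out[3]) - dx_cm
  dims <- c(ceiling((xmax - xmin) / dx_cm), ceiling((ymax - ymin) / dx_cm),
            ceiling((0 - zmin) / dx_cm))
  origin <- c(xmin, ymin, zmin)
  gidx <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  centers <- sweep((gidx - 0.5) * dx_cm, 2, origin, "+")
  masks <- .bv_masks(centers, geo)

  arr_myo <- array(FALSE, dims); arr_myo[gidx[masks$myo, , drop = FALSE]] <- TRUE
  arr_lv <- array(FALSE, dims); arr_lv[gidx[masks$lv_cavity, , drop = FALSE]] <- TRUE
  arr_rv <- array(FALSE, dims); arr_rv[gidx[masks$rv_cavity, , drop = FALSE]] <- TRUE
  arr_cav <- arr_lv | arr_rv

  # cavity voxels adjacent to the wall (attachment candidates)
  shift <- function(a, d) {
    b <- array(FALSE, dim(a))
    src <- lapply(1:3, function(k) {
      i <- seq_len(dims[k]); pmin(pmax(i + d[k], 1L), dims[k])
    })
    b[] <- a[src[[1]], src[[2]], src[[3]]]
    b
  }
  wall_adj <- arr_cav & (shift(arr_myo, c(1, 0, 0)) | shift(arr_myo, c(-1, 0, 0)) |
                           shift(arr_myo, c(0, 1, 0)) | shift(arr_myo, c(0, -1, 0)) |
                           shift(arr_myo, c(0, 0, 1)) | shift(arr_myo, c(0, 0, -1)))

  vox_z <- function(k) origin[3] + (k - 0.5) * dx_cm
  cav_k <- which(arr_cav, arr.ind = TRUE)
  z_rng <- range(vox_z(cav_k[, 3]))
  apical23 <- function(idx) vox_z(idx[, 3]) < z_rng[1] + 2 / 3 * diff(z_rng)

  v_smoothed <- sum(arr_myo) * dx_cm^3
  added <- matrix(integer(0), 0, 3)
  added_lab <- character(0)
  added_axis <- matrix(numeric(0), 0, 3)
  arr_added <- array(FALSE, dims)

  mark <- function(vx, lab, axis) {
    keep <- !arr_added[vx]
    vx <- vx[keep, , drop = FALSE]
    if (!nrow(vx)) return(invisible())
    arr_added[vx] <<- TRUE
    added <<- rbind(added, vx)
    added_lab <<- c(added_lab, rep(lab, nrow(vx)))
    added_axis <<- rbind(added_axis, matrix(rep(axis, nrow(vx)), ncol = 3,
                                            byrow = TRUE))
    invisible()
  }

  # false tendons: straight >= 1 cm bridges between wall-adjacent cavity
  # voxels of the same cavity
  if (n_false_tendons > 0) {
    ft_offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    for (ft in seq_len(n_false_tendons)) {
      cav_arr <- if (ft %% 2 == 1) arr_rv else arr_lv
      cand <- which(wall_adj & cav_arr, arr.ind = TRUE)
      if (nrow(cand) < 2) next
      # longest free-running chord found (>= min length when attainable)
      best <- NULL; best_len <- 0
      for (try in 1:300) {
        pick <- cand[sample(nrow(cand), 2), , drop = FALSE]
        p1 <- origin + (pick[1, ] - 0.5) * dx_cm
        p2 <- origin + (pick[2, ] - 0.5) * dx_cm
        len <- sqrt(sum((p2 - p1)^2))
        if (len > best_len) { best <- list(p1 = p1, p2 = p2); best_len <- len }
        if (len >= 1.0) break
      }
      p1 <- best$p1; p2 <- best$p2
      npts <- ceiling(best_len / (dx_cm / 2))
      ts <- seq(0, 1, length.out = npts)
      pts <- outer(ts, p2 - p1) + matrix(rep(p1, npts), ncol = 3, byrow = TRUE)
      vft <- unique(floor(sweep(pts, 2, origin) / dx_cm) + 1L)
      inside <- vft[, 1] >= 1 & vft[, 1] <= dims[1] & vft[, 2] >= 1 &
        vft[, 2] <= dims[2] & vft[, 3] >= 1 & vft[, 3] <= dims[3]
      vft <- vft[inside, , drop = FALSE]
      vft <- .dilate_voxels(vft, ft_offsets, arr_cav, dims)
      mark(vft, "false_tendon", (p2 - p1) / best_len)
    }
  }

  # trabecular ridges until the volume target is met
  target_added <- v_smoothed * trabecular_fraction_target /
    (1 - trabecular_fraction_target)
  if (trabecular_fraction_target > 0) {
    seeds <- which(wall_adj, arr.ind = TRUE)
    seeds <- seeds[apical23(seeds), , drop = FALSE]
    max_iter <- 5000
    it <- 0
    while (nrow(added) * dx_cm^3 < target_added && it < max_iter) {
      it <- it + 1
      s <- seeds[sample(nrow(seeds), 1), ]
      vx <- .grow_trabecula(s, arr_cav, dims)
      mark(vx, "trabecula", c(0, 0, 1))
    }
    achieved <- nrow(added) * dx_cm^3 / (v_smoothed + nrow(added) * dx_cm^3)
    if (abs(achieved - trabecular_fraction_target) > 0.02)
      stop(sprintf(
        "unattainable trabecular fraction at this resolution: target %.3f, achieved %.3f",
        trabecular_fraction_target, achieved))
  }

  build <- function(detailed) {
    vox <- gidx[masks$myo, , drop = FALSE]
    lab <- rep("myocardium", nrow(vox))
    axes <- matrix(NA_real_, nrow(vox), 3)
    if (detailed && nrow(added)) {
      vox <- rbind(vox, added)
      lab <- c(lab, added_lab)
      axes <- rbind(axes, added_axis)
    }
    vm <- .voxel_tet_mesh(vox - 1L, origin, dx_cm)
    mesh <- .new_mesh(vm$nodes, vm$elems, lab[vm$elem_voxel], dx_cm,
                      meta = list(kind = "biventricular", geometry = geo,
                                  seed = seed, detailed = detailed),
                      elem_axis = axes[vm$elem_voxel, , drop = FALSE])
    # boundary classification via empty-neighbor location
    cls <- .classify_boundary(mesh, function(p) {
      mk <- .bv_masks(p, geo)
      ifelse(mk$lv_cavity | mk$rv_cavity, "endo",
             ifelse(p[, 3] > -dx_cm * 0.25, "base", "epi"))
    })
    endo_f <- cls$label == "endo"
    epi_f <- cls$label == "epi"
    mesh$surfaces <- list(
      endo = list(faces = cls$faces[endo_f, , drop = FALSE],
                  owner = cls$owner[endo_f]),
      epi = list(faces = cls$faces[epi_f, , drop = FALSE],
                 owner = cls$owner[epi_f]))
    endo_nodes <- unique(as.vector(mesh$surfaces$endo$faces))
    epi_nodes <- setdiff(unique(as.vector(mesh$surfaces$epi$faces)), endo_nodes)
    mesh$phi <- .laplace_solve(mesh, c(endo_nodes, epi_nodes),
                               c(rep(0, length(endo_nodes)),
                                 rep(1, length(epi_nodes))))
    mesh$phi <- pmin(pmax(mesh$phi, 0), 1)
    # apicobasal coordinate
    zc <- mesh$nodes[, 3]
    apex_nodes <- which(zc < min(zc) + 3 * dx_cm)
    base_nodes <- which(zc > max(zc) - dx_cm / 2)
    mesh$z_ab <- .laplace_solve(mesh, c(apex_nodes, base_nodes),
                                c(rep(0, length(apex_nodes)),
                                  rep(1, length(base_nodes))))
    mesh$z_ab <- pmin(pmax(mesh$z_ab, 0), 1)
    mesh <- .assign_layers(mesh)
    # one-element fast-endocardial layer, apical two-thirds, compact wall only
    endo_owner <- unique(mesh$surfaces$endo$owner)
    ec <- .elem_centroids(mesh)
    elem_zab <- (mesh$z_ab[mesh$elems[, 1]] + mesh$z_ab[mesh$elems[, 2]] +
                   mesh$z_ab[mesh$elems[, 3]] + mesh$z_ab[mesh$elems[, 4]]) / 4
    fe <- intersect(endo_owner, which(mesh$region == "myocardium" &
                                        elem_zab < 2 / 3))
    mesh$region[fe] <- "fast_endo"
    mesh
  }

  list(detailed = build(TRUE), smoothed = build(FALSE))
}

#' Insert a transmural scar with a border-zone channel
#'
#' Elements within `radius_cm` of `center` become non-excitable dense scar;
#' a surrounding shell of width `border_width_cm` becomes border zone; a
#' border-zone corridor of width `channel_width_cm` along `channel_axis`
#' crosses the dense core, forming the isthmus that supports
#' channel-dependent reentry.
#'
#' @param mesh a `cardiac_mesh`.
#' @param center scar center (cm).
#' @param radius_cm dense-core radius; 0 leaves the mesh unchanged.
#' @param border_width_cm border-zone shell width.
#' @param channel_width_cm isthmus width (must be smaller than the core
#'   diameter).
#' @param channel_axis direction of the corridor.
#' @return the mesh with updated region labels.
#' @export
insert_scar <- function(mesh, center, radius_cm, border_width_cm = 0.5,
                        channel_width_cm = 0.3, channel_axis = c(1, 0, 0)) {
  if (radius_cm == 0) return(mesh)
  if (channel_width_cm >= 2 * radius_cm)
    stop("channel wider than the scar core")
  ec <- .elem_centroids(mesh)
  rel <- sweep(ec, 2, center)
  d <- sqrt(rowSums(rel^2))
  core <- d < radius_cm
  ring <- d >= radius_cm & d < radius_cm + border_width_cm
  if (!any(core)) stop("scar core contains no elements (outside the mesh?)")
  u <- channel_axis / sqrt(sum(channel_axis^2))
  along <- rel %*% u
  perp <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
  channel <- core & perp < channel_width_cm / 2
  mesh$region[ring] <- "border_zone"
  mesh$region[core] <- "dense_scar"
  mesh$region[channel] <- "border_zone"
  mesh
}

#' Stimulus site
#'
#' @param label site name.
#' @param nodes node indices receiving the stimulus.
#' @param onset_ms stimulus onset (ms).
#' @param amplitude stimulus amplitude (µA/µF, inward negative).
#' @param duration_ms stimulus duration (ms).
#' @export
stimulus_site <- function(label, nodes, onset_ms = 0, amplitude = -80,
                          duration_ms = 2) {
  nodes <- as.integer(nodes)
  if (!length(nodes)) stop("stimulus site has an empty node set")
  structure(list(label = label, nodes = nodes, onset = onset_ms,
                 amplitude = amplitude, duration = duration_ms),
            class = "stimulus_site")
}

# endo-surface nodes within radius of the endo node closest to a target point
.endo_patch <- function(mesh, target, radius = 0.15) {
  en <- unique(as.vector(mesh$surfaces$endo$faces))
  p <- mesh$nodes[en, , drop = FALSE]
  d <- sqrt(colSums((t(p) - target)^2))
  anchor <- p[which.min(d), ]
  en[sqrt(colSums((t(p) - anchor)^2)) <= radius]
}

# analytic landmark targets shared by both members of a geometry pair
.iar_targets <- function(geo) {
  lv_in <- geo$lv_semi_out - geo$lv_wall
  rv_in <- geo$rv_semi_out - geo$rv_wall
  on_s <- function(c0, s, d) c0 + s * (d / sqrt(sum(d^2)))
  list(
    IAR1 = on_s(geo$rv_center, rv_in, c(0.75, 0.45, -0.5)),
    IAR2 = on_s(geo$rv_center, rv_in, c(0.75, -0.45, -0.5)),
    IAR3 = on_s(geo$lv_center, lv_in, c(0.45, 0.80, -0.40)),
    IAR4 = on_s(geo$lv_center, lv_in, c(0.87, 0, -0.50)),
    IAR5 = c(0.35, -0.42) # posterior paraseptal direction; z from z_ab = 1/3
  )
}

# site 5 anchor: endocardial node closest to apicobasal coordinate 1/3 in
# the posterior paraseptal sector (definition shared by both pair members)
.iar5_anchor <- function(mesh, dir_xy) {
  en <- unique(as.vector(mesh$surfaces$endo$faces))
  p <- mesh$nodes[en, , drop = FALSE]
  ctr <- mesh$meta$geometry$lv_center
  dxy <- cbind(p[, 1] - ctr[1], p[, 2] - ctr[2])
  dxy <- dxy / pmax(sqrt(rowSums(dxy^2)), 1e-9)
  u <- dir_xy / sqrt(sum(dir_xy^2))
  score <- 3 * (mesh$z_ab[en] - 1 / 3)^2 + (1 - (dxy %*% u))^2
  mesh$nodes[en[which.min(score)], ]
}

#' Place the five sinus initial-activation regions
#'
#' Endocardial patches at the analogues of the human activation-map sites:
#' two on the RV free wall, a high anterior paraseptal LV area, the central
#' left septal surface, and a posterior paraseptal LV area at one third of
#' the apex-base distance. The same analytic target coordinates are used
#' for both members of a detailed/smoothed pair.
#'
#' @param mesh a biventricular `cardiac_mesh`.
#' @param radius patch radius (cm).
#' @param onset_ms,amplitude,duration_ms stimulus parameters.
#' @return list of five [stimulus_site()] objects.
#' @export
place_iars <- function(mesh, radius = 0.15, onset_ms = 0, amplitude = -80,
                       duration_ms = 2) {
  if (is.null(mesh$meta$kind) || mesh$meta$kind != "biventricular")
    stop("initial-activation regions require a biventricular mesh")
  targets <- .iar_targets(mesh$meta$geometry)
  targets$IAR5 <- .iar5_anchor(mesh, targets$IAR5)
  patches <- lapply(targets, function(tg) .endo_patch(mesh, tg, radius))
  # overlapping patches: each node belongs to the closest site
  all_nodes <- unlist(patches)
  dup <- unique(all_nodes[duplicated(all_nodes)])
  if (length(dup)) {
    anchors <- do.call(rbind, targets)
    for (nd in dup) {
      dists <- sqrt(rowSums(sweep(anchors, 2, mesh$nodes[nd, ])^2))
      keep <- which.min(dists)
      for (k in seq_along(patches))
        if (k != keep) patches[[k]] <- setdiff(patches[[k]], nd)
    }
  }
  mapply(function(nm, nd) stimulus_site(nm, nd, onset_ms, amplitude,
                                        duration_ms),
         names(targets), patches, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Pacing site for the programmed-stimulation protocol
#'
#' @param mesh a biventricular `cardiac_mesh`.
#' @param site one of `"LV_apex"`, `"RV_apex"`, `"RVOT"`.
#' @inheritParams place_iars
#' @return a [stimulus_site()].
#' @export
place_pacing_site <- function(mesh, site = c("LV_apex", "RV_apex", "RVOT"),
                              radius = 0.15, onset_ms = 0, amplitude = -80,
                              duration_ms = 2) {
  site <- match.arg(site)
  if (is.null(mesh$meta$kind) || mesh$meta$kind != "biventricular")
    stop("pacing sites require a biventricular mesh")
  geo <- mesh$meta$geometry
  lv_in <- geo$lv_semi_out - geo$lv_wall
  rv_in <- geo$rv_semi_out - geo$rv_wall
  target <- switch(site,
    LV_apex = geo$lv_center + c(0, 0, -lv_in[3]),
    RV_apex = geo$rv_center + c(0, 0, -rv_in[3]),
    RVOT = geo$rv_center + rv_in * c(0.3, 0.9, -0.3) /
      sqrt(sum(c(0.3, 0.9, -0.3)^2)))
  stimulus_site(site, .endo_patch(mesh, target, radius), onset_ms, amplitude,
                duration_ms)
}
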