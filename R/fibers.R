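# Rule-based myofiber orientation with trabecula detection.
#
# The compact wall follows the classical transmural helix rule (helix angle
# interpolating linearly in the transmural coordinate, transverse angle 0).
# Thin endocardial sub-structures are detected from the magnitude of the
# transmural-coordinate gradient: where the gradient collapses (no opposing
# endo/epi boundaries), the trabecula parameter t drops below 1 and the
# fiber direction is blended toward the structure's long axis.

#' Gradient of the transmural coordinate
#'
#' Element-wise P1 gradients of the Laplace transmural coordinate, recovered
#' at nodes by volume-weighted averaging.
#'
#' @param mesh a `cardiac_mesh` carrying `phi`.
#' @return n x 3 matrix of nodal gradients (1/cm).
#' @export
transmural_gradient <- function(mesh) {
  if (is.null(mesh$phi)) stop("mesh carries no transmural coordinate phi")
  eg <- .elem_gradients(mesh)
  el <- mesh$elems
  ge <- matrix(0, nrow(el), 3)
  for (i in 1:4)
    ge <- ge + eg$g[[i]] * mesh$phi[el[, i]]
  n <- nrow(mesh$nodes)
  gn <- matrix(0, n, 3)
  wt <- numeric(n)
  for (i in 1:4) {
    for (k in 1:3) {
      acc <- tapply(eg$vol * ge[, k], el[, i], sum)
      gn[as.integer(names(acc)), k] <- gn[as.integer(names(acc)), k] +
        as.numeric(acc)
    }
    accw <- tapply(eg$vol, el[, i], sum)
    wt[as.integer(names(accw))] <- wt[as.integer(names(accw))] + as.numeric(accw)
  }
  gn / wt
}

#' Trabecula detection parameter
#'
#' `t = ||grad phi|| / T` where the gradient magnitude is below the
#' threshold `T`, and 1 otherwise. Compact wall (opposing endocardial and
#' epicardial boundaries) has t = 1; thin cavity structures have t near 0.
#'
#' @param grad_norm non-negative gradient magnitudes (in the normalized-phi
#'   per mm scaling under which the default threshold is expressed).
#' @param threshold detection threshold (default 0.1).
#' @return vector of t values in `[0, 1]`.
#' @export
detect_trabeculae <- function(grad_norm, threshold = 0.1) {
  if (any(grad_norm < 0)) stop("gradient magnitudes must be non-negative")
  if (threshold <= 0) stop("threshold must be positive")
  pmin(grad_norm / threshold, 1)
}

# a unit vector orthogonal to u (deterministic choice)
.orth <- function(u) {
  ref <- matrix(rep(c(0, 0, 1), nrow(u)), ncol = 3, byrow = TRUE)
  par <- abs(u[, 3]) > 0.9
  ref[par, ] <- matrix(rep(c(1, 0, 0), sum(par)), ncol = 3, byrow = TRUE)
  v <- cbind(u[, 2] * ref[, 3] - u[, 3] * ref[, 2],
             u[, 3] * ref[, 1] - u[, 1] * ref[, 3],
             u[, 1] * ref[, 2] - u[, 2] * ref[, 1])
  v / sqrt(rowSums(v^2))
}

.normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Assign fiber, sheet and normal directions
#'
#' Compact wall: orthonormal triad from the transmural gradient (sheet
#' normal) and the apicobasal gradient, with helix angle interpolating
#' linearly from `alpha_endo_deg` (endocardium) to `alpha_epi_deg`
#' (epicardium) and transverse angle 0. Sub-structures (t < 1): helix angle
#' `90*(1-t) + alpha_endo*t` in a frame whose longitudinal axis is the
#' structure's long axis, giving a purely longitudinal fiber as t -> 0 and a
#' smooth transition at the endocardial junction.
#'
#' @param mesh a `cardiac_mesh` with `phi` and `z_ab`.
#' @param t optional per-node trabecula parameter; computed from
#'   [transmural_gradient()] and [detect_trabeculae()] when `NULL`.
#' @param alpha_endo_deg,alpha_epi_deg helix angles at the endo/epicardium.
#' @param threshold trabecula-detection threshold.
#' @return object of class `fiber_field`: per-node unit vectors `f`, `s`,
#'   `n`, the trabecula parameter `t`, helix angle `alpha` (deg) and
#'   transverse angle `beta` (deg), plus per-element averages used in
#'   assembly.
#' @export
assign_fibers <- function(mesh, t = NULL, alpha_endo_deg = 60,
                          alpha_epi_deg = -60, threshold = 0.1,
                          smooth_t_passes = 2) {
  n <- nrow(mesh$nodes)
  grad <- transmural_gradient(mesh)
  gnorm_mm <- sqrt(rowSums(grad^2)) / 10 # per-mm scaling of the threshold
  if (is.null(t)) {
    t <- detect_trabeculae(gnorm_mm, threshold)
    # Jacobi smoothing spreads the junction transition over a couple of
    # elements so the helix angle varies continuously at the resolution of
    # the voxel meshes
    for (pass in seq_len(smooth_t_passes)) {
      acc <- numeric(n); cnt <- numeric(n)
      for (i in 1:4) {
        idx <- mesh$elems[, i]
        tmean <- (t[mesh$elems[, 1]] + t[mesh$elems[, 2]] +
                    t[mesh$elems[, 3]] + t[mesh$elems[, 4]]) / 4
        a <- tapply(tmean, idx, sum)
        acc[as.integer(names(a))] <- acc[as.integer(names(a))] + as.numeric(a)
        ccount <- tapply(rep(1, length(idx)), idx, sum)
        cnt[as.integer(names(ccount))] <- cnt[as.integer(names(ccount))] +
          as.numeric(ccount)
      }
      t <- acc / pmax(cnt, 1)
    }
    t <- pmin(pmax(t, 0), 1)
  }

  # wall-normal direction (unit transmural gradient; fallback where flat)
  nvec <- grad
  flat <- sqrt(rowSums(grad^2)) < 1e-8
  nvec[flat, ] <- matrix(rep(c(0, 0, 1), sum(flat)), ncol = 3, byrow = TRUE)
  nvec <- .normalize_rows(nvec)

  # apicobasal (longitudinal) direction projected into the wall tangent plane
  if (!is.null(mesh$z_ab) && !is.null(mesh$meta$kind) &&
      mesh$meta$kind == "biventricular") {
    zgrad <- {
      tmp <- mesh; tmp$phi <- mesh$z_ab
      transmural_gradient(tmp)
    }
  } else {
    ax <- mesh$meta$fiber_axis
    if (is.null(ax)) ax <- c(1, 0, 0)
    zgrad <- matrix(rep(ax, n), ncol = 3, byrow = TRUE)
  }
  ell <- zgrad - nvec * rowSums(zgrad * nvec)
  deg <- sqrt(rowSums(ell^2)) < 1e-8
  ell[deg, ] <- .orth(nvec[deg, , drop = FALSE])
  ell <- .normalize_rows(ell)
  circ <- cbind(nvec[, 2] * ell[, 3] - nvec[, 3] * ell[, 2],
                nvec[, 3] * ell[, 1] - nvec[, 1] * ell[, 3],
                nvec[, 1] * ell[, 2] - nvec[, 2] * ell[, 1])
  circ <- .normalize_rows(circ)

  # sub-structure frame: longitudinal axis from the generator, averaged to
  # nodes over sub-structure elements
  sub_elems <- which(is.finite(mesh$elem_axis[, 1]))
  axis_n <- matrix(0, n, 3)
  if (length(sub_elems)) {
    for (i in 1:4) {
      idx <- mesh$elems[sub_elems, i]
      axis_n[idx, ] <- axis_n[idx, ] + mesh$elem_axis[sub_elems, , drop = FALSE]
    }
    has_axis <- rowSums(abs(axis_n)) > 0
    axis_n[has_axis, ] <- .normalize_rows(axis_n[has_axis, , drop = FALSE])
    # in the sub-structure frame the longitudinal direction is the long axis
    blend <- has_axis & t < 1
    ell[blend, ] <- axis_n[blend, , drop = FALSE]
    circ[blend, ] <- .orth(ell[blend, , drop = FALSE])
    nvec[blend, ] <- cbind(
      ell[blend, 2] * circ[blend, 3] - ell[blend, 3] * circ[blend, 2],
      ell[blend, 3] * circ[blend, 1] - ell[blend, 1] * circ[blend, 3],
      ell[blend, 1] * circ[blend, 2] - ell[blend, 2] * circ[blend, 1])
  }

  phi <- if (is.null(mesh$phi)) rep(0, n) else mesh$phi
  alpha_wall <- alpha_endo_deg + (alpha_epi_deg - alpha_endo_deg) * phi
  alpha_trab <- 90 * (1 - t) + alpha_endo_deg * t
  alpha <- ifelse(t < 1, alpha_trab, alpha_wall)
  ar <- alpha * pi / 180
  f <- circ * cos(ar) + ell * sin(ar)
  f <- .normalize_rows(f)
  # sheet = wall normal component orthogonal to f; normal completes the triad
  s <- nvec - f * rowSums(nvec * f)
  degs <- sqrt(rowSums(s^2)) < 1e-8
  s[degs, ] <- .orth(f[degs, , drop = FALSE])
  s <- .normalize_rows(s)
  nn <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
              f[, 3] * s[, 1] - f[, 1] * s[, 3],
              f[, 1] * s[, 2] - f[, 2] * s[, 1])

  # per-element triads for assembly (averaged, re-orthonormalized)
  el <- mesh$elems
  favg <- (f[el[, 1], ] + f[el[, 2], ] + f[el[, 3], ] + f[el[, 4], ]) / 4
  savg <- (s[el[, 1], ] + s[el[, 2], ] + s[el[, 3], ] + s[el[, 4], ]) / 4
  favg <- .normalize_rows(favg)
  savg <- savg - favg * rowSums(savg * favg)
  degsa <- sqrt(rowSums(savg^2)) < 1e-8
  savg[degsa, ] <- .orth(favg[degsa, , drop = FALSE])
  savg <- .normalize_rows(savg)
  navg <- cbind(favg[, 2] * savg[, 3] - favg[, 3] * savg[, 2],
                favg[, 3] * savg[, 1] - favg[, 1] * savg[, 3],
                favg[, 1] * savg[, 2] - favg[, 2] * savg[, 1])

  structure(list(f = f, s = s, n = nn, t = t, alpha = alpha,
                 beta = rep(0, n),
                 elem_f = favg, elem_s = savg, elem_n = navg),
            class = "fiber_field")
}

#' Uniform fiber field (cable/slab fixtures)
#'
#' @param mesh a `cardiac_mesh`.
#' @param axis fiber direction.
#' @return a `fiber_field` with t = 1 everywhere.
#' @export
uniform_fibers <- function(mesh, axis = mesh$meta$fiber_axis) {
  if (is.null(axis)) axis <- c(1, 0, 0)
  axis <- axis / sqrt(sum(axis^2))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  f <- matrix(rep(axis, n), ncol = 3, byrow = TRUE)
  s <- .orth(f)
  nn <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
              f[, 3] * s[, 1] - f[, 1] * s[, 3],
              f[, 1] * s[, 2] - f[, 2] * s[, 1])
  structure(list(f = f, s = s, n = nn, t = rep(1, n),
                 alpha = rep(NA_real_, n), beta = rep(0, n),
                 elem_f = matrix(rep(axis, m), ncol = 3, byrow = TRUE),
                 elem_s = s[rep(1, m), , drop = FALSE],
                 elem_n = nn[rep(1, m), , drop = FALSE]),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat("<fiber_field> ", nrow(x$f), " nodes; t < 1 at ",
      sum(x$t < 1), " nodes\n", sep = "")
  invisible(x)
}
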