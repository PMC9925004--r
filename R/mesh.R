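# Tetrahedral mesh core: structured voxel-to-tet meshing (Kuhn subdivision,
# conforming across cells), boundary-face extraction and classification,
# P1 finite-element assembly and Laplace coordinate solves.

# Kuhn subdivision of a cube into 6 positively-oriented tetrahedra.
# Corner ids 1..8 with bit offsets x=+1, y=+2, z=+4.
.kuhn_tets <- matrix(c(
  1, 2, 4, 8,
  1, 2, 8, 6,
  1, 3, 8, 4,
  1, 3, 7, 8,
  1, 5, 6, 8,
  1, 5, 8, 7), ncol = 4, byrow = TRUE)

.corner_offsets <- cbind(
  x = c(0, 1, 0, 1, 0, 1, 0, 1),
  y = c(0, 0, 1, 1, 0, 0, 1, 1),
  z = c(0, 0, 0, 0, 1, 1, 1, 1))

# Build a tetrahedral mesh from occupied voxels of a regular grid.
# vox: integer matrix (k x 3) of 0-based voxel indices; origin: corner of
# voxel (0,0,0); dx: edge length (cm). Returns nodes, elems and the voxel
# id of every element (6 tets per voxel, in order).
.voxel_tet_mesh <- function(vox, origin, dx) {
  stopifnot(is.matrix(vox), ncol(vox) == 3, nrow(vox) >= 1)
  nx1 <- max(vox[, 1]) + 2L # corner-grid extents
  ny1 <- max(vox[, 2]) + 2L
  # corner ids for all 8 corners of all voxels (0-based grid linearization)
  corner_key <- function(ci) {
    (vox[, 1] + .corner_offsets[ci, 1]) +
      nx1 * ((vox[, 2] + .corner_offsets[ci, 2]) +
               ny1 * (vox[, 3] + .corner_offsets[ci, 3]))
  }
  keys <- vapply(1:8, corner_key, numeric(nrow(vox)))
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = 1)
  ukeys <- sort(unique(as.vector(keys)))
  idx <- matrix(match(keys, ukeys), nrow = nrow(vox))
  # node coordinates from grid keys
  kx <- ukeys %% nx1
  rest <- (ukeys - kx) / nx1
  ky <- rest %% ny1
  kz <- (rest - ky) / ny1
  nodes <- cbind(origin[1] + kx * dx, origin[2] + ky * dx, origin[3] + kz * dx)
  # 6 tets per voxel
  nv <- nrow(vox)
  elems <- matrix(0L, nv * 6L, 4L)
  for (tti in 1:6) {
    rows <- seq.int(tti, by = 6L, length.out = nv)
    elems[rows, ] <- idx[, .kuhn_tets[tti, ], drop = FALSE]
  }
  list(nodes = nodes, elems = elems, elem_voxel = rep(seq_len(nv), each = 6L))
}

#' Signed volumes of the tetrahedra of a mesh
#'
#' @param mesh a `cardiac_mesh`.
#' @return numeric vector of element volumes (cm^3).
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cc <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  det / 6
}

#' Total mesh volume
#' @param mesh a `cardiac_mesh`.
#' @param region optional region label(s) to restrict to.
#' @return volume in cm^3.
#' @export
mesh_volume <- function(mesh, region = NULL) {
  v <- element_volumes(mesh)
  if (!is.null(region)) v <- v[mesh$region %in% region]
  sum(v)
}

# element centroids (m x 3)
.elem_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], , drop = FALSE] +
     mesh$nodes[mesh$elems[, 2], , drop = FALSE] +
     mesh$nodes[mesh$elems[, 3], , drop = FALSE] +
     mesh$nodes[mesh$elems[, 4], , drop = FALSE]) / 4
}

# Boundary faces: triangles owned by exactly one tetrahedron.
# Returns a data.frame-free list: face node matrix (r x 3) and owner element.
.boundary_faces <- function(mesh) {
  el <- mesh$elems
  m <- nrow(el)
  combs <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  f <- rbind(el[, combs[1, ]], el[, combs[2, ]], el[, combs[3, ]],
             el[, combs[4, ]])
  owner <- rep(seq_len(m), 4)
  fs <- t(apply(f, 1, sort))
  n <- nrow(mesh$nodes)
  key <- (fs[, 1] - 1) + n * ((fs[, 2] - 1) + n * (fs[, 3] - 1))
  tab <- table(key)
  solo <- as.numeric(names(tab)[tab == 1L])
  keep <- key %in% solo
  list(faces = f[keep, , drop = FALSE], owner = owner[keep])
}

# classify boundary faces of a voxel mesh by the location of the empty
# neighbor cell; classify_fn(p) maps empty-cell centers (r x 3) to labels
.classify_boundary <- function(mesh, classify_fn) {
  bf <- .boundary_faces(mesh)
  nd <- mesh$nodes
  p1 <- nd[bf$faces[, 1], , drop = FALSE]
  p2 <- nd[bf$faces[, 2], , drop = FALSE]
  p3 <- nd[bf$faces[, 3], , drop = FALSE]
  cent <- (p1 + p2 + p3) / 3
  own_cent <- .elem_centroids(mesh)[bf$owner, , drop = FALSE]
  dx <- mesh$dx
  # boundary triangles of the voxel mesh lie on axis-aligned planes; find
  # the constant axis and step half a voxel away from the owner
  neighbor <- cent
  for (ax in 1:3) {
    const_ax <- abs(p1[, ax] - p2[, ax]) < 1e-9 & abs(p1[, ax] - p3[, ax]) < 1e-9
    sgn <- sign(cent[, ax] - own_cent[, ax])
    neighbor[const_ax, ax] <- cent[const_ax, ax] + sgn[const_ax] * dx / 2
  }
  lab <- classify_fn(neighbor)
  list(faces = bf$faces, owner = bf$owner, label = lab, centroid = cent)
}

.new_mesh <- function(nodes, elems, region, dx, meta = list(),
                      phi = NULL, z_ab = NULL, elem_axis = NULL) {
  m <- nrow(elems)
  structure(list(
    nodes = nodes, elems = elems,
    region = factor(region,
                    levels = c("myocardium", "fast_endo", "trabecula",
                               "false_tendon", "border_zone", "dense_scar")),
    dx = dx, phi = phi, z_ab = z_ab,
    layer = NULL,
    elem_axis = if (is.null(elem_axis)) matrix(NA_real_, m, 3) else elem_axis,
    surfaces = NULL, meta = meta
  ), class = "cardiac_mesh")
}

#' @export
print.cardiac_mesh <- function(x, ...) {
  cat("<cardiac_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elems),
      " tetrahedra, dx = ", x$dx, " cm\n", sep = "")
  print(table(x$region))
  invisible(x)
}

# layer labels from the transmural coordinate: inner 30% endo, middle 40%
# mid, outer 30% epi
.assign_layers <- function(mesh) {
  stopifnot(!is.null(mesh$phi))
  lay <- ifelse(mesh$phi < 0.3, "endo", ifelse(mesh$phi <= 0.7, "mid", "epi"))
  mesh$layer <- factor(lay, levels = c("endo", "mid", "epi"))
  mesh
}

#' Pseudo-one-dimensional cable mesh
#'
#' A tetrahedralized strand of square cross-section `dx` used for conduction
#' velocity calibration; fibers run along the x axis.
#'
#' @param length_cm cable length (cm).
#' @param dx_cm element size (cm).
#' @return a `cardiac_mesh` with all-myocardium labels, fiber axis metadata,
#'   transmural coordinate across the strand and apicobasal coordinate along
#'   it.
#' @export
make_cable <- function(length_cm = 2, dx_cm = 0.04) {
  if (dx_cm <= 0) stop("dx_cm must be positive")
  if (length_cm < 20 * dx_cm) stop("cable must span at least 20 elements")
  nx <- round(length_cm / dx_cm)
  vox <- cbind(0:(nx - 1L), 0L, 0L)
  vm <- .voxel_tet_mesh(vox, c(0, 0, 0), dx_cm)
  mesh <- .new_mesh(vm$nodes, vm$elems, rep("myocardium", nrow(vm$elems)),
                    dx_cm, meta = list(kind = "cable", fiber_axis = c(1, 0, 0),
                                       length = length_cm))
  mesh$phi <- vm$nodes[, 3] / dx_cm
  mesh$z_ab <- vm$nodes[, 1] / length_cm
  mesh$layer <- factor(rep("endo", nrow(vm$nodes)),
                       levels = c("endo", "mid", "epi"))
  mesh
}

#' Axis-aligned slab mesh
#'
#' @param lx,ly,lz extents (cm); the transmural coordinate runs along z.
#' @param dx_cm element size (cm).
#' @param fiber_axis in-plane fiber direction stored as metadata.
#' @return a `cardiac_mesh`.
#' @export
make_slab <- function(lx, ly, lz, dx_cm = 0.05, fiber_axis = c(1, 0, 0)) {
  if (dx_cm <= 0) stop("dx_cm must be positive")
  if (lx < dx_cm || ly < dx_cm || lz < dx_cm) stop("degenerate slab extents")
  nx <- max(1L, round(lx / dx_cm))
  ny <- max(1L, round(ly / dx_cm))
  nz <- max(1L, round(lz / dx_cm))
  g <- as.matrix(expand.grid(0:(nx - 1L), 0:(ny - 1L), 0:(nz - 1L)))
  vm <- .voxel_tet_mesh(g, c(0, 0, 0), dx_cm)
  mesh <- .new_mesh(vm$nodes, vm$elems, rep("myocardium", nrow(vm$elems)),
                    dx_cm,
                    meta = list(kind = "slab",
                                fiber_axis = fiber_axis / sqrt(sum(fiber_axis^2)),
                                extents = c(lx, ly, lz) ))
  mesh$phi <- vm$nodes[, 3] / (nz * dx_cm)
  mesh$z_ab <- vm$nodes[, 1] / (nx * dx_cm)
  mesh <- .assign_layers(mesh)
  mesh
}

# ---------------- finite elements ----------------

# per-element barycentric gradients; returns list of four m x 3 matrices and
# volumes
.elem_gradients <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cc <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cr(b, cc); cxa <- cr(cc, a); axb <- cr(a, b)
  det <- rowSums(a * bxc)
  g2 <- bxc / det; g3 <- cxa / det; g4 <- axb / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = abs(det) / 6)
}

# stiffness matrix for per-element symmetric tensors D (m x 6:
# Dxx,Dyy,Dzz,Dxy,Dxz,Dyz) and lumped mass vector
.fem_assemble <- function(mesh, D) {
  eg <- .elem_gradients(mesh)
  g <- eg$g; vol <- eg$vol
  m <- nrow(mesh$elems)
  apply_D <- function(gi) {
    cbind(D[, 1] * gi[, 1] + D[, 4] * gi[, 2] + D[, 5] * gi[, 3],
          D[, 4] * gi[, 1] + D[, 2] * gi[, 2] + D[, 6] * gi[, 3],
          D[, 5] * gi[, 1] + D[, 6] * gi[, 2] + D[, 3] * gi[, 3])
  }
  q <- lapply(g, apply_D)
  ii <- jj <- xx <- vector("list", 16)
  k <- 1
  for (i in 1:4) for (j in 1:4) {
    ii[[k]] <- mesh$elems[, i]
    jj[[k]] <- mesh$elems[, j]
    xx[[k]] <- vol * rowSums(q[[i]] * g[[j]])
    k <- k + 1
  }
  n <- nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  mass <- as.numeric(tabulate(as.vector(mesh$elems), nbins = n) * 0) # init
  mass <- numeric(n)
  for (i in 1:4) {
    acc <- tapply(vol, mesh$elems[, i], sum)
    mass[as.integer(names(acc))] <- mass[as.integer(names(acc))] + as.numeric(acc)
  }
  list(K = K, mass = mass / 4, vol = vol)
}

# isotropic Laplace solve with Dirichlet boundary values
.laplace_solve <- function(mesh, dirichlet_nodes, dirichlet_values) {
  n <- nrow(mesh$nodes)
  D <- cbind(1, 1, 1, 0, 0, 0)[rep(1, nrow(mesh$elems)), , drop = FALSE]
  K <- .fem_assemble(mesh, D)$K
  fixed <- unique(dirichlet_nodes)
  vals <- dirichlet_values[match(fixed, dirichlet_nodes)]
  free <- setdiff(seq_len(n), fixed)
  phi <- numeric(n)
  phi[fixed] <- vals
  if (length(free)) {
    rhs <- -K[free, fixed, drop = FALSE] %*% vals
    phi[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  }
  phi
}
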