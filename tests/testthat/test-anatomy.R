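# Synthetic anatomy: meshing primitives, the paired detailed/smoothed
# generator, scar insertion and activation-site placement.

test_that("cable and slab constructors honour their contracts", {
  m <- make_cable(2, 0.04)
  expect_equal(nrow(m$elems), 50 * 6)
  expect_true(all(element_volumes(m) > 0))
  expect_equal(mesh_volume(m), 2 * 0.04^2, tolerance = 1e-12)
  m2 <- make_cable(2, 0.04)
  expect_identical(m$nodes, m2$nodes) # determinism
  expect_error(make_cable(2, -1), "positive")
  expect_error(make_cable(0.2, 0.04), "20")

  s <- make_slab(1, 0.5, 0.2, dx_cm = 0.1)
  expect_true(all(element_volumes(s) > 0))
  expect_equal(mesh_volume(s), 1 * 0.5 * 0.2, tolerance = 1e-12)
  expect_error(make_slab(0.01, 1, 1, dx_cm = 0.1), "degenerate")
  # transmural layering at thresholds 0.3/0.7: 30/40/30 volume shares on a
  # wall resolved by ten element layers
  s2 <- make_slab(0.5, 0.3, 1.0, dx_cm = 0.1)
  ev <- element_volumes(s2)
  ephi <- rowMeans(matrix(s2$phi[s2$elems], ncol = 4))
  lay <- cut(ephi, c(-Inf, 0.3, 0.7, Inf), labels = c("endo", "mid", "epi"))
  share <- as.numeric(tapply(ev, lay, sum) / sum(ev))
  expect_equal(share, c(0.3, 0.4, 0.3), tolerance = 0.05)
})

test_that("trabecular volume percentage follows its definition", {
  expect_equal(round(trabecular_volume_pct(394.2, 329.8), 1), 16.3)
  expect_equal(round(trabecular_volume_pct(299.2, 268), 1), 10.4)
  expect_equal(trabecular_volume_pct(5, 5), 0)
  expect_error(trabecular_volume_pct(5, 6), "exceeds")
  expect_error(trabecular_volume_pct(5, 0), "positive")
})

test_that("the biventricular pair meets its generator contract", {
  pair <- fx_pair()
  d <- pair$detailed; s <- pair$smoothed
  expect_true(all(element_volumes(d) > 0))
  expect_true(all(element_volumes(s) > 0))
  expect_equal(levels(d$region), levels(s$region))
  expect_equal(sum(s$region %in% c("trabecula", "false_tendon")), 0)

  pct <- trabecular_volume_pct(mesh_volume(d), mesh_volume(s))
  expect_gte(pct, 10); expect_lte(pct, 14) # target 12% within 2 points

  # transmural coordinate spans [0, 1] with the right boundary values
  expect_equal(range(d$phi), c(0, 1))
  en <- unique(as.vector(d$surfaces$endo$faces))
  ep <- setdiff(unique(as.vector(d$surfaces$epi$faces)), en)
  expect_lt(max(d$phi[en]), 0.05)
  expect_gt(min(d$phi[ep]), 0.95)

  # no false tendons requested: none generated
  p0 <- make_biventricular_pair(0.05, 0, seed = 4, dx_cm = 0.06)
  expect_equal(sum(p0$detailed$region == "false_tendon"), 0)

  # determinism: same configuration and seed reproduce the mesh
  pair2 <- make_biventricular_pair(0.12, 2, seed = 1)
  expect_identical(pair$detailed$nodes, pair2$detailed$nodes)
  expect_identical(pair$detailed$region, pair2$detailed$region)
})

test_that("the achievable trabecular fractions cover the reference range", {
  lo <- make_biventricular_pair(0.087, 2, seed = 2)
  hi <- make_biventricular_pair(0.163, 2, seed = 2)
  pct <- function(p) trabecular_volume_pct(mesh_volume(p$detailed),
                                           mesh_volume(p$smoothed))
  expect_equal(pct(lo), 8.7, tolerance = 0.25)
  expect_equal(pct(hi), 16.3, tolerance = 0.15)
})

test_that("fast-endocardial layer is one element thick and apical", {
  d <- fx_pair()$detailed
  fe <- which(d$region == "fast_endo")
  expect_gt(length(fe), 0)
  # every fast-endo element owns at least one endocardial boundary face
  endo_owner <- unique(d$surfaces$endo$owner)
  expect_true(all(fe %in% endo_owner))
  # absent from the basal third
  elem_zab <- rowMeans(matrix(d$z_ab[d$elems[fe, ]], ncol = 4))
  expect_true(all(elem_zab < 2 / 3 + 0.05))
})

test_that("scar insertion labels core, border zone and channel correctly", {
  m <- make_slab(2, 2, 0.08, dx_cm = 0.08)
  expect_identical(insert_scar(m, c(1, 1, 0), 0), m) # radius 0: unchanged
  sm <- insert_scar(m, c(1, 1, 0.04), radius_cm = 0.5,
                    border_width_cm = 0.3, channel_width_cm = 0.2)
  core <- which(sm$region == "dense_scar")
  bz <- which(sm$region == "border_zone")
  expect_gt(length(core), 0)
  expect_gt(length(bz), 0)
  expect_length(intersect(core, bz), 0)
  expect_error(insert_scar(m, c(1, 1, 0), 0.3, 0.2, 0.8), "wider")

  # the channel corridor connects the two border-zone sides through the core
  ec <- (m$nodes[m$elems[, 1], ] + m$nodes[m$elems[, 2], ] +
           m$nodes[m$elems[, 3], ] + m$nodes[m$elems[, 4], ]) / 4
  west <- which(sm$region == "border_zone" & ec[, 1] < 0.6)
  east <- which(sm$region == "border_zone" & ec[, 1] > 1.4)
  # breadth-first search over node-sharing adjacency within the border zone
  bz_set <- sm$region == "border_zone"
  node_elems <- split(rep(seq_len(nrow(sm$elems)), 4), as.vector(sm$elems))
  seen <- rep(FALSE, nrow(sm$elems))
  queue <- west
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nbs <- unique(unlist(node_elems[as.character(sm$elems[cur, ])]))
    nbs <- nbs[bz_set[nbs] & !seen[nbs]]
    seen[nbs] <- TRUE
    queue <- c(queue, nbs)
  }
  expect_true(any(seen[east]))
})

test_that("initial-activation regions are placed consistently", {
  pair <- fx_pair()
  id <- place_iars(pair$detailed)
  is_ <- place_iars(pair$smoothed)
  expect_length(id, 5)
  expect_false(any(duplicated(unlist(lapply(id, `[[`, "nodes")))))
  # the same analytic targets serve both members of the pair
  dmax <- max(vapply(1:5, function(k) {
    cd <- colMeans(pair$detailed$nodes[id[[k]]$nodes, , drop = FALSE])
    cs <- colMeans(pair$smoothed$nodes[is_[[k]]$nodes, , drop = FALSE])
    sqrt(sum((cd - cs)^2))
  }, 1.0))
  expect_lt(dmax, 0.04 * sqrt(3) * 1.5) # about one element diameter
  # posterior paraseptal site sits at one third of the apex-base distance
  z5 <- mean(pair$detailed$z_ab[id[[5]]$nodes])
  expect_lt(abs(z5 - 1 / 3), 0.1)
  expect_error(place_iars(make_cable(2, 0.04)), "biventricular")
})

test_that("stimulus sites validate their node sets", {
  expect_error(stimulus_site("x", integer(0)), "empty")
  s <- stimulus_site("x", 1:3, 5, -80, 2)
  expect_s3_class(s, "stimulus_site")
  expect_equal(s$onset, 5)
})
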