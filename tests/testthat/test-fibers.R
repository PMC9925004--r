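# Fiber orientation: transmural gradients, trabecula detection and the
# helix-angle rules.

test_that("transmural gradient recovers analytic fields", {
  s <- make_slab(1, 0.5, 0.3, dx_cm = 0.1) # phi = z / 0.3
  g <- transmural_gradient(s)
  inner <- s$nodes[, 3] > 0.05 & s$nodes[, 3] < 0.25
  expect_equal(mean(sqrt(rowSums(g[inner, ]^2))), 1 / 0.3, tolerance = 1e-6)
  expect_equal(mean(abs(g[inner, 1])), 0, tolerance = 1e-9)

  flat <- s; flat$phi <- rep(0.5, nrow(s$nodes))
  gf <- transmural_gradient(flat)
  expect_lt(max(abs(gf)), 1e-10)

  nophil <- s; nophil$phi <- NULL
  expect_error(transmural_gradient(nophil), "phi")
})

test_that("trabecula detection follows the threshold rule", {
  expect_equal(detect_trabeculae(0.05, 0.1), 0.5)
  expect_equal(detect_trabeculae(0.2, 0.1), 1)
  expect_equal(detect_trabeculae(0, 0.1), 0)
  expect_error(detect_trabeculae(-0.1), "non-negative")
  expect_error(detect_trabeculae(0.1, 0), "positive")

  # thin cavity structures sit far below the compact-wall gradient level
  d <- fx_pair()$detailed
  fib <- fx_fibers("detailed")
  wall_nodes <- setdiff(unique(as.vector(d$elems[d$region == "myocardium", ])),
                        unique(as.vector(d$elems[d$region %in%
                                                   c("trabecula", "false_tendon"), ])))
  sub_only <- setdiff(unique(as.vector(d$elems[d$region %in%
                                                 c("trabecula", "false_tendon"), ])),
                      unique(as.vector(d$elems[!d$region %in%
                                                 c("trabecula", "false_tendon"), ])))
  expect_gt(median(fib$t[wall_nodes]), 0.95)
  expect_lt(median(fib$t[sub_only]), 0.5)
})

test_that("helix-angle rule hits its limits and blends linearly", {
  # the sub-structure rule: alpha = 90 (1 - t) + alpha_endo t
  tvals <- c(0, 0.5, 1)
  expect_equal(90 * (1 - tvals[1]) + 60 * tvals[1], 90)
  d <- fx_pair()$detailed
  f0 <- assign_fibers(d, t = rep(0, nrow(d$nodes)))
  expect_true(all(abs(f0$alpha - 90) < 1e-9))
  fhalf <- assign_fibers(d, t = rep(0.5, nrow(d$nodes)),
                         alpha_endo_deg = -60)
  expect_true(all(abs(fhalf$alpha - 15) < 1e-9))
  # t = 1 on the endocardium reduces to the wall rule, alpha_endo at phi=0
  f1 <- assign_fibers(d, t = rep(1, nrow(d$nodes)), alpha_endo_deg = 60,
                      alpha_epi_deg = -60)
  endo_nodes <- which(d$phi < 1e-9)
  expect_true(all(abs(f1$alpha[endo_nodes] - 60) < 1e-6))
})

test_that("fiber triads are orthonormal and the slab reduces to the helix rule", {
  d <- fx_pair()$detailed
  fib <- fx_fibers("detailed")
  dots <- c(abs(rowSums(fib$f * fib$s)), abs(rowSums(fib$f * fib$n)),
            abs(rowSums(fib$s * fib$n)))
  expect_lt(max(dots), 1e-6)
  norms <- c(abs(sqrt(rowSums(fib$f^2)) - 1), abs(sqrt(rowSums(fib$s^2)) - 1))
  expect_lt(max(norms), 1e-6)
  expect_true(all(fib$t >= 0 & fib$t <= 1))

  # pure slab: t = 1 away from boundaries, angles follow the transmural rule
  s <- make_slab(1.2, 0.8, 0.4, dx_cm = 0.08)
  fs <- assign_fibers(s)
  interior <- s$nodes[, 1] > 0.2 & s$nodes[, 1] < 1.0 &
    s$nodes[, 2] > 0.2 & s$nodes[, 2] < 0.6
  expect_true(all(fs$t[interior] == 1))
  mid <- interior & abs(s$phi - 0.5) < 1e-9
  expect_true(all(abs(fs$alpha[mid]) < 1e-6)) # mid-wall: alpha = 0
})

test_that("helix angle varies continuously across the trabecular junction", {
  d <- fx_pair()$detailed
  fib <- fx_fibers("detailed")
  # edges spanning the junction: one endpoint inside a sub-structure
  sub_elems <- which(d$region %in% c("trabecula", "false_tendon"))
  sub_nodes <- unique(as.vector(d$elems[sub_elems, ]))
  el <- d$elems[sub_elems, , drop = FALSE]
  edges <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                 el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  jump <- abs(fib$alpha[edges[, 1]] - fib$alpha[edges[, 2]])
  expect_lt(stats::quantile(jump, 0.95), 15)
})
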