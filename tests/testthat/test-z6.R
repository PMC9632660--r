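test_that("drift has the closed-form fixed points and cycle radii", {
  expect_equal(z6_drift(0 + 0i, lambda = 0.25), 0 + 0i)
  # radial equilibria r^2 = 1 +/- sqrt(lambda): purely rotational drift
  for (lam in c(0.1, 0.25, 0.5, 0.9)) {
    for (r in sqrt(1 + c(-1, 1) * sqrt(lam))) {
      f <- z6_drift(r + 0i, lambda = lam, omega = 1)
      expect_lt(abs(Re(f)), 1e-12)         # no radial component
      expect_equal(Im(f), r, tolerance = 1e-12)  # rotation at omega
    }
  }
})

test_that("deterministic dynamics converge to the stable cycle", {
  # independent oracle: integrate the polar radial ODE dr/dt = r(-r^4+2r^2
  # + lambda - 1) with deSolve from r(0) = 0.8 at lambda = 0.25
  sol <- deSolve::ode(y = c(r = 0.8), times = c(0, 50),
                      func = function(t, y, p) {
                        list(y * (-y^4 + 2 * y^2 + 0.25 - 1))
                      }, parms = NULL)
  expect_equal(unname(sol[2, "r"]), sqrt(1.5), tolerance = 1e-6)

  # the package Euler step reaches the same attractor when following the
  # radial dynamics (an ODE fixed point is exactly an Euler fixed point;
  # the rotation term adds a documented O(omega^2 dt) radial bias)
  z <- 0.8 + 0i
  for (i in seq_len(1000)) z <- z + 0.05 * z6_drift(z, 0.25, omega = 0)
  expect_equal(Mod(z), sqrt(1.5), tolerance = 1e-3)
})

test_that("coupling normalization scales the strongest edge to K", {
  W <- matrix(c(0, 2, 4, 0), 2, 2)
  G <- normalize_coupling(W, K = 1000)
  expect_equal(max(G), 1000)
  expect_equal(G[2, 1], 500)
  expect_equal(normalize_coupling(matrix(0, 3, 3)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(normalize_coupling(matrix(c(0, -1, 1, 0), 2, 2)),
               class = "epitarget_invalid")
})

test_that("simulation is seed-deterministic and respects the quiet limit", {
  G <- matrix(0, 3, 3)
  p <- z6_params(t_max = 20)
  t1 <- simulate_network(G, 0.5, params = p, seed = 3)
  t2 <- simulate_network(G, 0.5, params = p, seed = 3)
  expect_identical(t1$z, t2$z)
  expect_false(identical(t1$z, simulate_network(G, 0.5, params = p,
                                                seed = 4)$z))

  # alpha = 0 from z = 0: the origin is a fixed point, no escape ever
  quiet <- simulate_network(G, 0.5, params = z6_params(alpha = 0, t_max = 20),
                            seed = 1)
  expect_true(all(Mod(quiet$z) == 0))
  et <- escape_times(quiet)
  expect_true(all(et$censored))
  expect_equal(et$network_mean, 20)
})

test_that("trajectory and batch escape paths agree for the same stream", {
  G <- normalize_coupling(mvar5_ground_truth()$adjacency)
  p <- z6_params(t_max = 60)
  tr <- simulate_network(G, 0.4, params = p, seed = 9)
  et <- escape_times(tr)
  batch <- epitarget:::network_escape_samples(G, rep(0.4, 5), p, 1, seed = 9)
  filled <- ifelse(is.na(et$times), p$t_max, et$times)
  expect_equal(unname(mean(filled)), batch$mean_tes, tolerance = 1e-12)
})

test_that("fully excitable networks escape quickly", {
  p <- z6_params(t_max = 50)
  s <- epitarget:::network_escape_samples(matrix(0, 5, 5), rep(1, 5), p,
                                          100, seed = 5)
  expect_gte(1 - s$censor_frac, 0.95)          # >= 95% of node-escapes by t=50
  expect_equal(s$n_diverged, 0)
})

test_that("escape time decreases with excitability", {
  par <- z6_params()
  G <- matrix(0, 5, 5)
  med <- vapply(c(0.15, 0.45), function(lam) {
    median(epitarget:::network_escape_samples(G, rep(lam, 5), par, 50,
                                              seed = 6)$mean_tes)
  }, numeric(1))
  expect_lt(med[2], med[1])
})

test_that("Monte-Carlo error of T0 shrinks like one over sqrt(n)", {
  G <- matrix(0, 4, 4)
  par <- z6_params()
  t0_at <- function(n, rep) {
    mean(epitarget:::network_escape_samples(G, rep(0.5, 4), par, n,
                                            seed = 1000 * rep)$mean_tes)
  }
  sd_small <- sd(vapply(1:25, function(r) t0_at(20, r), numeric(1)))
  sd_big <- sd(vapply(1:25, function(r) t0_at(40, r + 100), numeric(1)))
  ratio <- sd_small / sd_big
  expect_gt(ratio, sqrt(2) * 0.7)
  expect_lt(ratio, sqrt(2) * 1.3)
})

test_that("hub perturbation outweighs an isolated node", {
  # hub (node 1) drives nodes 2-4; node 5 is fully disconnected
  W <- matrix(0, 5, 5)
  W[2:4, 1] <- 1
  G <- normalize_coupling(W)
  wins <- vapply(1:10, function(r) {
    d <- delta_t_map(G, 0.3, 0.9, n_realizations = 30, seed = 2000 + r)
    d$delta_t[1] > d$delta_t[5]
  }, logical(1))
  expect_true(all(wins))
})

test_that("divergent realizations are flagged, not fatal", {
  # a = +1 makes the quintic term destabilizing: |z| blows past 10
  p <- z6_params(a = 1, t_max = 20)
  tr <- simulate_network(matrix(0, 2, 2), 1, params = p, seed = 1)
  expect_true(tr$diverged)
})
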