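test_that("five-node process follows the printed recursions", {
  rec <- mvar5_long()
  x <- unclass(rec)

  # direct OLS of X2(n) on X1(n-2): the true cross coefficient is 0.5
  n <- nrow(x)
  b <- coef(lm(x[3:n, 2] ~ x[1:(n - 2), 1]))[2]
  expect_lt(abs(b - 0.5), 0.02)

  # full Yule-Walker refit recovers every coefficient
  fit <- fit_mvar(rec, max_order = 5)
  expect_gte(fit$order, 3)
  truth <- epitarget:::mvar5_coeffs()
  expect_lt(max(abs(fit$coeffs[, , 1:3] - truth)), 0.03)

  # covariance stationarity: split-half variance ratio near 1
  v1 <- apply(x[1:(n %/% 2), ], 2, var)
  v2 <- apply(x[(n %/% 2 + 1):n, ], 2, var)
  expect_true(all(v1 / v2 > 0.8 & v1 / v2 < 1.25))
})

test_that("simulator is seed-deterministic and validates arguments", {
  a <- simulate_mvar5(600, seed = 5)
  b <- simulate_mvar5(600, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(simulate_mvar5(600, seed = 6))))
  expect_error(simulate_mvar5(100), class = "epitarget_invalid")
  expect_error(simulate_mvar5(1000, noise_sd = -1), class = "epitarget_invalid")
})

test_that("ground truth stores the printed cross-coupling magnitudes", {
  gt <- mvar5_ground_truth()
  A <- gt$adjacency
  expect_equal(A["X3", "X1"], 0.4)
  expect_equal(A["X2", "X3"], 0)
  expect_equal(A["X2", "X1"], 0.5)
  expect_equal(A["X4", "X1"], 0.5)
  expect_equal(A["X4", "X5"], 0.252)
  expect_equal(A["X5", "X4"], 0.252)
  expect_equal(sum(A != 0), 5)
  expect_identical(gt$hub_index, 1L)
  expect_true(all(diag(A) == 0))
})

test_that("planted-hub generator honors its contract", {
  syn <- generate_synthetic_ieeg(8, hub_index = 3, duration_s = 4, seed = 2)
  expect_equal(dim(syn$recording), c(round(4 * 500), 8))
  expect_equal(sampling_rate(syn$recording), 500)   # fs defaults to 500
  expect_identical(syn$truth$hub_index, 3L)

  for (s in 1:5) {
    tr <- generate_synthetic_ieeg(7, hub_index = 2, duration_s = 2,
                                  seed = s)$truth
    out_deg <- colSums(tr$adjacency != 0)
    expect_identical(unname(which.max(out_deg)), 2L)  # hub has max out-degree
    expect_gte(out_deg[2], 3)
    w <- tr$adjacency[tr$adjacency != 0]
    expect_true(all(w >= 0.3 & w <= 0.6))
  }
  expect_error(generate_synthetic_ieeg(4, 1, 1), class = "epitarget_invalid")
  expect_error(generate_synthetic_ieeg(6, 9, 1), class = "epitarget_invalid")
})

test_that("electrode layouts are reproducible grids with valid flags", {
  labs <- paste0("E", 1:9)
  el <- generate_electrode_layout(labs, resected_labels = c("E2", "E5"),
                                  seed = 3)
  expect_identical(el$label, labs)
  expect_identical(sum(el$resected), 2L)
  expect_identical(el, generate_electrode_layout(labs, c("E2", "E5"), seed = 3))

  # pairwise distances: symmetric, zero diagonal, 10 mm pitch multiples
  xyz <- as.matrix(el[, c("x_mm", "y_mm", "z_mm")])
  D <- as.matrix(dist(xyz))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))

  expect_equal(distance_to_resection("E2", el), 0)
  expect_error(generate_electrode_layout(labs, "nope"),
               class = "epitarget_invalid")
  expect_error(generate_electrode_layout(c("a", "a")),
               class = "epitarget_invalid")
})

test_that("recordings and electrode sets round-trip through CSV", {
  rec <- simulate_mvar5(600, seed = 9, fs = 250)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_equal(sampling_rate(back), 250)
  expect_equal(channel_labels(back), channel_labels(rec))
  expect_equal(unclass(back), unclass(rec), tolerance = 1e-12,
               ignore_attr = TRUE)

  el <- generate_electrode_layout(paste0("X", 1:5), "X4", seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_electrodes(el, f2)
  expect_equal(as.data.frame(read_electrodes(f2)), as.data.frame(el))
})
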