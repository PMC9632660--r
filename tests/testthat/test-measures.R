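test_that("Pearson matrix reflects linear coupling magnitudes", {
  x <- withr::with_seed(1, rnorm(2000))
  twin <- mc_recording(cbind(a = x, b = x + 1e-8 * rnorm(2000)), fs = 500)
  expect_gt(unclass(pearson_matrix(twin))[1, 2], 0.999)

  indep <- mc_recording(withr::with_seed(2, matrix(rnorm(10000 * 2), ncol = 2)),
                        fs = 500)
  expect_lt(unclass(pearson_matrix(indep))[1, 2], 0.05)

  # X1 drives X2 directly; X2 and X3 share only the common driver
  P <- unclass(pearson_matrix(mvar5_long()))
  expect_gt(P[1, 2], P[2, 3])

  const <- mc_recording(cbind(rnorm(500), rep(2, 500)), fs = 500)
  expect_error(pearson_matrix(const), class = "epitarget_degenerate")
})

test_that("wPLI detects quadrature phase coupling and ignores zero lag", {
  fs <- 500
  t <- seq(0, 2, length.out = 2 * fs)
  s1 <- sin(2 * pi * 40 * t)
  s2 <- sin(2 * pi * 40 * t + pi / 2)
  noisy <- withr::with_seed(3, cbind(s1 + 0.1 * rnorm(length(t)),
                                     s2 + 0.1 * rnorm(length(t))))
  w <- wpli_matrix(mc_recording(noisy, fs = fs), band = c(31, 80))
  expect_gte(unclass(w)[1, 2], 0.9)
  expect_equal(unclass(w), t(unclass(w)), ignore_attr = TRUE)
  expect_true(all(unclass(w) >= 0 & unclass(w) <= 1))

  # zero-lag identical signals: the imaginary cross term vanishes
  same <- mc_recording(cbind(s1, s1 + 1e-12), fs = fs)
  expect_equal(unclass(wpli_matrix(same))[1, 2], 0)
})

test_that("KL spectrogram divergence is zero on self, asymmetric across", {
  fs <- 500
  t <- seq(0, 4, length.out = 4 * fs)
  x10 <- sin(2 * pi * 10 * t)
  x10b <- sin(2 * pi * 10 * t + 1)
  x60 <- 0.5 * sin(2 * pi * 60 * t)
  rec <- mc_recording(withr::with_seed(4, cbind(a = x10 + 0.05 * rnorm(length(t)),
                                                b = x10b + 0.05 * rnorm(length(t)),
                                                c = x60 + 0.05 * rnorm(length(t)))),
                      fs = fs)
  D <- unclass(kldiv_matrix(rec))
  expect_true(all(diag(D) == 0))          # D(W, W) = 0 by construction
  expect_true(all(D >= 0))
  expect_false(isTRUE(all.equal(D[1, 3], D[3, 1])))   # asymmetric
  expect_gte(D[1, 3], 10 * D[1, 2])       # 10 vs 60 Hz >> 10 vs 10 Hz
})
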