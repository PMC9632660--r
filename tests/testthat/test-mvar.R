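test_that("Yule-Walker solution matches a direct least-squares oracle", {
  rec <- mvar5_long()
  fit <- fit_mvar(rec, max_order = 6)
  p <- fit$order
  X <- sweep(unclass(rec), 2, colMeans(unclass(rec)))
  n <- nrow(X); N <- ncol(X)
  # independent oracle: multivariate OLS on lagged regressors
  Y <- X[(p + 1):n, ]
  Z <- do.call(cbind, lapply(1:p, function(j) X[(p + 1 - j):(n - j), ]))
  B <- qr.solve(Z, Y)
  A_ls <- array(0, c(N, N, p))
  for (j in 1:p) A_ls[, , j] <- t(B[((j - 1) * N + 1):(j * N), ])
  expect_lt(max(abs(fit$coeffs - A_ls)), 2e-3)

  # the printed lag-2 coefficient from node 1 to node 2
  expect_lt(abs(fit$coeffs[2, 1, 2] - 0.5), 0.03)
})

test_that("FPE order selection reaches the true maximal lag", {
  hits <- 0
  for (s in 1:10) {
    fit <- fit_mvar(simulate_mvar5(10000, seed = 300 + s), max_order = 8)
    if (fit$order >= 3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("white-noise null gives near-zero coefficients", {
  rec <- mc_recording(withr::with_seed(4, matrix(rnorm(10000 * 4), ncol = 4)),
                      fs = 500)
  fit <- fit_mvar(rec)
  expect_lt(max(abs(fit$coeffs)), 0.05)
})

test_that("degenerate channels are rejected", {
  m <- cbind(rnorm(500), rep(1, 500))
  rec <- mc_recording(m, fs = 500)
  expect_error(fit_mvar(rec), class = "epitarget_degenerate")
})

test_that("tidy and glance expose the fitted model", {
  fit <- fit_mvar(mvar5_rec(1), max_order = 5)
  td <- tidy(fit)
  expect_named(td, c("lag", "receiver", "sender", "coefficient"))
  expect_equal(nrow(td), fit$order * 25)
  expect_equal(td$coefficient[td$lag == 1 & td$receiver == "X1" &
                                td$sender == "X1"],
               fit$coeffs[1, 1, 1])
  gl <- glance(fit)
  expect_equal(gl$order, fit$order)
  expect_equal(gl$n_channels, 5)
})
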