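test_that("DTF rows are exactly normalized and bounded", {
  fit <- fit_mvar(mvar5_rec(1), max_order = 8)
  sp <- dtf_spectrum(fit, 31:80)
  sums <- apply(sp$values, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  expect_true(all(sp$values >= 0 & sp$values <= 1))
  expect_error(dtf_spectrum(fit, c(100, 300)), class = "epitarget_invalid")
})

test_that("DTF and PDC recover the 1 -> 2 direction", {
  dtf_hits <- pdc_hits <- 0
  for (s in 1:10) {
    fit <- fit_mvar(simulate_mvar5(2000, seed = 400 + s), max_order = 6)
    d <- epitarget:::band_collapse(dtf_spectrum(fit, 31:80))
    p <- epitarget:::band_collapse(pdc_spectrum(fit, 31:80))
    if (d[2, 1] > d[1, 2]) dtf_hits <- dtf_hits + 1
    if (p[2, 1] > p[1, 2]) pdc_hits <- pdc_hits + 1
  }
  expect_gte(dtf_hits, 9)
  expect_gte(pdc_hits, 9)
})

test_that("PDC columns are exactly normalized; null coupling stays flat", {
  fit <- fit_mvar(mvar5_rec(2), max_order = 8)
  sp <- pdc_spectrum(fit, 31:80)
  sums <- apply(sp$values^2, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)

  nullrec <- mc_recording(withr::with_seed(8, matrix(rnorm(8000 * 3), ncol = 3)),
                          fs = 500)
  nfit <- fit_mvar(nullrec)
  np <- epitarget:::band_collapse(pdc_spectrum(nfit, 31:80))
  expect_lt(max(epitarget:::offdiag(np)), 0.1)
})

test_that("iCoh suppresses the indirect 1 -> 4 -> 5 chain", {
  hits <- 0
  for (s in 1:10) {
    fit <- fit_mvar(simulate_mvar5(5000, seed = 500 + s), max_order = 6)
    ic <- epitarget:::band_collapse(icoh_spectrum(fit, 31:80))
    expect_true(all(ic >= 0 & ic <= 1))
    expect_true(all(diag(ic) == 0))
    if (ic[5, 4] >= 5 * ic[5, 1]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("spectral estimators commute with channel relabeling", {
  rec <- mvar5_rec(3)
  perm <- c(4, 2, 5, 1, 3)
  prec <- mc_recording(unclass(rec)[, perm], fs = sampling_rate(rec),
                       labels = channel_labels(rec)[perm])
  for (method in c("dtf", "pdc", "icoh")) {
    m1 <- epitarget:::raw_network(rec, method)
    m2 <- epitarget:::raw_network(prec, method)
    expect_equal(unclass(m2), unclass(m1)[perm, perm], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})
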