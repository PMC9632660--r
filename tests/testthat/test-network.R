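test_that("build_network output respects the matrix contract", {
  rec <- mvar5_rec(1)
  for (method in c("dtf", "pdc", "icoh", "pcc", "wpli", "kldiv")) {
    m <- build_network(rec, method)
    expect_true(all(diag(unclass(m)) == 0))
    expect_true(all(unclass(m) >= 0))
    expect_identical(attr(m, "directed"),
                     !method %in% c("pcc", "wpli"))
  }
  expect_error(build_network(rec, "dtf", band = c(200, 400)),
               class = "epitarget_invalid")
  expect_error(build_network(rec, "granger"), class = "epitarget_invalid")
})

test_that("directed estimators rank true edges above false edges", {
  truth <- mvar5_ground_truth()$adjacency
  pos <- epitarget:::offdiag(truth) > 0
  for (method in c("dtf", "pdc", "icoh")) {
    aucs <- vapply(1:10, function(s) {
      w <- epitarget:::offdiag(epitarget:::raw_network(mvar5_rec(s), method))
      r <- rank(w)
      (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    }, numeric(1))
    expect_gt(mean(aucs), 0.9)
  }
})

test_that("benchmark returns all nine methods, best scoring exactly 1", {
  b <- mvar5_benchmark(1)
  expect_equal(nrow(b), 9)
  expect_setequal(b$method, c("PCC", "DTF", "DTF-SA", "PDC", "PDC-SA",
                              "ICOH", "ICOH-SA", "WPLI", "KLDIV"))
  expect_equal(max(b$score), 1)
  expect_equal(b$score, b$correlation / max(b$correlation))
  # the MVAR-based estimators dominate the benchmark on this process
  expect_gt(max(b$correlation[b$method %in% c("DTF", "PDC", "ICOH")]), 0.8)
})

test_that("connectivity matrices round-trip through CSV and edge lists", {
  m <- mvar5_dtfsa(1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_conn_matrix(m, f)
  back <- read_conn_matrix(f)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(back, "method"), attr(m, "method"))
  expect_equal(attr(back, "band"), attr(m, "band"))

  ed <- tidy(m)
  expect_named(ed, c("receiver", "sender", "weight", "method",
                     "band_lo", "band_hi"))
  expect_equal(nrow(ed), sum(unclass(m) != 0))
})
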