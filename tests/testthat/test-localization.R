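test_that("localization validates its inputs", {
  expect_error(mc_recording(matrix(rnorm(100), ncol = 1), fs = 500),
               class = "epitarget_invalid")
  expect_error(localize_target(list()), class = "epitarget_invalid")
})

test_that("identity resection reproduces the unresected target", {
  syn <- hub_synth(1)
  el <- generate_electrode_layout(channel_labels(syn$recording), seed = 1)
  plain <- suppressWarnings(
    localize_target(syn$recording, method = "dtf", lambda0 = 0.22,
                    lambda1 = 1.0, n_realizations = 30, seed = 5))
  resected <- suppressWarnings(
    virtual_resection(syn$recording, el, method = "dtf",
                      n_realizations = 30, seed = 5))
  expect_identical(resected$target, plain$target)
  expect_equal(resected$delta_t, plain$delta_t)
})

test_that("resected channels vanish from the report", {
  syn <- hub_synth(1)
  labs <- channel_labels(syn$recording)
  hub_lab <- syn$truth$labels[syn$truth$hub_index]
  drop <- setdiff(labs, hub_lab)[1:2]
  el <- generate_electrode_layout(labs, resected_labels = drop, seed = 2)
  rep <- suppressWarnings(
    virtual_resection(syn$recording, el, method = "dtf",
                      n_realizations = 20, seed = 5))
  expect_false(any(drop %in% rep$labels))
  expect_length(rep$delta_t, length(labs) - 2)
  expect_equal(rep$lambda0, 0.22)
  expect_equal(rep$lambda1, 1.0)

  all_but_one <- generate_electrode_layout(labs, labs[-1], seed = 2)
  expect_error(virtual_resection(syn$recording, all_but_one, method = "dtf"),
               class = "epitarget_invalid")
})

test_that("the chosen target is invariant to channel permutation", {
  syn <- hub_synth(2)
  rec <- syn$recording
  perm <- withr::with_seed(1, sample(n_channels(rec)))
  prec <- mc_recording(unclass(rec)[, perm], fs = sampling_rate(rec),
                       labels = channel_labels(rec)[perm])
  r1 <- suppressWarnings(localize_target(rec, method = "dtf", lambda0 = 0.3,
                                         lambda1 = 0.9, n_realizations = 40,
                                         seed = 6))
  r2 <- suppressWarnings(localize_target(prec, method = "dtf", lambda0 = 0.3,
                                         lambda1 = 0.9, n_realizations = 40,
                                         seed = 6))
  expect_identical(r1$target, r2$target)   # same physical channel
})

test_that("distances to resection are minima over resected contacts", {
  el <- tibble::tibble(label = c("A", "B", "C", "D"),
                       x_mm = c(0, 30, 0, 10),
                       y_mm = c(0, 0, 40, 0),
                       z_mm = 0,
                       resected = c(FALSE, TRUE, TRUE, FALSE))
  class(el) <- c("electrode_set", class(el))
  # brute-force minimum over both resected contacts
  expect_equal(distance_to_resection("A", el), min(30, 40))
  expect_equal(distance_to_resection("D", el), 20)
  expect_equal(distance_to_resection("B", el), 0)
  expect_error(distance_to_resection("Z", el), class = "epitarget_invalid")

  none <- el
  none$resected <- FALSE
  expect_true(is.na(distance_to_resection("A", none)))
})

test_that("modulation validation normalizes and is null on rings", {
  # symmetric ring: all nodes exchangeable, a random 'target' shows nothing
  N <- 6
  W <- matrix(0, N, N)
  for (i in 1:N) W[i, i %% N + 1] <- W[i %% N + 1, i] <- 1
  G <- normalize_coupling(W)
  val <- validate_modulation(G, target = 2, lambda0 = 0.5,
                             n_realizations = 40, seed = 8)
  expect_true(all(val$samples$tes_norm >= 0 & val$samples$tes_norm <= 1))
  expect_gt(val$p_value, 0.01)

  # degenerate: noiseless network never escapes -> explicit failure
  expect_error(validate_modulation(G, 1, lambda0 = 0.5, n_realizations = 3,
                                   seed = 1,
                                   params = z6_params(alpha = 0, t_max = 5)),
               class = "epitarget_censored")
})
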