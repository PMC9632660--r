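# Shared fixtures, computed once per test session.  The expensive objects
# (long simulations, surrogate-thresholded networks) are reused across
# test files; everything is derived from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# 100 s of the five-node benchmark process, for coefficient-recovery checks.
mvar5_long <- function() cached("mvar5_long", simulate_mvar5(50000, seed = 1))

# 10 s recording (the validation setting) per seed.
mvar5_rec <- function(seed) {
  cached(paste0("mvar5_rec_", seed), simulate_mvar5(5000, seed = seed))
}

# Surrogate-thresholded DTF network of the 10 s recording, per seed.
mvar5_dtfsa <- function(seed) {
  cached(paste0("mvar5_dtfsa_", seed), suppressWarnings(
    build_network(mvar5_rec(seed), "dtf-sa", seed = seed)))
}

# Planted-hub synthetic iEEG (10 channels, 20 s) per seed; hub position
# varies with the seed so recovery is not an artifact of node order.
hub_synth <- function(seed) {
  cached(paste0("hub_synth_", seed),
         generate_synthetic_ieeg(10, hub_index = (seed %% 10) + 1,
                                 duration_s = 20, seed = seed))
}

# Full localization report on the planted-hub recording, per seed.
hub_report <- function(seed) {
  cached(paste0("hub_report_", seed), suppressWarnings(
    localize_target(hub_synth(seed)$recording, lambda0 = 0.3, lambda1 = 0.9,
                    n_realizations = 50, seed = seed)))
}

# Nine-method benchmark on the 10 s recording, per seed.
mvar5_benchmark <- function(seed) {
  cached(paste0("mvar5_benchmark_", seed),
         benchmark_methods(mvar5_rec(seed), mvar5_ground_truth(),
                           seed = seed))
}
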