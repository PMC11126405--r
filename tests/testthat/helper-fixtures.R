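# Shared desk-scale fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Boosted-tree config small enough for toy cohorts: min_child_weight must be
# tiny because classes have only a handful of samples.
tiny_config <- function(nrounds = 30L) {
  list(max_depth = 3L, eta = 0.3, nrounds = nrounds, subsample = 1,
       colsample_bytree = 1, lambda = 1, min_child_weight = 0.1)
}

small_archetypes <- function(seed = 3L, pair_delta = 0.5) {
  make_archetypes(default_probe_grid(400L), segments_per_class = 3L,
                  min_seg_probes = 5L, max_seg_probes = 12L,
                  pair_delta = pair_delta, seed = seed)
}

small_cohort <- function(n = 80L, noise_sd = 0.1, seed = 5L, ...) {
  arch <- cached("small_arch", small_archetypes())
  simulate_cohort(arch, n, noise_sd = noise_sd, seed = seed, ...)
}

# Study-scale fixture: the default generator conditions (2000-probe grid,
# default archetype geometry, two-platform pair n = 1000 / 500) with a
# trained cascade. Built once; shared by the cross-cutting pipeline checks.
study_fit <- function() {
  cached("study_fit", {
    arch <- make_archetypes(default_probe_grid(2000L), seed = 101L)
    pair <- simulate_two_platform_pair(arch, n_train = 1000L, n_test = 500L,
                                       seed = 101L)
    regions <- suppressWarnings(
      derive_regions(pair$train$profiles, pair$train$labels))
    ftr <- suppressWarnings(
      cohort_features(pair$train$profiles, regions, scale = TRUE))
    fte <- suppressWarnings(
      cohort_features(pair$test$profiles, regions, scale = TRUE))
    bundle <- train_cascade(ftr, pair$train$labels, seed = 101L)
    list(archetypes = arch, pair = pair, regions = regions,
         features_train = ftr, features_test = fte, bundle = bundle)
  })
}

# A trained toy bundle with its cohorts, regions and features.
small_fit <- function() {
  cached("small_fit", {
    arch <- cached("small_arch", small_archetypes())
    cohort <- small_cohort(n = 100L, noise_sd = 0.1, seed = 5L)
    regions <- suppressWarnings(
      derive_regions(cohort$profiles, cohort$labels, kmin = 3L))
    features <- suppressWarnings(
      cohort_features(cohort$profiles, regions, scale = TRUE))
    bundle <- train_cascade(features, cohort$labels,
                            multiclass_config = tiny_config(),
                            binary_configs = tiny_config(), seed = 1L)
    list(archetypes = arch, cohort = cohort, regions = regions,
         features = features, bundle = bundle)
  })
}
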