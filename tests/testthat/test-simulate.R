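test_that("archetypes are seeded, piecewise constant, with the pair structure", {
  a1 <- small_archetypes(seed = 3)
  a2 <- small_archetypes(seed = 3)
  expect_identical(a1$profiles, a2$profiles)
  expect_identical(a1$segments, a2$segments)

  # paired archetypes differ at exactly pair_segments contiguous runs
  for (p in intclust_pairs()) {
    diffmask <- a1$profiles[p[1], ] != a1$profiles[p[2], ]
    runs <- rle(diffmask)
    expect_equal(sum(runs$values), 2L)  # pair_segments default in fixture
  }

  # pair_delta = 0 collapses each pair
  a0 <- small_archetypes(seed = 3, pair_delta = 0)
  for (p in intclust_pairs()) {
    expect_identical(a0$profiles[p[1], ], a0$profiles[p[2], ])
  }

  expect_error(make_archetypes(default_probe_grid(100)), "capacity")
})

test_that("noise-free simulation reproduces archetypes exactly", {
  arch <- small_archetypes()
  coh <- simulate_cohort(arch, 20, noise_sd = 0, seed = 5)
  wide <- tidyr::pivot_wider(coh$profiles, id_cols = "sample_id",
                             names_from = c("chrom", "pos"),
                             values_from = "value")
  m <- as.matrix(wide[, -1])
  for (i in seq_len(nrow(m))) {
    cls <- coh$labels$intclust[coh$labels$sample_id == wide$sample_id[i]]
    expect_equal(unname(m[i, ]), unname(arch$profiles[cls, ]))
  }
})

test_that("cohort simulation is seeded and validates its spec", {
  arch <- small_archetypes()
  c1 <- simulate_cohort(arch, 30, seed = 9, missing_fraction = 0.1)
  c2 <- simulate_cohort(arch, 30, seed = 9, missing_fraction = 0.1)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$labels, c2$labels)
  expect_gt(mean(is.na(c1$profiles$value)), 0.05)

  expect_error(simulate_cohort(arch, 10, class_proportions = rep(0.2, 10)),
               "sum to 1")
  expect_error(simulate_cohort(arch, 10, missing_fraction = 1), "missing_fraction")
  expect_error(simulate_cohort(arch, 10, attenuation = 0), "attenuation")
})

test_that("sample region means converge to archetype region means", {
  arch <- small_archetypes()
  sigma <- 0.3
  n <- 200L
  coh <- simulate_cohort(arch, n, class_proportions = c(1, rep(0, 9)),
                         noise_sd = sigma, seed = 17)
  regions <- tibble::tibble(chrom = "1", start = 1L, end = max(arch$grid$pos),
                            region_id = "1:all")
  feats <- cohort_features(coh$profiles, regions)
  n_probes_chr1 <- sum(arch$grid$chrom == "1")
  arch_mean <- mean(arch$profiles[1, arch$grid$chrom == "1"])
  sample_means <- features_matrix(feats)[, 1]
  # Monte-Carlo against the analytic mean: cohort mean of per-sample region
  # means has sd sigma / sqrt(n * n_probes)
  expect_lt(abs(mean(sample_means) - arch_mean),
            3 * sigma / sqrt(n * n_probes_chr1))
})

test_that("platform pairs share archetypes across different grids", {
  arch <- small_archetypes()
  pair <- simulate_two_platform_pair(arch, n_train = 60, n_test = 60,
                                     seed = 21)
  g_tr <- profile_grid(pair$train$profiles)
  g_te <- profile_grid(pair$test$profiles)
  expect_lt(nrow(g_te), nrow(g_tr))
  expect_false(isTRUE(all.equal(g_te$pos[1:10], g_tr$pos[1:10])))

  # reproducibility of the whole pair
  pair2 <- simulate_two_platform_pair(arch, n_train = 60, n_test = 60,
                                      seed = 21)
  expect_identical(pair$test$profiles, pair2$test$profiles)

  # regions derived on the training platform apply to both; after scaling,
  # per-class region means of the two cohorts agree closely at small noise.
  # Class means on the z-scale carry 1/sqrt(n_c) sampling error per region,
  # so the check needs sizeable balanced classes.
  lowpair <- simulate_two_platform_pair(
    arch, n_train = 500, n_test = 500, seed = 23,
    train_spec = list(noise_sd = 0.05),
    test_spec = list(noise_sd = 0.05, attenuation = 0.5, offset = 0.2),
    class_proportions = rep(0.1, 10))
  regions <- suppressWarnings(
    derive_regions(lowpair$train$profiles, lowpair$train$labels, kmin = 3))
  ftr <- suppressWarnings(
    cohort_features(lowpair$train$profiles, regions, scale = TRUE))
  fte <- suppressWarnings(
    cohort_features(lowpair$test$profiles, regions, scale = TRUE))
  class_means <- function(f, labels) {
    m <- features_matrix(f)
    cls <- labels$intclust[match(rownames(m), labels$sample_id)]
    t(vapply(sort(unique(cls)),
             function(k) colMeans(m[cls == k, , drop = FALSE], na.rm = TRUE),
             numeric(ncol(m))))
  }
  mtr <- class_means(ftr, lowpair$train$labels)
  mte <- class_means(fte, lowpair$test$labels)
  common <- sort(intersect(lowpair$train$labels$intclust,
                           lowpair$test$labels$intclust))
  cors <- vapply(seq_along(common), function(i) {
    ok <- is.finite(mtr[i, ]) & is.finite(mte[i, ])
    cor(mtr[i, ok], mte[i, ok])
  }, numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("cohorts round-trip through the standard on-disk formats", {
  arch <- small_archetypes()
  coh <- simulate_cohort(arch, 12, noise_sd = 0.1, seed = 25)
  dir <- tempfile()
  write_cohort(coh, dir, archetypes = arch)
  expect_true(all(file.exists(file.path(dir, c("matrix.tsv", "labels.tsv",
                                               "cohort.seg")))))
  prof <- read_profile_matrix(file.path(dir, "matrix.tsv"))
  expect_equal(nrow(prof), nrow(coh$profiles))
  expect_equal(read_labels(file.path(dir, "labels.tsv")), coh$labels)
  segs <- read_seg(file.path(dir, "cohort.seg"))
  # SEG projection back onto the grid reproduces each sample's archetype
  s1 <- coh$labels$sample_id[1]
  cls <- coh$labels$intclust[1]
  back <- segments_to_profile(segs[segs$sample_id == s1, ], arch$grid,
                              sample_id = s1)
  expect_equal(back$value, unname(arch$profiles[cls, ]))
})
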