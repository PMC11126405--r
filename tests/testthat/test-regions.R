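toy_profiles <- function() {
  # 3 samples, shared 4-locus grid on chr1
  tidyr::expand_grid(sample_id = c("a", "b", "c"),
                     chrom = "1", pos = c(10L, 20L, 30L, 40L)) %>%
    dplyr::mutate(value = c(0, 0, 1, 1,   2, 2, 3, 3,   4, 4, NA, 5))
}

test_that("class averages are missing-aware per-locus means", {
  prof <- toy_profiles()
  labels <- tibble::tibble(sample_id = c("a", "b", "c"),
                           intclust = c(1L, 1L, 1L))
  avg <- class_average_profile(prof, labels, 1)
  expect_equal(avg$value, c(2, 2, 2, 3))  # locus 30: mean(1, 3) over non-missing

  one <- class_average_profile(prof, tibble::tibble(sample_id = "b",
                                                    intclust = 2L), 2)
  expect_equal(one$value, c(2, 2, 3, 3))

  two <- class_average_profile(
    prof[prof$sample_id != "c", ],
    tibble::tibble(sample_id = c("a", "b"), intclust = c(3L, 3L)), 3)
  expect_equal(two$value[1], 1)  # mean of 0 and 2

  expect_error(class_average_profile(prof, labels, 9), "no samples")
})

fake_segmentation <- function(chrom, start_bp, end_bp, cut_bp) {
  tibble::tibble(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 cut_bp = cut_bp)
}

test_that("regions are the sorted breakpoint union cut into abutting intervals", {
  # chr1 extent 1-200; class A cuts after bp 100, class B after bp 150
  a <- fake_segmentation("1", c(1L, 101L), c(100L, 200L), c(NA, 100L))
  b <- fake_segmentation("1", c(1L, 151L), c(150L, 200L), c(NA, 150L))
  regions <- build_regions(list(A = a, B = b),
                           extents = tibble::tibble(chrom = "1", min_bp = 1L,
                                                    max_bp = 200L))
  expect_equal(regions$start, c(1L, 101L, 151L))
  expect_equal(regions$end, c(100L, 150L, 200L))

  # duplicated breakpoints and class order do not matter
  r2 <- build_regions(list(B = b, A = a, A2 = a),
                      extents = tibble::tibble(chrom = "1", min_bp = 1L,
                                               max_bp = 200L))
  expect_equal(r2[, c("chrom", "start", "end")],
               regions[, c("chrom", "start", "end")], ignore_attr = TRUE)

  # one segment per class per chromosome -> one region per chromosome
  segs23 <- lapply(1:3, function(i) {
    fake_segmentation(cn_chromosomes(), rep(1L, 23), rep(1000L, 23),
                      rep(NA_integer_, 23))
  })
  r23 <- build_regions(segs23)
  expect_equal(nrow(r23), 23)

  expect_error(build_regions(list()), "empty")
})

test_that("derived regions partition each chromosome's probe span", {
  fit <- small_fit()
  regions <- fit$regions
  grid <- profile_grid(fit$cohort$profiles)
  for (ch in unique(regions$chrom)) {
    rr <- regions[regions$chrom == ch, ]
    rr <- rr[order(rr$start), ]
    gg <- grid[grid$chrom == ch, ]
    expect_equal(rr$start[1], min(gg$pos))
    expect_equal(rr$end[nrow(rr)], max(gg$pos))
    if (nrow(rr) > 1) {
      expect_equal(rr$start[-1], rr$end[-nrow(rr)] + 1L)  # abutting, no overlap
    }
  }
})

test_that("region means filter probes by interval membership", {
  prof <- tibble::tibble(sample_id = "s", chrom = "1",
                         pos = c(10L, 20L, 30L), value = c(1, 2, 3))
  regions <- tibble::tibble(chrom = "1", start = 1L, end = 25L,
                            region_id = "1:1-25")
  expect_equal(region_means(prof, regions)$value, 1.5)

  # constant profile -> every feature equals the constant
  fitx <- small_fit()
  const <- fitx$cohort$profiles %>%
    dplyr::filter(sample_id == sample_id[1]) %>%
    dplyr::mutate(value = 0.42)
  rm <- region_means(const, fitx$regions)
  expect_true(all(abs(rm$value - 0.42) < 1e-12))

  # region on a chromosome absent from the profile -> missing
  regions2 <- tibble::tibble(chrom = c("1", "2"), start = c(1L, 1L),
                             end = c(25L, 50L),
                             region_id = c("1:1-25", "2:1-50"))
  rm2 <- region_means(prof, regions2)
  expect_true(is.na(rm2$value[rm2$region_id == "2:1-50"]))
})

test_that("scaler centers and spreads per region, flagging degenerate columns", {
  regions <- tibble::tibble(chrom = c("1", "1"), start = c(1L, 11L),
                            end = c(10L, 20L),
                            region_id = c("1:1-10", "1:11-20"))
  prof <- tidyr::expand_grid(sample_id = c("a", "b", "c"),
                             chrom = "1", pos = c(5L, 15L)) %>%
    dplyr::mutate(value = c(1, 7, 2, 7, 3, 7))
  feats <- cohort_features(prof, regions)
  expect_warning(sc <- fit_scaler(feats), "degenerate")
  expect_equal(sc$center, c(2, 7))
  expect_equal(sc$spread, c(1, 1))
  expect_equal(sc$degenerate, c(FALSE, TRUE))

  expect_error(fit_scaler(feats[1:2, ]), "few samples")

  scaled <- apply_scaler(feats, sc)
  expect_true(attr(scaled, "scaled"))
  expect_equal(scaled[["1:1-10"]], c(-1, 0, 1))
})

test_that("fit+apply standardizes every column of a random matrix", {
  withr::with_seed(37, {
    cohort <- small_cohort(n = 50L, noise_sd = 0.3, seed = 9L)
    fit <- small_fit()
    feats <- cohort_features(cohort$profiles, fit$regions)
    scaled <- apply_scaler(feats, fit_scaler(feats))
    m <- features_matrix(scaled)
    expect_true(all(abs(colMeans(m, na.rm = TRUE)) < 1e-10))
    sds <- apply(m, 2, sd, na.rm = TRUE)
    expect_true(all(abs(sds - 1) < 1e-10))
  })
})

test_that("scaling removes cohort-wide affine shifts and keeps missing missing", {
  fit <- small_fit()
  prof <- small_cohort(n = 40L, noise_sd = 0.2, seed = 13L,
                       missing_fraction = 0.05)$profiles
  shifted <- dplyr::mutate(prof, value = 0.6 * value + 0.25)
  f1 <- cohort_features(prof, fit$regions, scale = TRUE)
  f2 <- cohort_features(shifted, fit$regions, scale = TRUE)
  m1 <- features_matrix(f1); m2 <- features_matrix(f2)
  expect_identical(is.na(m1), is.na(m2))
  expect_true(max(abs(m1 - m2), na.rm = TRUE) < 1e-8)

  # already-standardized columns unchanged
  f3 <- apply_scaler(f1, fit_scaler(f1))
  expect_true(max(abs(features_matrix(f3) - m1), na.rm = TRUE) < 1e-10)

  bad <- fit_scaler(f1)[1:3, ]
  expect_error(apply_scaler(f1, bad), "match")
})
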