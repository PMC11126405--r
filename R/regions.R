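#' Average copy-number profile of one class
#'
#' Per-locus arithmetic mean (or median) over the samples of one class,
#' ignoring missing values; a locus missing in every class sample stays
#' missing. All profiles must share the same locus grid.
#'
#' @param profiles Long profile tibble for the cohort.
#' @param labels Label tibble (`sample_id`, `intclust`).
#' @param class_id The class (integer 1..10) to average.
#' @param stat `"mean"` (default) or `"median"`.
#' @return A single-sample profile tibble with `sample_id = "class<k>"`.
#' @export
class_average_profile <- function(profiles, labels, class_id,
                                  stat = c("mean", "median")) {
  stat <- match.arg(stat)
  labels <- validate_labels(labels)
  ids <- labels$sample_id[labels$intclust == class_id]
  if (length(ids) == 0) abort(sprintf("no samples with class %s", class_id))
  sub <- profiles[profiles$sample_id %in% ids, , drop = FALSE]
  if (!shared_grid(sub)) abort("class samples do not share a locus grid")
  fun <- if (stat == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  }
  sub %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(value = fun(.data$value), .groups = "drop") %>%
    mutate(sample_id = paste0("class", class_id), .before = 1) %>%
    arrange(chrom_rank(.data$chrom), .data$pos)
}

#' Average profiles for every class in a labelled cohort
#'
#' @inheritParams class_average_profile
#' @param classes Classes to include (default: all present in `labels`).
#' @return A named list of single-sample profile tibbles, one per class.
#' @export
class_average_profiles <- function(profiles, labels, classes = NULL,
                                   stat = c("mean", "median")) {
  stat <- match.arg(stat)
  labels <- validate_labels(labels)
  if (is.null(classes)) classes <- sort(unique(labels$intclust))
  purrr::map(purrr::set_names(classes, as.character(classes)),
             ~ class_average_profile(profiles, labels, .x, stat = stat))
}

validate_regions <- function(regions) {
  regions <- as_tibble(regions)
  if (any(regions$start > regions$end)) abort("region with start > end")
  by_chr <- split(regions, regions$chrom)
  for (rr in by_chr) {
    rr <- rr[order(rr$start), ]
    if (nrow(rr) > 1 && any(rr$start[-1] <= rr$end[-nrow(rr)])) {
      abort(sprintf("overlapping regions on chromosome %s", rr$chrom[1]))
    }
  }
  regions
}

#' Cut the genome into regions at the breakpoint union of several segmentations
#'
#' Collects the internal breakpoint positions (`cut_bp`) of every class's
#' segmentation, deduplicates them per chromosome, and cuts each
#' chromosome's extent into abutting 1-based inclusive regions. Chromosome
#' boundaries always cut, so no region spans chromosomes; per chromosome the
#' region count is the number of unique internal breakpoints plus one.
#'
#' @param segmentations A list of segmentation tibbles from
#'   [segment_profile()] (typically one per class).
#' @param extents Optional tibble (`chrom`, `min_bp`, `max_bp`); defaults to
#'   the observed probe span per chromosome across the segmentations.
#' @return A region tibble (`chrom`, `start`, `end`, `region_id`) in
#'   canonical order, with a `provenance` attribute.
#' @export
build_regions <- function(segmentations, extents = NULL) {
  if (length(segmentations) == 0) abort("empty segmentation list")
  all_seg <- bind_rows(lapply(segmentations, as_tibble))
  if (is.null(extents)) {
    extents <- all_seg %>%
      group_by(.data$chrom) %>%
      summarise(min_bp = min(.data$start_bp), max_bp = max(.data$end_bp),
                .groups = "drop")
  }
  extents <- arrange(as_tibble(extents), chrom_rank(.data$chrom))
  pieces <- vector("list", nrow(extents))
  for (i in seq_len(nrow(extents))) {
    ch <- extents$chrom[i]
    lo <- extents$min_bp[i]; hi <- extents$max_bp[i]
    cuts <- all_seg$cut_bp[all_seg$chrom == ch & !is.na(all_seg$cut_bp)]
    cuts <- sort(unique(cuts[cuts >= lo & cuts < hi]))
    starts <- c(lo, cuts + 1L)
    ends <- c(cuts, hi)
    pieces[[i]] <- tibble(chrom = ch, start = as.integer(starts),
                          end = as.integer(ends))
  }
  regions <- bind_rows(pieces)
  regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                               regions$end)
  regions <- validate_regions(regions)
  attr(regions, "provenance") <- list(
    n_segmentations = length(segmentations),
    classes = names(segmentations),
    gamma = attr(segmentations[[1]], "gamma"),
    kmin = attr(segmentations[[1]], "kmin")
  )
  regions
}

#' Derive feature regions from a labelled cohort
#'
#' The region-derivation pipeline in one call: average the profiles of each
#' class, segment each class average with the penalized piecewise-constant
#' fit, and cut the genome at the union of all classes' breakpoints.
#'
#' @inheritParams class_average_profile
#' @inheritParams segment_profile
#' @param stat Averaging statistic, `"mean"` or `"median"`.
#' @return A region tibble (see [build_regions()]); the `provenance`
#'   attribute records gamma, kmin and per-class segment counts.
#' @export
derive_regions <- function(profiles, labels, gamma = 40, kmin = 5L,
                           normalize = TRUE, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  averages <- class_average_profiles(profiles, labels, stat = stat)
  segmentations <- purrr::map(averages, segment_profile, gamma = gamma,
                              kmin = kmin, normalize = normalize)
  regions <- build_regions(segmentations)
  prov <- attr(regions, "provenance")
  prov$segments_per_class <- vapply(segmentations, nrow, integer(1))
  prov$stat <- stat
  attr(regions, "provenance") <- prov
  regions
}

#' Mean copy number per region for one profile
#'
#' @param profile A single-sample profile tibble.
#' @param regions A region tibble.
#' @return A tibble (`region_id`, `value`) in region order; regions covering
#'   no non-missing probe get `NA`.
#' @export
region_means <- function(profile, regions) {
  feats <- cohort_features(profile, regions, scale = FALSE)
  tibble(region_id = attr(feats, "region_ids"),
         value = as.numeric(as.matrix(feats[, -1])[1, ]))
}

#' Build the samples-by-regions feature matrix of a cohort
#'
#' Assigns every probe to the region containing its position (regions are
#' abutting within a chromosome, so the assignment is unique; probes outside
#' every region are dropped) and averages non-missing values per (sample,
#' region). A region with no non-missing probe for a sample is missing.
#'
#' @param profiles Long profile tibble (one or many samples).
#' @param regions A region tibble.
#' @param scale If `TRUE`, fit a scaler on this cohort and apply it (the
#'   default workflow: every cohort is scaled with its own parameters).
#' @return A `cn_features` tibble: `sample_id` plus one column per region, in
#'   region order. Attributes: `region_ids`, `regions` (the region tibble),
#'   `scaled`, and after scaling `scaler`.
#' @export
cohort_features <- function(profiles, regions, scale = FALSE) {
  regions <- as_tibble(regions)
  probe_region <- rep(NA_character_, nrow(profiles))
  for (ch in unique(regions$chrom)) {
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    pi <- which(profiles$chrom == ch)
    if (length(pi) == 0) next
    idx <- findInterval(profiles$pos[pi], rr$start)
    hit <- idx >= 1 & profiles$pos[pi] <= rr$end[pmax(idx, 1)]
    probe_region[pi[hit]] <- rr$region_id[idx[hit]]
  }
  long <- profiles %>%
    mutate(region_id = probe_region) %>%
    filter(!is.na(.data$region_id)) %>%
    group_by(.data$sample_id, .data$region_id) %>%
    summarise(value = if (all(is.na(.data$value))) NA_real_
              else mean(.data$value, na.rm = TRUE),
              .groups = "drop")
  wide <- tidyr::pivot_wider(long, id_cols = "sample_id",
                             names_from = "region_id", values_from = "value")
  for (rid in setdiff(regions$region_id, names(wide))) wide[[rid]] <- NA_real_
  wide <- wide[, c("sample_id", regions$region_id)]
  wide <- arrange(wide, .data$sample_id)
  out <- new_cn_features(wide, regions, scaled = FALSE)
  if (scale) out <- apply_scaler(out, fit_scaler(out))
  out
}

new_cn_features <- function(tbl, regions, scaled, scaler = NULL) {
  attr(tbl, "region_ids") <- regions$region_id
  attr(tbl, "regions") <- regions
  attr(tbl, "scaled") <- scaled
  if (!is.null(scaler)) attr(tbl, "scaler") <- scaler
  class(tbl) <- unique(c("cn_features", class(tbl)))
  tbl
}

#' @export
`[.cn_features` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("sample_id", attr(x, "region_ids")) %in% names(out))) {
    out <- new_cn_features(out, attr(x, "regions"),
                           scaled = attr(x, "scaled"),
                           scaler = attr(x, "scaler"))
  }
  out
}

#' Feature matrix as a plain numeric matrix
#'
#' @param features A `cn_features` tibble.
#' @return A numeric matrix with sample ids as row names.
#' @export
features_matrix <- function(features) {
  m <- as.matrix(features[, attr(features, "region_ids"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$sample_id
  m
}

#' Fit per-region scaling parameters on a reference cohort
#'
#' Center = mean and spread = standard deviation of each region's non-missing
#' values. Regions with zero (or inestimable) spread are flagged degenerate
#' and given spread 1 so scaling is a no-op shift for them.
#'
#' @param features An unscaled `cn_features` tibble.
#' @param min_samples Minimum cohort size (default 3); cohort-level scaling
#'   is meaningless for a single or very few samples.
#' @return A tibble (`region_id`, `center`, `spread`, `degenerate`).
#' @export
fit_scaler <- function(features, min_samples = 3L) {
  if (nrow(features) < min_samples) {
    abort(sprintf(paste0(
      "scaling needs >= %d samples (got %d): cohort-level feature scaling ",
      "is unreliable for a single or few samples"), min_samples,
      nrow(features)))
  }
  m <- features_matrix(features)
  center <- colMeans(m, na.rm = TRUE)
  spread <- apply(m, 2, sd, na.rm = TRUE)
  n_ok <- colSums(!is.na(m))
  degenerate <- is.na(spread) | spread == 0 | n_ok < 2
  if (any(degenerate)) {
    warn(sprintf("%d region(s) with degenerate spread; using spread 1",
                 sum(degenerate)))
  }
  center[is.na(center) | is.nan(center)] <- 0
  spread[degenerate] <- 1
  tibble(region_id = colnames(m), center = unname(center),
         spread = unname(spread), degenerate = unname(degenerate))
}

#' Apply scaling parameters to a feature matrix
#'
#' Each value becomes `(value - center) / spread`; missing values stay
#' missing.
#'
#' @param features An unscaled `cn_features` tibble.
#' @param params A scaler tibble from [fit_scaler()].
#' @return A scaled `cn_features` tibble (`scaled` attribute `TRUE`).
#' @export
apply_scaler <- function(features, params) {
  ids <- attr(features, "region_ids")
  if (!identical(ids, params$region_id)) {
    abort("scaler regions do not match the feature matrix columns")
  }
  m <- features_matrix(features)
  m <- sweep(sweep(m, 2, params$center, "-"), 2, params$spread, "/")
  out <- features
  out[, ids] <- as_tibble(m)
  new_cn_features(out, attr(features, "regions"), scaled = TRUE,
                  scaler = params)
}
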