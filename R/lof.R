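#' Local outlier factor scores
#'
#' Classical LOF with Euclidean distances. For each point, its k nearest
#' neighbours are the first k other points ordered by (distance, index) —
#' the index tie-break makes duplicated points deterministic. The k-distance
#' is the distance to the k-th such neighbour; the reachability distance
#' from a to b is `max(k-distance(b), d(a, b))`; the local reachability
#' density (lrd) is the reciprocal mean reachability distance to the
#' neighbours; and `LOF(a)` is the mean `lrd(neighbour) / lrd(a)` over a's
#' neighbours. Points in a locally homogeneous configuration score 1;
#' scores well above 1 flag outliers. A point whose neighbours coincide with
#' it (zero mean reachability) gets infinite density; ratios Inf/Inf are 1
#' by convention.
#'
#' @param x Numeric matrix or data frame of feature vectors (rows = points,
#'   no missing values).
#' @param k Number of neighbours, `1 <= k <= n - 1`.
#' @return Numeric vector of LOF scores, one per row of `x`.
#' @export
lof_scores <- function(x, k) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("lof_scores requires complete feature vectors (impute first)")
  n <- nrow(m)
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1")
  if (n <= k) abort(sprintf("need n >= k + 1 points (n = %d, k = %d)", n, k))
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  # neighbours: first k by (distance, index)
  nn <- t(apply(d, 1, function(row) order(row, seq_len(n))[seq_len(k)]))
  kdist <- d[cbind(rep(seq_len(n), k), as.vector(nn))]
  kdist <- matrix(kdist, n, k)[, k]
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nn[i, ]], d[i, nn[i, ]])
    mr <- mean(reach)
    lrd[i] <- if (mr == 0) Inf else 1 / mr
  }
  lof <- numeric(n)
  for (i in seq_len(n)) {
    r <- lrd[nn[i, ]] / lrd[i]
    r[lrd[nn[i, ]] == Inf & lrd[i] == Inf] <- 1
    lof[i] <- mean(r)
  }
  lof
}

#' Remove intra-class outliers from a training cohort
#'
#' Computes LOF scores independently within each class of a scaled feature
#' matrix and removes samples scoring above the threshold. Classes with at
#' most `k + 1` members are skipped (no removal) with a warning. Missing
#' feature values are median-imputed per region within the class for the
#' distance computation only; downstream feature values are untouched.
#'
#' @param features A scaled `cn_features` tibble.
#' @param labels Label tibble covering every sample in `features`.
#' @param k Neighbour count (default 20).
#' @param threshold LOF score above which a sample is removed (default 1.5).
#' @return A list with `retained` (character vector of sample ids) and `lof`,
#'   a tibble (`sample_id`, `intclust`, `k`, `score`, `removed`); skipped
#'   classes carry `NA` scores.
#' @export
filter_intraclass_outliers <- function(features, labels, k = 20L,
                                       threshold = 1.5) {
  labels <- validate_labels(labels)
  unlabeled <- setdiff(features$sample_id, labels$sample_id)
  if (length(unlabeled) > 0) {
    abort(paste0("unlabeled sample(s) in feature matrix: ",
                 paste(head(unlabeled, 5), collapse = ", ")))
  }
  m <- features_matrix(features)
  lab <- labels$intclust[match(rownames(m), labels$sample_id)]
  results <- list()
  for (cls in sort(unique(lab))) {
    idx <- which(lab == cls)
    if (length(idx) <= k + 1) {
      warn(sprintf("class %d has %d samples (<= k + 1 = %d): LOF skipped, all retained",
                   cls, length(idx), k + 1L))
      results[[as.character(cls)]] <- tibble(
        sample_id = rownames(m)[idx], intclust = cls, k = as.integer(k),
        score = NA_real_, removed = FALSE)
      next
    }
    sub <- m[idx, , drop = FALSE]
    # per-region median imputation within the class, for the metric only
    for (j in seq_len(ncol(sub))) {
      nas <- is.na(sub[, j])
      if (any(nas)) {
        med <- median(sub[, j], na.rm = TRUE)
        sub[nas, j] <- if (is.na(med)) 0 else med
      }
    }
    scores <- lof_scores(sub, k = k)
    results[[as.character(cls)]] <- tibble(
      sample_id = rownames(m)[idx], intclust = cls, k = as.integer(k),
      score = scores, removed = scores > threshold)
  }
  lof <- bind_rows(results)
  list(retained = lof$sample_id[!lof$removed], lof = lof)
}
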