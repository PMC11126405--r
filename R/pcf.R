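#' Within-segment sum of squared errors
#'
#' The cost kernel of the piecewise-constant fit: for a contiguous slice of
#' values, the sum of squared deviations from the slice mean, computed over
#' non-missing entries.
#'
#' @param values Numeric vector (missing allowed, but not all missing).
#' @return The SSE, a single non-negative number.
#' @export
segment_cost <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) abort("segment_cost: slice has no non-missing values")
  cost_fn <- make_cost_fn(values)
  cost_fn(1L, length(values))
}

# Prefix-sum SSE oracle: cost(i, j) of the slice values[i..j] in O(1).
# Missing values contribute nothing (skipped, but keep their grid position).
make_cost_fn <- function(values) {
  ok <- !is.na(values)
  v <- ifelse(ok, values, 0)
  s1 <- cumsum(v)
  s2 <- cumsum(v * v)
  cnt <- cumsum(ok)
  function(i, j) {
    n <- cnt[j] - if (i > 1) cnt[i - 1] else 0
    if (n == 0) return(0)
    a <- s1[j] - if (i > 1) s1[i - 1] else 0
    b <- s2[j] - if (i > 1) s2[i - 1] else 0
    max(0, b - a * a / n)
  }
}

#' Exact penalized piecewise-constant fit of an ordered signal
#'
#' Finds the global minimiser of
#' \deqn{\sum_{segments} SSE + \gamma \,(\#segments - 1)}
#' over all partitions of the index range into contiguous segments of at
#' least `kmin` points, by Bellman dynamic programming in O(n^2) with O(1)
#' prefix-sum cost queries. Missing values are skipped in the cost but keep
#' their grid positions. Ties (within a relative tolerance of 1e-9, which
#' absorbs floating-point differences between algebraically equal costs) are
#' broken toward fewer segments, then toward the earlier last breakpoint,
#' applied recursively — so the result is deterministic.
#'
#' @param values Numeric vector, ordered along the genome; `NA` allowed but
#'   at least one value must be present.
#' @param gamma Penalty per breakpoint, >= 0.
#' @param kmin Minimum segment length in grid points, >= 1.
#' @return A tibble with one row per segment: `start_index`, `end_index`
#'   (1-based inclusive), `mean` (least-squares level over non-missing
#'   points; `NA` if the segment covers none), `n_obs`. Attributes `gamma`,
#'   `kmin`, `total_cost` (sum of SSEs plus `gamma` times breakpoints) and
#'   `breakpoints` (indices after which the signal is cut).
#' @export
pcf_segment <- function(values, gamma, kmin = 1L) {
  if (gamma < 0) abort("gamma must be >= 0")
  kmin <- as.integer(kmin)
  if (kmin < 1) abort("kmin must be >= 1")
  n <- length(values)
  if (sum(!is.na(values)) < 1) abort("pcf_segment: no non-missing values")
  cost <- make_cost_fn(values)
  if (n < kmin) {
    warn(sprintf("signal length %d < kmin %d: returning a single segment", n, kmin))
    return(pcf_result(values, breaks = integer(0), gamma = gamma, kmin = kmin,
                      cost_fn = cost))
  }
  # F[j+1]: best (cost, nseg) for prefix 1..j ; F[1] is the empty prefix.
  eps <- 1e-9
  fcost <- rep(Inf, n + 1L); fcost[1] <- 0
  fnseg <- rep(NA_integer_, n + 1L); fnseg[1] <- 0L
  prev <- rep(NA_integer_, n + 1L)
  for (j in seq_len(n)) {
    if (j < kmin) next
    # last segment is (t+1)..j, t = 0 or a feasible prefix end, j - t >= kmin
    best_c <- Inf; best_n <- NA_integer_; best_t <- NA_integer_
    for (t in 0:(j - kmin)) {
      if (!is.finite(fcost[t + 1L])) next
      cand <- fcost[t + 1L] + cost(t + 1L, j) + if (t > 0) gamma else 0
      cand_n <- fnseg[t + 1L] + 1L
      if (!is.finite(best_c)) {
        best_c <- cand; best_n <- cand_n; best_t <- t
        next
      }
      tol <- eps * (1 + abs(best_c))
      if (cand < best_c - tol ||
          (cand <= best_c + tol &&
           (cand_n < best_n || (cand_n == best_n && t < best_t)))) {
        # keep the smaller cost of tied candidates to stop tolerance drift
        if (cand < best_c) best_c <- cand
        best_n <- cand_n; best_t <- t
      }
    }
    if (is.finite(best_c)) {
      fcost[j + 1L] <- best_c; fnseg[j + 1L] <- best_n; prev[j + 1L] <- best_t
    }
  }
  if (!is.finite(fcost[n + 1L])) {
    warn(sprintf("no partition into segments of length >= %d: returning a single segment", kmin))
    return(pcf_result(values, breaks = integer(0), gamma = gamma, kmin = kmin,
                      cost_fn = cost))
  }
  breaks <- integer(0)
  j <- n
  while (j > 0) {
    t <- prev[j + 1L]
    if (t > 0) breaks <- c(t, breaks)
    j <- t
  }
  pcf_result(values, breaks = breaks, gamma = gamma, kmin = kmin, cost_fn = cost)
}

pcf_result <- function(values, breaks, gamma, kmin, cost_fn) {
  n <- length(values)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  seg_mean <- numeric(length(starts))
  seg_n <- integer(length(starts))
  sse <- 0
  for (s in seq_along(starts)) {
    slice <- values[starts[s]:ends[s]]
    seg_n[s] <- sum(!is.na(slice))
    seg_mean[s] <- if (seg_n[s] > 0) mean(slice, na.rm = TRUE) else NA_real_
    sse <- sse + cost_fn(starts[s], ends[s])
  }
  out <- tibble(start_index = starts, end_index = ends,
                mean = seg_mean, n_obs = seg_n)
  attr(out, "gamma") <- gamma
  attr(out, "kmin") <- kmin
  attr(out, "breakpoints") <- as.integer(breaks)
  attr(out, "total_cost") <- sse + gamma * length(breaks)
  class(out) <- c("cn_segmentation", class(out))
  out
}

# Robust residual-sd estimate from successive differences: most adjacent
# probe pairs sit on the same segment, so median |diff| / (sqrt(2) * qnorm(.75))
# estimates the probe noise sd without being inflated by level changes.
estimate_noise_sd <- function(values) {
  d <- diff(values)
  d <- d[!is.na(d)]
  if (length(d) == 0) return(0)
  median(abs(d)) / (sqrt(2) * qnorm(0.75))
}

#' Segment a copy-number profile chromosome by chromosome
#'
#' Runs [pcf_segment()] independently within each chromosome, so breakpoints
#' are forced at every chromosome boundary and no segment ever spans two
#' chromosomes. By default the penalty is normalised by a robust estimate of
#' the probe noise variance (median absolute successive difference), i.e.
#' the effective per-breakpoint penalty is `gamma * sigma_hat^2`; this makes
#' the default `gamma = 40` meaningful across signal scales. Set
#' `normalize = FALSE` to use `gamma` on the raw SSE scale.
#'
#' @param profile A single sample's long profile tibble.
#' @param gamma Penalty per breakpoint (default 40).
#' @param kmin Minimum segment length in probes (default 5).
#' @param normalize Scale the penalty by the estimated noise variance
#'   (default `TRUE`).
#' @return A tibble with one row per segment: `chrom`, `start_index`,
#'   `end_index` (1-based within the chromosome's probe grid), `start_bp`,
#'   `end_bp` (positions of the flanking probes), `cut_bp` (the breakpoint
#'   position preceding the segment, the midpoint between the flanking
#'   probes, `NA` for the first segment of a chromosome), `mean`, `n_obs`.
#'   Attributes `gamma`, `kmin`, `gamma_eff`, `sd_estimate`.
#' @export
segment_profile <- function(profile, gamma = 40, kmin = 5L, normalize = TRUE) {
  profile <- validate_profiles(profile)
  if (dplyr::n_distinct(profile$sample_id) > 1) {
    abort("segment_profile expects a single sample")
  }
  sd_hat <- if (normalize) estimate_noise_sd(profile$value) else NA_real_
  gamma_eff <- if (normalize) gamma * sd_hat^2 else gamma
  pieces <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    if (all(is.na(p$value))) {
      warn(sprintf("chromosome %s has no non-missing values; skipped", ch))
      next
    }
    seg <- pcf_segment(p$value, gamma = gamma_eff, kmin = kmin)
    cut_bp <- rep(NA_integer_, nrow(seg))
    if (nrow(seg) > 1) {
      left <- p$pos[seg$end_index[-nrow(seg)]]
      right <- p$pos[seg$start_index[-1]]
      cut_bp[-1] <- as.integer(floor((left + right) / 2))
    }
    pieces[[ch]] <- tibble(
      chrom = ch,
      start_index = seg$start_index, end_index = seg$end_index,
      start_bp = as.integer(p$pos[seg$start_index]),
      end_bp = as.integer(p$pos[seg$end_index]),
      cut_bp = cut_bp, mean = seg$mean, n_obs = seg$n_obs
    )
  }
  if (length(pieces) == 0) abort("no chromosome could be segmented")
  out <- bind_rows(pieces)
  attr(out, "gamma") <- gamma
  attr(out, "kmin") <- kmin
  attr(out, "gamma_eff") <- gamma_eff
  attr(out, "sd_estimate") <- sd_hat
  class(out) <- c("cn_segmentation", class(out))
  out
}
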