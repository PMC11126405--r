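# Independent reference implementations used to check the package's
# algorithms. These deliberately use the most naive formulation available
# (exhaustive enumeration, per-point loops, direct formulas).

# --- penalized piecewise-constant fit: exhaustive enumeration ---------------

# SSE of a slice by the plain two-pass formula.
naive_sse <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(0)
  sum((v - mean(v))^2)
}

# Enumerate every breakpoint subset of an n-point signal (n <= ~14), apply
# the kmin constraint, and return the winner per gamma under the published
# tie rule: lowest cost (1e-9 relative tolerance), then fewest segments,
# then the earlier last breakpoint (comparing breakpoint vectors from the
# last position backwards). Slice SSEs come from the naive two-pass formula,
# tabulated once for all slices.
enumerate_pcf_multi <- function(values, gammas, kmin = 1L) {
  n <- length(values)
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) C[i, j] <- naive_sse(values[i:j])
  best <- setNames(vector("list", length(gammas)), as.character(gammas))
  for (mask in 0:(2^(n - 1) - 1)) {
    breaks <- which(bitwAnd(bitwShiftL(1L, 0:(n - 2)), mask) > 0)
    bounds <- c(0L, breaks, n)
    if (any(diff(bounds) < kmin)) next
    sse <- sum(C[cbind(bounds[-length(bounds)] + 1L, bounds[-1])])
    for (g in seq_along(gammas)) {
      cand <- list(breaks = breaks, cost = sse + gammas[g] * length(breaks),
                   nseg = length(breaks) + 1L)
      if (is.null(best[[g]]) || pcf_better(cand, best[[g]])) best[[g]] <- cand
    }
  }
  best
}

enumerate_pcf <- function(values, gamma, kmin = 1L) {
  enumerate_pcf_multi(values, gamma, kmin)[[1]]
}

pcf_better <- function(a, b) {
  tol <- 1e-9 * (1 + abs(b$cost))
  if (a$cost < b$cost - tol) return(TRUE)
  if (a$cost > b$cost + tol) return(FALSE)
  if (a$nseg != b$nseg) return(a$nseg < b$nseg)
  # earlier last breakpoint, recursively towards the front
  if (length(a$breaks) == 0) return(FALSE)
  ra <- rev(a$breaks); rb <- rev(b$breaks)
  for (i in seq_along(ra)) {
    if (ra[i] != rb[i]) return(ra[i] < rb[i])
  }
  FALSE
}

# --- local outlier factor: per-point loops ----------------------------------

naive_lof <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  nn <- vector("list", n)
  kdist <- numeric(n)
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    ord <- others[order(d[i, others], others)]
    nn[[i]] <- ord[1:k]
    kdist[i] <- d[i, nn[[i]][k]]
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    reach <- vapply(nn[[i]], function(j) max(kdist[j], d[i, j]), numeric(1))
    lrd[i] <- if (mean(reach) == 0) Inf else 1 / mean(reach)
  }
  vapply(1:n, function(i) {
    r <- lrd[nn[[i]]] / lrd[i]
    r[lrd[nn[[i]]] == Inf & lrd[i] == Inf] <- 1
    mean(r)
  }, numeric(1))
}

# --- binary MCC -------------------------------------------------------------

binary_mcc <- function(tp, fn, fp, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
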