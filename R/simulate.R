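#' Default probe grid over chromosomes 1..22 and X
#'
#' Probes are spread over the 23 chromosomes proportionally to their
#' (approximate, Mb-scale) physical lengths, evenly spaced within each
#' chromosome. 2,000 probes is a desk-scale stand-in for array resolution.
#'
#' @param n_probes Total probe count (default 2000).
#' @return A grid tibble (`chrom`, `pos`).
#' @export
default_probe_grid <- function(n_probes = 2000L) {
  # approximate chromosome lengths in Mb (GRCh37 scale)
  len_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
              115, 107, 103, 90, 81, 78, 59, 63, 48, 51, 155)
  chroms <- cn_chromosomes()
  m <- pmax(10L, round(n_probes * len_mb / sum(len_mb)))
  pieces <- lapply(seq_along(chroms), function(i) {
    gap <- floor(len_mb[i] * 1e6 / (m[i] + 1))
    tibble(chrom = chroms[i], pos = as.integer(gap * seq_len(m[i])))
  })
  bind_rows(pieces)
}

#' Default class mixture
#'
#' Uneven 10-class proportions resembling a breast-cancer cohort (common
#' luminal-range classes larger, amplifier classes smaller).
#'
#' @return A numeric vector of 10 proportions summing to 1.
#' @export
default_class_proportions <- function() {
  c(0.08, 0.05, 0.14, 0.16, 0.08, 0.05, 0.10, 0.14, 0.08, 0.12)
}

#' Generate class archetype copy-number profiles
#'
#' Builds 10 piecewise-constant archetypes on a probe grid with the signal
#' geometry the classifier targets: each backbone class carries
#' `segments_per_class` random aberrant segments (levels `±amp_effect` plus
#' a little level noise); each of the four merged pairs shares a backbone and
#' differs only in `pair_segments` designated discriminative segments of
#' effect size `pair_delta`. With `pair_delta = 0` paired archetypes are
#' identical, so within-pair assignment is information-free by construction.
#'
#' @param grid Probe grid tibble (`chrom`, `pos`).
#' @param pairs Named list of merged pairs (default [intclust_pairs()]).
#' @param segments_per_class Aberrant segments per backbone class (default 6).
#' @param amp_effect Aberration amplitude on the log-ratio scale (default 1).
#' @param pair_delta Effect size of discriminative segments (default 0.5).
#' @param pair_segments Discriminative segments per pair (default 2).
#' @param min_seg_probes,max_seg_probes Segment length range in probes.
#' @param seed Integer seed; identical seeds give identical archetypes.
#' @return A `cn_archetypes` list: `grid`, `profiles` (10 x n_probes matrix,
#'   one row per class), `segments` (planted segment table), `breakpoints`
#'   (the union of level-change positions across classes, with grid gap index
#'   and the midpoint cut position the pipeline should recover), `pairs`,
#'   `params`.
#' @export
make_archetypes <- function(grid, pairs = intclust_pairs(),
                            segments_per_class = 6L, amp_effect = 1,
                            pair_delta = 0.5, pair_segments = 2L,
                            min_seg_probes = 10L, max_seg_probes = 40L,
                            seed = 1L) {
  grid <- arrange(as_tibble(grid), chrom_rank(.data$chrom), .data$pos)
  chrom_sizes <- table(factor(grid$chrom, levels = unique(grid$chrom)))
  if (max_seg_probes + 8L > max(chrom_sizes)) {
    abort("segment length exceeds grid capacity on every chromosome")
  }
  chrom_offset <- c(0L, cumsum(as.integer(chrom_sizes)))[seq_along(chrom_sizes)]
  names(chrom_offset) <- names(chrom_sizes)
  n_probes <- nrow(grid)
  backbones <- c(vapply(pairs, `[`, integer(1), 1), setdiff(1:10, unlist(pairs)))
  margin <- 4L; gap <- 6L

  sample_segments <- function(n_seg) {
    placed <- list()
    tries <- 0L
    while (length(placed) < n_seg) {
      tries <- tries + 1L
      if (tries > 2000L) abort("segments_per_class exceeds grid capacity")
      ch <- sample(names(chrom_sizes), 1, prob = as.integer(chrom_sizes))
      m <- as.integer(chrom_sizes[[ch]])
      lens <- min_seg_probes:max_seg_probes
      len <- lens[sample.int(length(lens), 1)]
      if (m < len + 2L * margin) next
      starts_ok <- (margin + 1L):(m - margin - len + 1L)
      s <- starts_ok[sample.int(length(starts_ok), 1)]
      e <- s + len - 1L
      clash <- any(vapply(placed, function(p) {
        p$chrom == ch && s <= p$end + gap && e >= p$start - gap
      }, logical(1)))
      if (clash) next
      placed[[length(placed) + 1L]] <- list(chrom = ch, start = s, end = e)
    }
    placed
  }

  withr::with_seed(seed, {
    profiles <- matrix(0, nrow = 10, ncol = n_probes,
                       dimnames = list(as.character(1:10), NULL))
    seg_rows <- list()
    for (cls in backbones) {
      pair_name <- names(pairs)[vapply(pairs, function(p) cls %in% p, logical(1))]
      n_disc <- if (length(pair_name)) pair_segments else 0L
      segs <- sample_segments(segments_per_class + n_disc)
      roles <- c(rep("aberration", segments_per_class), rep("pair", n_disc))
      for (i in seq_along(segs)) {
        sg <- segs[[i]]
        idx <- chrom_offset[[sg$chrom]] + sg$start:sg$end
        if (roles[i] == "aberration") {
          level <- sample(c(-1, 1), 1) * amp_effect +
            rnorm(1, 0, 0.1 * amp_effect)
          profiles[cls, idx] <- level
          seg_rows[[length(seg_rows) + 1L]] <- tibble(
            class = cls, chrom = sg$chrom, start_probe = sg$start,
            end_probe = sg$end, level = level, role = "aberration")
        } else {
          partner <- setdiff(pairs[[pair_name]], cls)
          delta <- sample(c(-1, 1), 1) * pair_delta
          seg_rows[[length(seg_rows) + 1L]] <- tibble(
            class = partner, chrom = sg$chrom, start_probe = sg$start,
            end_probe = sg$end, level = delta, role = "pair_delta")
        }
      }
      if (length(pair_name)) {
        partner <- setdiff(pairs[[pair_name]], cls)
        profiles[partner, ] <- profiles[cls, ]
        for (r in seg_rows) {
          if (r$class == partner && r$role == "pair_delta") {
            idx <- chrom_offset[[r$chrom]] + r$start_probe:r$end_probe
            profiles[partner, idx] <- profiles[partner, idx] + r$level
          }
        }
      }
    }
  })
  segments <- bind_rows(seg_rows)

  # union of realised level changes across class profiles, as grid gap index
  # and the midpoint cut position the region pipeline should recover
  bp_rows <- list()
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    if (length(gi) < 2) next
    changed <- rep(FALSE, length(gi) - 1L)
    for (cls in 1:10) {
      v <- profiles[cls, gi]
      changed <- changed | (v[-1] != v[-length(v)])
    }
    gaps <- which(changed)
    if (length(gaps)) {
      bp_rows[[ch]] <- tibble(
        chrom = ch, gap_index = gaps,
        cut_bp = as.integer(floor((grid$pos[gi[gaps]] + grid$pos[gi[gaps + 1L]]) / 2)))
    }
  }
  structure(list(
    grid = grid, profiles = profiles, segments = segments,
    breakpoints = bind_rows(bp_rows), pairs = pairs,
    params = list(segments_per_class = segments_per_class,
                  amp_effect = amp_effect, pair_delta = pair_delta,
                  pair_segments = pair_segments, seed = as.integer(seed))
  ), class = "cn_archetypes")
}

#' Simulate a labelled copy-number cohort from archetypes
#'
#' Each sample's profile is `attenuation * archetype + offset + N(0, noise_sd)`
#' per probe, with labels drawn from the class proportions and an optional
#' uniformly random missing mask. Fully seeded.
#'
#' @param archetypes A `cn_archetypes` object.
#' @param n_samples Cohort size.
#' @param class_proportions 10 proportions summing to 1
#'   (default [default_class_proportions()]).
#' @param noise_sd Per-probe Gaussian noise sd (default 0.25).
#' @param attenuation Multiplicative platform signal factor `a > 0` (default 1).
#' @param offset Additive platform offset `b` (default 0).
#' @param missing_fraction Fraction of values masked missing (default 0).
#' @param seed Integer seed.
#' @param grid Probe grid to sample on (default: the archetype grid). When a
#'   different grid is given, each probe takes the archetype value of the
#'   grid cell containing its position.
#' @param sample_prefix Prefix for generated sample ids.
#' @param ensure_all_classes Guarantee every class with positive proportion
#'   appears at least once (training cohorts need all 10 classes); set
#'   `FALSE` for raw multinomial draws.
#' @return A `cn_cohort` list: `profiles` (long tibble) and `labels`.
#' @export
simulate_cohort <- function(archetypes, n_samples,
                            class_proportions = default_class_proportions(),
                            noise_sd = 0.25, attenuation = 1, offset = 0,
                            missing_fraction = 0, seed = 1L, grid = NULL,
                            sample_prefix = "S", ensure_all_classes = TRUE) {
  stopifnot(inherits(archetypes, "cn_archetypes"))
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("class proportions must sum to 1")
  }
  if (noise_sd < 0 || attenuation <= 0) abort("need noise_sd >= 0 and attenuation > 0")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must be in [0, 1)")
  }
  own_grid <- is.null(grid)
  if (own_grid) grid <- archetypes$grid
  grid <- arrange(as_tibble(grid), chrom_rank(.data$chrom), .data$pos)
  n_probes <- nrow(grid)
  arch <- if (own_grid) archetypes$profiles
          else archetype_values_at(archetypes, grid)
  withr::with_seed(seed, {
    labels <- sample(1:10, n_samples, replace = TRUE, prob = class_proportions)
    if (ensure_all_classes) {
      eligible <- which(class_proportions > 0)
      for (cls in setdiff(eligible, labels)) labels[sample(n_samples, 1)] <- cls
    }
    values <- attenuation * arch[labels, , drop = FALSE] + offset +
      matrix(rnorm(n_samples * n_probes, 0, noise_sd), n_samples, n_probes)
    if (missing_fraction > 0) {
      mask <- matrix(runif(n_samples * n_probes) < missing_fraction,
                     n_samples, n_probes)
      values[mask] <- NA_real_
    }
  })
  ids <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  profiles <- tibble(
    sample_id = rep(ids, each = n_probes),
    chrom = rep(grid$chrom, n_samples),
    pos = rep(as.integer(grid$pos), n_samples),
    value = as.numeric(t(values))
  )
  structure(list(profiles = profiles,
                 labels = tibble(sample_id = ids, intclust = as.integer(labels)),
                 seed = as.integer(seed)),
            class = "cn_cohort")
}

# Archetype value at arbitrary positions: each position takes the value of
# the archetype grid probe whose cell (midpoint-to-midpoint) contains it.
archetype_values_at <- function(archetypes, grid) {
  src <- archetypes$grid
  out <- matrix(0, nrow = 10, ncol = nrow(grid),
                dimnames = list(rownames(archetypes$profiles), NULL))
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    si <- which(src$chrom == ch)
    if (length(si) == 0) next
    pos <- src$pos[si]
    bounds <- c(-Inf, (pos[-length(pos)] + pos[-1]) / 2)
    nearest <- findInterval(grid$pos[gi], bounds)
    out[, gi] <- archetypes$profiles[, si[nearest], drop = FALSE]
  }
  out
}

#' Simulate a two-platform train/test cohort pair
#'
#' Emulates training on one profiling platform and external validation on
#' another: the test cohort is generated from the same archetypes but on a
#' thinned, position-jittered probe grid with its own signal attenuation,
#' offset, noise and missingness — the situation that motivates per-cohort
#' feature scaling.
#'
#' @param archetypes A `cn_archetypes` object.
#' @param n_train,n_test Cohort sizes.
#' @param train_spec,test_spec Named lists overriding `noise_sd`,
#'   `attenuation`, `offset`, `missing_fraction`; `test_spec` additionally
#'   takes `thin` (keep every `thin`-th probe, default 2) and
#'   `jitter_frac` (position jitter as a fraction of the local probe gap,
#'   default 0.25).
#' @param class_proportions Shared class mixture.
#' @param seed Integer seed.
#' @return A list with `train` and `test` `cn_cohort` objects.
#' @export
simulate_two_platform_pair <- function(archetypes, n_train = 1000L,
                                       n_test = 500L,
                                       train_spec = list(),
                                       test_spec = list(attenuation = 1.6,
                                                        offset = 0.1),
                                       class_proportions = default_class_proportions(),
                                       seed = 1L) {
  tr <- utils::modifyList(list(noise_sd = 0.25, attenuation = 1, offset = 0,
                               missing_fraction = 0), train_spec)
  te <- utils::modifyList(list(noise_sd = 0.25, attenuation = 1.6,
                               offset = 0.1, missing_fraction = 0,
                               thin = 2L, jitter_frac = 0.25), test_spec)
  src <- archetypes$grid
  test_grid <- withr::with_seed(seed + 7L, {
    keep <- src[seq(1, nrow(src), by = te$thin), , drop = FALSE]
    jittered <- lapply(unique(keep$chrom), function(ch) {
      g <- keep[keep$chrom == ch, , drop = FALSE]
      if (nrow(g) > 1) {
        gapw <- min(diff(g$pos))
        j <- round(runif(nrow(g), -te$jitter_frac, te$jitter_frac) * gapw)
        g$pos <- as.integer(pmax(1, g$pos + j))
        g <- g[order(g$pos), , drop = FALSE]
        g <- g[!duplicated(g$pos), , drop = FALSE]
      }
      g
    })
    bind_rows(jittered)
  })
  list(
    train = simulate_cohort(archetypes, n_train,
                            class_proportions = class_proportions,
                            noise_sd = tr$noise_sd, attenuation = tr$attenuation,
                            offset = tr$offset,
                            missing_fraction = tr$missing_fraction,
                            seed = seed, sample_prefix = "TR"),
    test = simulate_cohort(archetypes, n_test,
                           class_proportions = class_proportions,
                           noise_sd = te$noise_sd, attenuation = te$attenuation,
                           offset = te$offset,
                           missing_fraction = te$missing_fraction,
                           seed = seed + 1L, grid = test_grid,
                           sample_prefix = "TE")
  )
}

#' Write a simulated cohort to standard formats
#'
#' Probe matrix TSV (`matrix.tsv`), label TSV (`labels.tsv`) and, when the
#' archetypes are supplied, a segment-resolution SEG file (`cohort.seg`)
#' holding each sample's noise-free archetype segments on the cohort's
#' platform scale.
#'
#' @param cohort A `cn_cohort`.
#' @param dir Output directory.
#' @param archetypes Optional `cn_archetypes` for SEG output.
#' @param attenuation,offset Platform scale used for SEG segment means.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, archetypes = NULL, attenuation = 1,
                         offset = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_matrix(cohort$profiles, file.path(dir, "matrix.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  if (!is.null(archetypes)) {
    segs <- archetype_seg_records(archetypes, cohort$labels, attenuation,
                                  offset)
    write_seg(segs, file.path(dir, "cohort.seg"))
  }
  invisible(dir)
}

# Run-length segments of each sample's class archetype, on the platform scale.
archetype_seg_records <- function(archetypes, labels, attenuation = 1,
                                  offset = 0) {
  grid <- archetypes$grid
  rows <- list()
  per_class <- list()
  for (cls in sort(unique(labels$intclust))) {
    segs <- list()
    for (ch in unique(grid$chrom)) {
      gi <- which(grid$chrom == ch)
      v <- archetypes$profiles[cls, gi]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      segs[[ch]] <- tibble(
        chrom = ch,
        start = as.integer(grid$pos[gi[starts]]),
        end = as.integer(grid$pos[gi[ends]]),
        num_mark = as.integer(r$lengths),
        seg_mean = attenuation * r$values + offset)
    }
    per_class[[as.character(cls)]] <- bind_rows(segs)
  }
  for (i in seq_len(nrow(labels))) {
    s <- per_class[[as.character(labels$intclust[i])]]
    s$sample_id <- labels$sample_id[i]
    rows[[i]] <- s
  }
  out <- bind_rows(rows)
  out[, c("sample_id", "chrom", "start", "end", "num_mark", "seg_mean")]
}
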