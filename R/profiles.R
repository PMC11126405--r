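#' Validate and canonicalise a long table of copy-number profiles
#'
#' Copy-number profiles travel through the package as a long tibble with one
#' row per (sample, locus): columns `sample_id`, `chrom`, `pos`, `value`.
#' `value` is the per-locus log-ratio (or any monotone copy-number signal;
#' the pipeline is unit-agnostic) and may be `NA`. This function checks the
#' invariants — chromosomes from the canonical set (1..22, X), positions
#' positive integers, loci strictly increasing within each chromosome, no
#' duplicated locus within a sample — and returns the table sorted in
#' canonical order (sample, chromosome rank, position).
#'
#' Loci on chromosomes outside the canonical set (e.g. Y, MT) are dropped
#' with a warning; `"chr"` prefixes are stripped.
#'
#' @param profiles A data frame with columns `sample_id`, `chrom`, `pos`,
#'   `value`.
#' @return A validated tibble in canonical order.
#' @export
validate_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  required <- c("sample_id", "chrom", "pos", "value")
  missing_cols <- setdiff(required, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("profiles is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  profiles$chrom <- normalize_chrom(profiles$chrom)
  off <- !profiles$chrom %in% cn_chromosomes()
  if (any(off)) {
    warn(sprintf("dropping %d loci on chromosome(s) outside 1..22,X: %s",
                 sum(off), paste(unique(profiles$chrom[off]), collapse = ", ")))
    profiles <- profiles[!off, , drop = FALSE]
  }
  if (nrow(profiles) == 0) abort("no loci remain after chromosome filtering")
  if (any(profiles$pos < 1) || any(profiles$pos != floor(profiles$pos))) {
    abort("pos must be positive integers (1-based base pairs)")
  }
  if (any(is.infinite(profiles$value), na.rm = TRUE)) {
    abort("values must be finite where present")
  }
  profiles <- arrange(profiles, .data$sample_id, chrom_rank(.data$chrom), .data$pos)
  dup <- duplicated(profiles[, c("sample_id", "chrom", "pos")])
  if (any(dup)) {
    first <- profiles[which(dup)[1], ]
    abort(sprintf("duplicated locus %s:%d in sample %s",
                  first$chrom, as.integer(first$pos), first$sample_id))
  }
  profiles
}

#' Validate a sample-to-IntClust label table
#'
#' @param labels A data frame with columns `sample_id` and `intclust`
#'   (integers in 1..10).
#' @param sample_ids Optional character vector; every labelled id must occur
#'   in it.
#' @return A validated tibble with `intclust` as integer.
#' @export
validate_labels <- function(labels, sample_ids = NULL) {
  labels <- as_tibble(labels)
  if (!all(c("sample_id", "intclust") %in% names(labels))) {
    abort("labels must have columns sample_id and intclust")
  }
  labels$intclust <- as.integer(labels$intclust)
  if (any(is.na(labels$intclust)) || !all(labels$intclust %in% 1:10)) {
    abort("intclust labels must be integers in 1..10")
  }
  if (anyDuplicated(labels$sample_id)) {
    abort("duplicated sample_id in labels")
  }
  if (!is.null(sample_ids)) {
    unknown <- setdiff(labels$sample_id, sample_ids)
    if (length(unknown) > 0) {
      abort(paste0("labelled sample(s) absent from profiles: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  labels
}

#' Extract the locus grid of a profile table
#'
#' @param profiles A long profile tibble (see [validate_profiles()]).
#' @return A tibble with columns `chrom`, `pos`, one row per distinct locus,
#'   in canonical order.
#' @export
profile_grid <- function(profiles) {
  distinct(profiles, .data$chrom, .data$pos) %>%
    arrange(chrom_rank(.data$chrom), .data$pos)
}

# TRUE when every sample covers the identical locus grid.
shared_grid <- function(profiles) {
  counts <- dplyr::count(profiles, .data$chrom, .data$pos)
  n_samples <- dplyr::n_distinct(profiles$sample_id)
  all(counts$n == n_samples)
}
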