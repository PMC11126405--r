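#' Read a SEG file of segmented copy-number calls
#'
#' Reads the tab-separated SEG dialect used by cBioPortal: header columns
#' `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`, `seg.mean`. Coordinates
#' are 1-based inclusive. `"chr"` prefixes are stripped; chromosomes outside
#' 1..22, X are dropped with a warning. Segments of one sample must not
#' overlap within a chromosome.
#'
#' @param path Path to a SEG file.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `num_mark`, `seg_mean`, samples kept in file order.
#' @export
read_seg <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) abort("empty SEG file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 6) {
    abort("SEG header must have 6 columns (ID, chrom, loc.start, loc.end, num.mark, seg.mean)")
  }
  body <- fields[-1]
  keep <- lengths(body) > 0 & vapply(body, function(f) any(nzchar(f)), logical(1))
  body <- body[keep]
  line_no <- (2:length(lines))[keep]
  bad <- lengths(body) != 6
  if (any(bad)) {
    abort(sprintf("malformed SEG row at line %d: expected 6 tab-separated fields, got %d",
                  line_no[which(bad)[1]], lengths(body)[which(bad)[1]]))
  }
  m <- do.call(rbind, body)
  start <- suppressWarnings(as.numeric(m[, 3]))
  end <- suppressWarnings(as.numeric(m[, 4]))
  num_mark <- suppressWarnings(as.numeric(m[, 5]))
  seg_mean <- suppressWarnings(as.numeric(m[, 6]))
  bad_num <- which(is.na(start) | is.na(end) | is.na(seg_mean))
  if (length(bad_num) > 0) {
    abort(sprintf("malformed SEG row at line %d: non-numeric coordinate or mean",
                  line_no[bad_num[1]]))
  }
  segs <- tibble(
    sample_id = m[, 1],
    chrom = normalize_chrom(m[, 2]),
    start = as.integer(start),
    end = as.integer(end),
    num_mark = as.integer(num_mark),
    seg_mean = seg_mean
  )
  off <- !segs$chrom %in% cn_chromosomes()
  if (any(off)) {
    warn(sprintf("dropping %d SEG records on chromosome(s) outside 1..22,X",
                 sum(off)))
    segs <- segs[!off, , drop = FALSE]
  }
  if (any(segs$start > segs$end)) {
    abort("SEG record with start > end")
  }
  if (any(segs$start < 1)) abort("SEG coordinates must be >= 1 (1-based)")
  # non-overlap within sample/chromosome
  check <- segs %>%
    group_by(.data$sample_id, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(overlap = any(.data$start[-1] <= head(.data$end, -1)),
              .groups = "drop")
  if (any(check$overlap, na.rm = TRUE)) {
    first <- check[which(check$overlap)[1], ]
    abort(sprintf("overlapping segments in sample %s chromosome %s",
                  first$sample_id, first$chrom))
  }
  segs$sample_id <- factor(segs$sample_id, levels = unique(segs$sample_id))
  segs <- arrange(segs, .data$sample_id, chrom_rank(.data$chrom), .data$start)
  segs$sample_id <- as.character(segs$sample_id)
  segs
}

#' Write segments to a SEG file
#'
#' @param segs A tibble as returned by [read_seg()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path) {
  out <- tibble(
    ID = segs$sample_id, chrom = segs$chrom,
    `loc.start` = segs$start, `loc.end` = segs$end,
    `num.mark` = segs$num_mark, `seg.mean` = segs$seg_mean
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Project one sample's segments onto a probe grid
#'
#' Each grid locus takes the `seg_mean` of the segment whose 1-based
#' inclusive `[start, end]` interval contains it; loci covered by no segment
#' become missing. This lets SEG input feed the same probe-level pipeline as
#' matrix input.
#'
#' @param segs Segment records of a single sample (see [read_seg()]).
#' @param grid A tibble of loci with columns `chrom`, `pos`.
#' @param sample_id Sample name for the output; defaults to the one in `segs`.
#' @return A long profile tibble (`sample_id`, `chrom`, `pos`, `value`).
#' @export
segments_to_profile <- function(segs, grid, sample_id = NULL) {
  if (nrow(grid) == 0) abort("empty probe grid")
  ids <- unique(segs$sample_id)
  if (length(ids) > 1) abort("segments_to_profile expects a single sample")
  if (is.null(sample_id)) sample_id <- if (length(ids)) ids else "sample"
  grid <- arrange(as_tibble(grid), chrom_rank(.data$chrom), .data$pos)
  value <- rep(NA_real_, nrow(grid))
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    s <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    s <- arrange(s, .data$start)
    idx <- findInterval(grid$pos[gi], s$start)
    hit <- idx >= 1 & grid$pos[gi] <= s$end[pmax(idx, 1)]
    value[gi[hit]] <- s$seg_mean[idx[hit]]
  }
  tibble(sample_id = sample_id, chrom = grid$chrom, pos = as.integer(grid$pos),
         value = value)
}

#' Read a probe-level copy-number matrix
#'
#' Tab-separated file with columns `chrom`, `pos`, then one column per
#' sample. Blank or `NA` cells become missing values. Duplicate loci are an
#' error; unsorted loci are sorted with a warning.
#'
#' @param path Path to the TSV file.
#' @return A long profile tibble (`sample_id`, `chrom`, `pos`, `value`).
#' @export
read_profile_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  if (!all(c("chrom", "pos") %in% names(wide))) {
    abort("profile matrix must have 'chrom' and 'pos' columns")
  }
  wide$chrom <- normalize_chrom(wide$chrom)
  key <- paste(wide$chrom, wide$pos)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated locus in profile matrix: %s",
                  key[which(duplicated(key))[1]]))
  }
  ord <- order(chrom_rank(wide$chrom), wide$pos)
  if (is.unsorted(ord)) {
    warn("profile matrix loci were not in canonical order; sorting")
    wide <- wide[ord, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(wide, cols = -c("chrom", "pos"),
                              names_to = "sample_id", values_to = "value")
  validate_profiles(long)
}

#' Write profiles as a probe-level matrix TSV
#'
#' @param profiles Long profile tibble; all samples must share a grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(profiles, path) {
  wide <- tidyr::pivot_wider(profiles, id_cols = c("chrom", "pos"),
                             names_from = "sample_id", values_from = "value")
  wide <- arrange(wide, chrom_rank(.data$chrom), .data$pos)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read / write a two-column label table
#'
#' TSV with columns `sample_id` and `intclust` (integers 1..10).
#'
#' @param path File path.
#' @return [read_labels()] returns a validated label tibble.
#' @export
read_labels <- function(path) {
  validate_labels(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_labels
#' @param labels A label tibble.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(validate_labels(labels), path)
  invisible(path)
}

#' Export a region set as BED3
#'
#' Internal coordinates are 1-based inclusive `[start, end]`; BED is 0-based
#' half-open, so a region `chr1:1-100` is written as `1  0  100`.
#'
#' @param regions A region tibble (`chrom`, `start`, `end`, `region_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble(chrom = regions$chrom,
                start = as.integer(regions$start - 1L),
                end = as.integer(regions$end))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Import a BED3 file as a region set
#'
#' Inverse of [write_regions_bed()]: 0-based half-open intervals become
#' 1-based inclusive.
#'
#' @param path Path to a BED3 file.
#' @return A region tibble (`chrom`, `start`, `end`, `region_id`).
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         show_col_types = FALSE)
  regions <- tibble(chrom = normalize_chrom(bed$chrom),
                    start = as.integer(bed$start + 1L),
                    end = as.integer(bed$end))
  regions <- arrange(regions, chrom_rank(.data$chrom), .data$start)
  regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                               regions$end)
  validate_regions(regions)
}

#' Persist a trained model bundle to a directory
#'
#' Writes the six-class booster, the four pair-specific binary boosters, the
#' region set (BED3), the scaler and a JSON metadata file. [load_bundle()]
#' restores a bundle whose predictions are identical to the original's.
#'
#' @param bundle A `cn_bundle` from [train_cascade()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cn_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(bundle$multiclass, file.path(dir, "multiclass.ubj"))
  for (pair in names(bundle$binaries)) {
    fname <- paste0("binary_", gsub("/", "_", pair), ".ubj")
    xgboost::xgb.save(bundle$binaries[[pair]], file.path(dir, fname))
  }
  write_regions_bed(bundle$regions, file.path(dir, "regions.bed"))
  readr::write_tsv(bundle$scaler, file.path(dir, "scaler.tsv"))
  meta <- bundle$metadata
  meta$format_version <- bundle_format_version()
  meta$pairs <- lapply(bundle$label_scheme, as.integer)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) abort(paste0("no metadata.json in ", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ver <- meta$format_version
  if (!identical(ver, bundle_format_version())) {
    abort(sprintf("bundle format version mismatch: file has %s, package expects %s",
                  as.character(ver), bundle_format_version()))
  }
  pairs <- lapply(meta$pairs, as.integer)
  binaries <- list()
  for (pair in names(pairs)) {
    fname <- file.path(dir, paste0("binary_", gsub("/", "_", pair), ".ubj"))
    if (!file.exists(fname)) {
      abort(sprintf("bundle is missing the binary model for pair %s", pair))
    }
    binaries[[pair]] <- xgboost::xgb.load(fname)
  }
  meta$pairs <- NULL
  meta$format_version <- NULL
  structure(list(
    multiclass = xgboost::xgb.load(file.path(dir, "multiclass.ubj")),
    binaries = binaries,
    regions = read_regions_bed(file.path(dir, "regions.bed")),
    scaler = readr::read_tsv(file.path(dir, "scaler.tsv"),
                             show_col_types = FALSE),
    label_scheme = pairs,
    metadata = meta
  ), class = "cn_bundle")
}
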