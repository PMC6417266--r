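#' Distance from each peak to its nearest transcription start site
#'
#' For every peak, computes two distances to the nearest TSS on the same
#' chromosome, strand-ignored:
#' * `boundary_dist` - 0 when a TSS falls inside the peak span, otherwise
#'   the gap between the TSS and the nearest peak edge;
#' * `center_dist` - distance from the peak center
#'   (`floor((start + end) / 2)`) to the nearest TSS.
#'
#' Peaks on a chromosome with no annotated gene get `Inf` for both.
#'
#' @param peaks Tibble of peaks (`chrom`, `start`, `end`).
#' @param genes Tibble of gene models with a `tss` column (see
#'   [read_gtf_genes()]).
#' @return `peaks` with `boundary_dist` and `center_dist` columns added.
#' @export
nearest_tss_distances <- function(peaks, genes) {
  check_intervals(peaks, "peaks")
  tss_by_chrom <- split(genes$tss, genes$chrom)
  tss_by_chrom <- lapply(tss_by_chrom, sort)

  n <- nrow(peaks)
  bdist <- rep(Inf, n)
  cdist <- rep(Inf, n)
  for (ch in unique(peaks$chrom)) {
    tss <- tss_by_chrom[[ch]]
    idx <- which(peaks$chrom == ch)
    if (is.null(tss) || length(tss) == 0) next
    s <- peaks$start[idx]; e <- peaks$end[idx]
    ctr <- (s + e) %/% 2
    # nearest TSS via binary placement in the sorted TSS vector
    nearest_gap <- function(pos) {
      i <- findInterval(pos, tss)
      left <- ifelse(i >= 1, pos - tss[pmax(i, 1)], Inf)
      right <- ifelse(i < length(tss), tss[pmin(i + 1, length(tss))] - pos, Inf)
      pmin(left, right)
    }
    # boundary distance: 0 when a TSS touches the span [start, end]
    # (both edges in coordinate terms), else gap to the nearest edge
    inside <- findInterval(e, tss) - findInterval(s - 1L, tss) > 0
    bdist[idx] <- ifelse(inside, 0, pmin(nearest_gap(s), nearest_gap(e)))
    cdist[idx] <- nearest_gap(ctr)
  }
  peaks$boundary_dist <- bdist
  peaks$center_dist <- cdist
  peaks
}

#' Keep peaks distal to every transcription start site
#'
#' A peak is distal when its boundary is more than `boundary_min` (default
#' 1.5 kb) from every TSS, or its center more than `center_min` (default
#' 3 kb) from every TSS - the two criteria combine with OR. Both thresholds
#' are strict. Input order is preserved.
#'
#' @param peaks Tibble of peaks.
#' @param genes Tibble of gene models with a `tss` column.
#' @param boundary_min Minimum boundary-to-TSS gap, bp.
#' @param center_min Minimum center-to-TSS distance, bp.
#' @return The distal subset of `peaks` (distance columns dropped).
#' @export
filter_distal <- function(peaks, genes, boundary_min = 1500, center_min = 3000) {
  stopifnot(boundary_min > 0, center_min > 0)
  d <- nearest_tss_distances(peaks, genes)
  keep <- d$boundary_dist > boundary_min | d$center_dist > center_min
  peaks[keep, , drop = FALSE]
}

#' Stitch nearby peaks into enhancer regions
#'
#' Single-linkage merge per chromosome: two peaks join when the end-to-start
#' gap between them is strictly less than `gap` (default 12.5 kb);
#' overlapping or adjacent peaks always join; merging is transitive. Each
#' stitched region spans the hull of its constituents.
#'
#' @param peaks Tibble of peaks (may be unsorted).
#' @param gap Maximum (exclusive) inter-peak gap in bp.
#' @return A tibble sorted by `(chrom, start)` with columns `chrom`,
#'   `start`, `end`, `n_constituent_peaks` and a `constituents` list-column
#'   holding each region's member peaks (sorted by start).
#' @export
stitch <- function(peaks, gap = 12500) {
  check_intervals(peaks, "peaks")
  stopifnot(gap > 0)
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_constituent_peaks = integer(), constituents = list()))
  }
  peaks <- arrange(as_tibble(peaks), .data$chrom, .data$start, .data$end)
  out <- peaks |>
    group_by(.data$chrom) |>
    group_map(function(p, key) {
      # running hull end; new region when gap to previous hull >= gap
      run_end <- cummax_dbl(p$end)
      new_region <- c(TRUE, p$start[-1] - run_end[-nrow(p)] >= gap)
      rid <- cumsum(new_region)
      grp <- factor(rid, levels = unique(rid))  # keep genomic order
      tibble(
        chrom = key$chrom[1],
        start = as.integer(vapply(split(p$start, grp), min, 0)),
        end = as.integer(vapply(split(p$end, grp), max, 0)),
        n_constituent_peaks = as.integer(tabulate(rid)),
        constituents = unname(split(p, grp))
      )
    }) |>
    bind_rows()
  arrange(out, .data$chrom, .data$start)
}

cummax_dbl <- function(x) cummax(as.numeric(x))
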