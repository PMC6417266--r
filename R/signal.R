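#' Quantify track signal over regions
#'
#' Integrates a signal track over each region (sum over overlap bases of the
#' per-base value) and normalizes to reads/track mass per million:
#' `rpm = raw * 1e6 / total_mass`. Regions with no overlapping signal get 0.
#' The integral is computed from a per-chromosome cumulative mass function,
#' so it is exactly additive under region partition.
#'
#' @param track A [signal_track()].
#' @param regions Tibble of regions (`chrom`, `start`, `end`), e.g. peaks,
#'   stitched regions or genome bins.
#' @return `regions` with `raw` and `rpm` columns added.
#' @export
quantify <- function(track, regions) {
  check_intervals(regions, "regions")
  mass <- track_mass(track)
  raw <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    idx <- which(regions$chrom == ch)
    if (nrow(tr) == 0) next
    w <- tr$end - tr$start
    cum <- c(0, cumsum(tr$value * w))
    # F(pos): track integral over (-Inf, pos)
    Fpos <- function(pos) {
      i <- findInterval(pos, tr$start)
      partial <- ifelse(i >= 1,
                        tr$value[pmax(i, 1)] *
                          pmin(pmax(pos - tr$start[pmax(i, 1)], 0), w[pmax(i, 1)]),
                        0)
      cum[i + 1] - ifelse(i >= 1, tr$value[pmax(i, 1)] * w[pmax(i, 1)], 0) + partial
    }
    raw[idx] <- Fpos(regions$end[idx]) - Fpos(regions$start[idx])
  }
  if (any(raw > 0) && mass <= 0) {
    abort("track total_mass is 0 but regions carry signal")
  }
  regions$raw <- raw
  regions$rpm <- if (mass > 0) raw * 1e6 / mass else raw
  regions
}

#' Tile the genome into fixed-width bins
#'
#' Bins tile each chromosome from coordinate 0 in steps of `width` (default
#' 2 kb); the final bin is truncated at the chromosome end.
#'
#' @param chrom_sizes Named integer vector or tibble (`chrom`, `length`) of
#'   chromosome lengths.
#' @param width Bin width in bp.
#' @return Tibble of bins (`chrom`, `start`, `end`).
#' @export
bin_genome <- function(chrom_sizes, width = 2000) {
  stopifnot(width >= 1)
  if (is.data.frame(chrom_sizes)) {
    sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  } else {
    sizes <- chrom_sizes
  }
  if (any(sizes <= 0)) abort("chromosome lengths must be > 0")
  bind_rows(lapply(names(sizes), function(ch) {
    len <- sizes[[ch]]
    starts <- seq.int(0L, len - 1L, by = width)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + width, len)))
  }))
}

#' Bin-level signal matrix for several tracks
#'
#' Quantifies each track over a common set of genome bins, producing the
#' bins-by-samples matrix used for genome-wide mark/replicate comparison.
#'
#' @param tracks Named list of [signal_track()] objects.
#' @param bins Bin tibble from [bin_genome()].
#' @param normalized Use RPM (`TRUE`, default) or raw integrals.
#' @return `bins` with one signal column per track.
#' @export
bin_matrix <- function(tracks, bins, normalized = TRUE) {
  stopifnot(is.list(tracks), !is.null(names(tracks)), all(nzchar(names(tracks))))
  out <- bins
  for (nm in names(tracks)) {
    q <- quantify(tracks[[nm]], bins)
    out[[nm]] <- if (normalized) q$rpm else q$raw
  }
  out
}

#' Correlation matrix across samples or marks
#'
#' Pairwise correlation of the signal columns of a bin matrix (or any
#' all-numeric data frame / matrix). Spearman uses average ranks for ties.
#' Pairs involving a zero-variance vector are reported as `NA`, never as 0.
#'
#' @param mat Output of [bin_matrix()], or a numeric matrix/data frame.
#' @param method `"spearman"` (genome-wide comparisons) or `"pearson"`.
#' @return A symmetric correlation matrix.
#' @export
correlate_samples <- function(mat, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(mat)) {
    mat <- mat[, setdiff(names(mat), c("chrom", "start", "end")), drop = FALSE]
    mat <- as.matrix(mat)
  }
  if (ncol(mat) < 2) abort("need at least 2 signal vectors")
  if (nrow(mat) < 3) abort("need at least 3 bins/regions")
  suppressWarnings(cor(mat, method = method))
}

#' Correlation of two marks over enhancer regions
#'
#' Quantifies both tracks over the same regions (RPM) and correlates the two
#' vectors - the per-enhancer mark co-localization estimate. An optional
#' `log2(x + 1)` transform is available for heavy-tailed signal; it is off
#' by default.
#'
#' @param track_a,track_b [signal_track()] objects for the two marks.
#' @param regions Tibble of >= 3 regions.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log2_transform Apply `log2(rpm + 1)` before correlating.
#' @return A single correlation value (`NA` if either vector is constant).
#' @export
enhancer_correlation <- function(track_a, track_b, regions,
                                 method = c("pearson", "spearman"),
                                 log2_transform = FALSE) {
  method <- match.arg(method)
  if (nrow(regions) < 3) abort("need at least 3 regions")
  a <- quantify(track_a, regions)$rpm
  b <- quantify(track_b, regions)$rpm
  if (log2_transform) {
    a <- log2(a + 1)
    b <- log2(b + 1)
  }
  suppressWarnings(cor(a, b, method = method))
}
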