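#' Rank stitched regions by signal and scale the curve
#'
#' Orders regions ascending by signal (ties broken by genomic position),
#' assigns 0-based ranks, and scales both axes to `[0, 1]`:
#' `scaled_rank = rank / (n - 1)`, `scaled_signal = signal / max(signal)`.
#' This is the curve on which the slope-1 tangent cutoff is found.
#'
#' @param regions Tibble of regions with a `signal` column (typically RPM
#'   from [quantify()]); needs `n >= 3` and a positive maximum signal.
#' @return A `ranked_enhancers` tibble, cutoff not yet set.
#' @export
rank_and_scale <- function(regions) {
  check_intervals(regions, "regions")
  if (!"signal" %in% names(regions)) abort("regions need a 'signal' column")
  n <- nrow(regions)
  if (n < 3) abort("need at least 3 regions to rank")
  if (max(regions$signal) <= 0) abort("all signals are zero: no ranked curve")
  if (any(regions$signal < 0)) abort("signals must be >= 0")
  out <- arrange(as_tibble(regions), .data$signal, .data$chrom, .data$start)
  out$rank <- seq_len(n) - 1L
  out$scaled_rank <- out$rank / (n - 1)
  out$scaled_signal <- out$signal / max(out$signal)
  if (!"n_constituent_peaks" %in% names(out)) out$n_constituent_peaks <- 1L
  class(out) <- c("ranked_enhancers", class(out))
  out
}

#' Locate the slope-1 tangent cutoff on the ranked curve
#'
#' On the scaled ascending curve, the point where a tangent line of slope 1
#' touches is realized as the maximizer of the vertical distance between the
#' diagonal `y = x` and the curve, i.e. `argmax_i (scaled_rank[i] -
#' scaled_signal[i])`. Ties take the largest index (the fewest
#' super-enhancer calls), so an exactly linear curve yields zero supers.
#'
#' @param table A `ranked_enhancers` tibble from [rank_and_scale()].
#' @return The table with `is_super` set (signal strictly above the cutoff
#'   region's) and attributes `cutoff_rank` (0-based) and `cutoff_signal`.
#' @export
find_inflection <- function(table) {
  if (!inherits(table, "ranked_enhancers")) abort("run rank_and_scale() first")
  gapv <- table$scaled_rank - table$scaled_signal
  cut_i <- max(which(gapv == max(gapv)))   # largest index on ties
  table$is_super <- table$signal > table$signal[cut_i]
  attr(table, "cutoff_rank") <- table$rank[cut_i]
  attr(table, "cutoff_signal") <- table$signal[cut_i]
  table
}

#' Call super-enhancers from H3K27ac peaks and signal
#'
#' The full ROSE-style procedure: drop peaks near any TSS
#' ([filter_distal()]), stitch the surviving distal peaks into enhancer
#' regions ([stitch()]), quantify H3K27ac RPM per region ([quantify()],
#' optionally subtracting a control/input track, clamping at zero), rank and
#' scale the curve, and split super from typical enhancers at the slope-1
#' tangent point ([find_inflection()]).
#'
#' Replicate tracks should be pooled (summed) by the caller beforehand.
#'
#' @param peaks H3K27ac peak calls (tibble from [read_bed()]).
#' @param genes Gene models with TSSs (tibble from [read_gtf_genes()]).
#' @param track H3K27ac [signal_track()].
#' @param stitch_gap Stitching gap in bp.
#' @param boundary_min,center_min Distality thresholds in bp (see
#'   [filter_distal()]).
#' @param control_track Optional input/control [signal_track()] whose RPM is
#'   subtracted when `subtract_control = TRUE`.
#' @param subtract_control Subtract the control RPM (default off).
#' @return A labeled `ranked_enhancers` tibble.
#' @export
call_super_enhancers <- function(peaks, genes, track, stitch_gap = 12500,
                                 boundary_min = 1500, center_min = 3000,
                                 control_track = NULL,
                                 subtract_control = FALSE) {
  distal <- filter_distal(peaks, genes, boundary_min, center_min)
  if (nrow(distal) == 0) abort("no enhancers: no distal peaks survive TSS filtering")
  regions <- stitch(distal, gap = stitch_gap)
  regions <- quantify(track, regions)
  regions$signal <- regions$rpm
  if (subtract_control) {
    if (is.null(control_track)) abort("subtract_control = TRUE needs control_track")
    ctrl <- quantify(control_track, regions[c("chrom", "start", "end")])
    regions$signal <- pmax(regions$signal - ctrl$rpm, 0)
  }
  if (max(regions$signal) <= 0) {
    abort("all signals are zero: no ranked curve")
  }
  find_inflection(rank_and_scale(regions))
}

#' Call H3K4me3-enriched super-enhancers
#'
#' The distal/stitch/rank procedure applied to H3K4me3 peaks, except that
#' the ranked quantity is the H3K27ac signal over the stitched H3K4me3
#' regions: regions are defined by where distal H3K4me3 sits, activity by
#' H3K27ac.
#'
#' @param k4_peaks H3K4me3 peak calls.
#' @param genes Gene models with TSSs.
#' @param k27_track H3K27ac [signal_track()] used for ranking.
#' @inheritParams call_super_enhancers
#' @return A labeled `ranked_enhancers` tibble.
#' @export
call_h3k4me3_super_enhancers <- function(k4_peaks, genes, k27_track,
                                         stitch_gap = 12500,
                                         boundary_min = 1500,
                                         center_min = 3000,
                                         control_track = NULL,
                                         subtract_control = FALSE) {
  call_super_enhancers(k4_peaks, genes, k27_track, stitch_gap = stitch_gap,
                       boundary_min = boundary_min, center_min = center_min,
                       control_track = control_track,
                       subtract_control = subtract_control)
}

#' Compare two super-enhancer sets by genomic overlap
#'
#' Classifies the super-enhancers of two ranked tables into overlapping
#' (sharing at least `min_overlap` bp with a super of the other set) and
#' set-exclusive, with mean signal per class.
#'
#' @param a,b Labeled `ranked_enhancers` tibbles on the same genome.
#' @param min_overlap Minimum shared bp to count as overlap.
#' @return A tibble with one row per class (`a_only`, `b_only`,
#'   `overlapping_a`, `overlapping_b`): `n` and `mean_signal`.
#' @export
compare_enhancer_sets <- function(a, b, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  sup_a <- a[isTRUE_vec(a$is_super), , drop = FALSE]
  sup_b <- b[isTRUE_vec(b$is_super), , drop = FALSE]
  hit_a <- overlaps_any(sup_a, sup_b, min_overlap)
  hit_b <- overlaps_any(sup_b, sup_a, min_overlap)
  cls <- function(x, keep) {
    tibble(n = sum(keep),
           mean_signal = if (any(keep)) mean(x$signal[keep]) else NA_real_)
  }
  bind_rows(
    mutate(cls(sup_a, !hit_a), class = "a_only"),
    mutate(cls(sup_b, !hit_b), class = "b_only"),
    mutate(cls(sup_a, hit_a), class = "overlapping_a"),
    mutate(cls(sup_b, hit_b), class = "overlapping_b")
  )[, c("class", "n", "mean_signal")]
}

# does each interval of x overlap any interval of y by >= min_overlap bp?
overlaps_any <- function(x, y, min_overlap = 1) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  vapply(seq_len(nrow(x)), function(i) {
    same <- y$chrom == x$chrom[i]
    any(pmin(y$end[same], x$end[i]) - pmax(y$start[same], x$start[i]) >=
          min_overlap)
  }, TRUE)
}

#' @export
print.ranked_enhancers <- function(x, ...) {
  n <- nrow(x)
  cutoff <- attr(x, "cutoff_rank")
  cat(sprintf("Ranked enhancer table: %d regions", n))
  if (!is.null(cutoff)) {
    cat(sprintf("; %d super / %d typical (cutoff rank %d, signal %.4g)",
                sum(x$is_super), sum(!x$is_super), cutoff,
                attr(x, "cutoff_signal")))
  }
  cat("\n")
  NextMethod()
}

#' Tidy a ranked enhancer table
#'
#' One row per enhancer region with rank, scaled coordinates, signal and the
#' super/typical label, dropping the constituent list-column.
#'
#' @param x A `ranked_enhancers` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @exportS3Method generics::tidy
tidy.ranked_enhancers <- function(x, ...) {
  keep <- intersect(c("chrom", "start", "end", "n_constituent_peaks",
                      "signal", "rank", "scaled_rank", "scaled_signal",
                      "is_super"), names(x))
  as_tibble(as.data.frame(x)[, keep])
}

#' One-row summary of a super-enhancer call
#'
#' @param x A labeled `ranked_enhancers` tibble.
#' @param ... Unused.
#' @return A tibble with `n_enhancers`, `n_super`, `n_typical`,
#'   `cutoff_rank`, `cutoff_signal`, `mean_super_size`, `mean_typical_size`.
#' @exportS3Method generics::glance
glance.ranked_enhancers <- function(x, ...) {
  sup <- isTRUE_vec(x$is_super)
  tibble(
    n_enhancers = nrow(x),
    n_super = sum(sup),
    n_typical = sum(!sup),
    cutoff_rank = attr(x, "cutoff_rank") %||% NA_integer_,
    cutoff_signal = attr(x, "cutoff_signal") %||% NA_real_,
    mean_super_size = if (any(sup)) mean(x$end[sup] - x$start[sup]) else NA_real_,
    mean_typical_size = if (any(!sup)) mean(x$end[!sup] - x$start[!sup]) else NA_real_
  )
}

#' Ranked-signal curve plot
#'
#' The classic hockey-stick figure: enhancers by ascending rank against
#' scaled signal, the slope-1 tangent cutoff marked, super-enhancers
#' highlighted.
#'
#' @param object A labeled `ranked_enhancers` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ranked_enhancers <- function(object, ...) {
  df <- tidy(object)
  cutoff <- attr(object, "cutoff_rank")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scaled_rank,
                                        y = .data$scaled_signal,
                                        colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "super-enhancer") +
    ggplot2::labs(x = "Enhancer rank (scaled)",
                  y = "Signal / max signal",
                  title = "Ranked enhancer signal") +
    ggplot2::theme_classic()
  if (!is.null(cutoff) && nrow(df) > 1) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff / (nrow(df) - 1),
                                 linetype = "dashed", colour = "grey60")
  }
  p
}
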