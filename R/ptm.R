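#' Relative abundance of peptidoforms
#'
#' Within each peptide and sample, converts DIA peak areas to relative
#' abundance: the percentage of this form's area in the summed area of all
#' forms of that peptide. Percentages per (peptide, sample) sum to 100.
#'
#' @param records Long tibble of peptidoform peak areas (`peptide_id`,
#'   `ptm_combo`, `sample`, `condition`, `area`); the empty combo `""`
#'   denotes the unmodified form.
#' @return `records` with a `rel_abundance` column (percent).
#' @export
peptidoform_relative_abundance <- function(records) {
  stopifnot(all(c("peptide_id", "ptm_combo", "sample", "area") %in%
                  names(records)))
  if (any(records$area < 0)) abort("peak areas must be >= 0")
  out <- records |>
    group_by(.data$peptide_id, .data$sample) |>
    mutate(.total = sum(.data$area)) |>
    ungroup()
  if (any(out$.total <= 0)) {
    bad <- out[out$.total <= 0, ][1, ]
    abort(sprintf("total area is 0 for peptide %s in sample %s",
                  bad$peptide_id, bad$sample))
  }
  out$rel_abundance <- 100 * out$area / out$.total
  out$.total <- NULL
  out
}

#' Single-mark abundance by summation over modified forms
#'
#' The relative abundance of one histone mark is the sum of the relative
#' abundances of every peptidoform carrying that mark (on the peptide that
#' hosts the mark's residue). Because peptides are measured independently,
#' marks are aggregated per peptide - long-range PTM co-occurrence across
#' peptides is not resolvable by this approach.
#'
#' @param rel Output of [peptidoform_relative_abundance()].
#' @param marks Character vector of marks to report; default every mark
#'   observed in any combo.
#' @return Tibble with `mark`, `sample`, `condition` (when present) and
#'   `abundance` (percent, in `[0, 100]`). A requested mark absent from all
#'   combos is reported as 0 with a warning.
#' @export
single_mark_abundance <- function(rel, marks = NULL) {
  stopifnot("rel_abundance" %in% names(rel))
  combo_marks <- strsplit(rel$ptm_combo, "+", fixed = TRUE)
  seen <- unique(unlist(combo_marks))
  seen <- seen[nzchar(seen)]
  if (is.null(marks)) marks <- sort(seen)
  absent <- setdiff(marks, seen)
  if (length(absent) > 0) {
    warn(sprintf("mark(s) not observed on any peptidoform: %s",
                 paste(absent, collapse = ", ")))
  }
  samples <- distinct(rel[, intersect(c("sample", "condition"), names(rel))])
  bind_rows(lapply(marks, function(mk) {
    has <- vapply(combo_marks, function(cm) mk %in% cm, TRUE)
    ab <- rel[has, , drop = FALSE] |>
      group_by(.data$sample) |>
      summarise(abundance = sum(.data$rel_abundance), .groups = "drop")
    out <- left_join(samples, ab, by = "sample")
    out$abundance[is.na(out$abundance)] <- 0
    out$mark <- mk
    out
  }))[, c("mark", intersect(c("sample", "condition"), names(rel)), "abundance")]
}

#' Two-condition comparison of mark abundances
#'
#' Homoscedastic (equal-variance, two-sided) t-test per mark between two
#' replicate groups, with `fold_change = mean_b / mean_a` and a
#' significance flag at `alpha`. Degenerate zero-variance groups follow
#' sentinel rules: equal means give p = 1, unequal means give p = 0 with a
#' warning. Marks detected (non-zero) in only one condition are flagged
#' `one_condition`. No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds Benjamini-Hochberg adjusted p-values.
#'
#' @param abundances Tibble from [single_mark_abundance()] (`mark`,
#'   `sample`, `condition`, `abundance`).
#' @param condition_a,condition_b Group labels (baseline, comparison).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return One row per mark: group means, `fold_change`, `p_value`,
#'   `significant`, `one_condition` (and `p_adjusted` when requested).
#' @export
compare_conditions <- function(abundances, condition_a = "normal",
                               condition_b = "tumor", alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("mark", "condition", "abundance") %in% names(abundances)))
  out <- abundances |>
    filter(.data$condition %in% c(condition_a, condition_b)) |>
    group_by(.data$mark) |>
    group_map(function(d, key) {
      a <- d$abundance[d$condition == condition_a]
      b <- d$abundance[d$condition == condition_b]
      if (length(a) < 2 || length(b) < 2) {
        abort(sprintf("mark %s: need >= 2 replicates per condition",
                      key$mark[1]))
      }
      if (var(a) == 0 && var(b) == 0) {
        p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else {
          warn(sprintf("mark %s: zero variance with unequal means; p = 0",
                       key$mark[1]))
          0
        }
      } else {
        p <- t.test(b, a, var.equal = TRUE)$p.value
      }
      tibble(mark = key$mark[1],
             mean_a = mean(a), mean_b = mean(b),
             fold_change = mean(b) / mean(a),
             p_value = p,
             one_condition = xor(all(a == 0), all(b == 0)))
    }) |>
    bind_rows()
  if (adjust == "BH") {
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' Volcano table for mark comparisons
#'
#' One row per mark with `log2_fc` and `neg_log10_p` for plotting. Marks
#' detected in only one condition are kept but flagged, with `log2_fc = NA`
#' rather than an infinite coordinate.
#'
#' @param comparison Output of [compare_conditions()].
#' @return Tibble with `mark`, `log2_fc`, `neg_log10_p`, `significant`,
#'   `one_condition`.
#' @export
volcano_table <- function(comparison) {
  tibble(
    mark = comparison$mark,
    log2_fc = ifelse(comparison$one_condition | comparison$mean_a == 0,
                     NA_real_, log2(comparison$fold_change)),
    neg_log10_p = -log10(comparison$p_value),
    significant = comparison$significant,
    one_condition = comparison$one_condition
  )
}

#' Volcano plot of mark fold changes
#'
#' @param comparison Output of [compare_conditions()].
#' @param alpha Significance line.
#' @return A ggplot object; one-condition marks are omitted from the x-axis
#'   (they have no finite fold change).
#' @export
plot_volcano <- function(comparison, alpha = 0.05) {
  df <- volcano_table(comparison)
  df <- df[!is.na(df$log2_fc), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 p") +
    ggplot2::theme_classic()
}
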