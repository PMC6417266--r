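#' Assign adjacent genes to enhancer regions
#'
#' Links each enhancer to its putative target gene(s) by TSS proximity.
#' `mode = "nearest"` (default) links the single gene whose TSS is closest
#' to the enhancer midpoint; `mode = "window"` links every gene with a TSS
#' within `window` bp of the enhancer span. Equidistant TSSs break ties by
#' lexicographic `gene_id`. Enhancers on a chromosome without genes yield no
#' link (with a warning).
#'
#' @param enhancers Tibble of enhancer regions (`chrom`, `start`, `end`; a
#'   `ranked_enhancers` table works as-is).
#' @param genes Gene models with `gene_id` and `tss`.
#' @param window Window size in bp for `mode = "window"`.
#' @param mode Linking rule.
#' @return A tibble with the enhancer span, `gene_id` and `distance` - bp
#'   from the enhancer span to the TSS (0 when the TSS touches the span).
#' @export
assign_adjacent_genes <- function(enhancers, genes, window = 50000,
                                  mode = c("nearest", "window")) {
  mode <- match.arg(mode)
  check_intervals(enhancers, "enhancers")
  enh <- as_tibble(as.data.frame(enhancers)[, c("chrom", "start", "end")])
  links <- vector("list", nrow(enh))
  orphan <- FALSE
  for (i in seq_len(nrow(enh))) {
    g <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) { orphan <- TRUE; next }
    span_dist <- pmax(enh$start[i] - g$tss, g$tss - enh$end[i], 0)
    if (mode == "nearest") {
      mid <- (enh$start[i] + enh$end[i]) %/% 2
      mid_dist <- abs(g$tss - mid)
      best <- which(mid_dist == min(mid_dist))
      best <- best[order(g$gene_id[best])][1]   # lexicographic tie-break
      links[[i]] <- tibble(enh[i, ], gene_id = g$gene_id[best],
                           distance = span_dist[best])
    } else {
      keep <- which(span_dist <= window)
      keep <- keep[order(g$gene_id[keep])]
      if (length(keep) > 0) {
        links[[i]] <- tibble(enh[i, ][rep(1, length(keep)), ],
                             gene_id = g$gene_id[keep],
                             distance = span_dist[keep])
      }
    }
  }
  if (orphan) warn("some enhancers lie on chromosomes with no genes; no link made")
  out <- bind_rows(links)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), distance = numeric())
  }
  out
}

#' Classify expression change of linked genes between conditions
#'
#' For each linked gene, compares mean FPKM between the two conditions with
#' a pseudocount-guarded ratio `r = (m_tumor + pc) / (m_normal + pc)` and
#' labels the gene `increased` (`r >= fc_threshold`), `decreased`
#' (`r <= 1/fc_threshold`) or `no_change`. With `n_clusters = 4`, the
#' `no_change` genes are further split at a mean-FPKM cutoff into
#' `flat_low` / `flat_high`.
#'
#' @param links Tibble with a `gene_id` column (from
#'   [assign_adjacent_genes()]).
#' @param expr Long expression tibble (`gene_id`, `sample`, `condition`,
#'   `fpkm`).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param pseudocount Added to both means before the ratio (default
#'   `2^-5`, the offset used for log-FPKM displays).
#' @param condition_a,condition_b Baseline and comparison condition labels.
#' @param n_clusters 3 (default) or 4.
#' @param flat_cutoff Mean-FPKM boundary between `flat_low` and `flat_high`
#'   (4-cluster mode only).
#' @return `links` with `mean_a`, `mean_b`, `fold_change` and `cluster`
#'   columns added.
#' @export
classify_expression_change <- function(links, expr, fc_threshold = 1.5,
                                       pseudocount = 2^-5,
                                       condition_a = "normal",
                                       condition_b = "tumor",
                                       n_clusters = 3, flat_cutoff = 1) {
  stopifnot(fc_threshold >= 1, pseudocount >= 0, n_clusters %in% c(3, 4))
  missing_genes <- setdiff(unique(links$gene_id), unique(expr$gene_id))
  if (length(missing_genes) > 0) {
    abort(sprintf("gene absent from expression table: %s", missing_genes[1]))
  }
  means <- expr |>
    filter(.data$condition %in% c(condition_a, condition_b)) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(m = mean(.data$fpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  if (!all(c(condition_a, condition_b) %in% names(means))) {
    abort("expression table needs at least one sample per condition")
  }
  means <- tibble(gene_id = means$gene_id,
                  mean_a = means[[condition_a]],
                  mean_b = means[[condition_b]])
  out <- left_join(links, means, by = "gene_id")
  out$fold_change <- (out$mean_b + pseudocount) / (out$mean_a + pseudocount)
  out$cluster <- dplyr::case_when(
    out$fold_change >= fc_threshold ~ "increased",
    out$fold_change <= 1 / fc_threshold ~ "decreased",
    .default = "no_change"
  )
  if (n_clusters == 4) {
    flat <- out$cluster == "no_change"
    overall <- (out$mean_a + out$mean_b) / 2
    out$cluster[flat] <- ifelse(overall[flat] >= flat_cutoff,
                                "flat_high", "flat_low")
    out$cluster[out$cluster == "increased"] <- "up"
    out$cluster[out$cluster == "decreased"] <- "down"
  }
  out
}

#' Expression summaries for enhancer-defined gene classes
#'
#' Per gene class (e.g. super-enhancer-adjacent, typical-enhancer-adjacent,
#' no-enhancer) and condition, summarises the distribution of per-gene mean
#' FPKM: n, median and quartiles. Classes may overlap; empty classes are
#' reported with `n = 0`.
#'
#' @param expr Long expression tibble.
#' @param gene_sets Named list of gene-id character vectors.
#' @return A tibble with columns `class`, `condition`, `n`, `q1`, `median`,
#'   `q3`.
#' @export
summarize_expression_by_class <- function(expr, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  gene_means <- expr |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(m = mean(.data$fpkm), .groups = "drop")
  conds <- unique(gene_means$condition)
  bind_rows(lapply(names(gene_sets), function(cls) {
    gm <- gene_means[gene_means$gene_id %in% gene_sets[[cls]], , drop = FALSE]
    bind_rows(lapply(conds, function(cond) {
      v <- gm$m[gm$condition == cond]
      tibble(class = cls, condition = cond, n = length(v),
             q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
             median = if (length(v)) median(v) else NA_real_,
             q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
    }))
  }))
}

#' Box-plot of expression by enhancer class
#'
#' @param expr Long expression tibble.
#' @param gene_sets Named list of gene-id vectors (as in
#'   [summarize_expression_by_class()]).
#' @param pseudocount Offset inside the log2 display transform.
#' @return A ggplot object (log2(FPKM + pseudocount) by class and
#'   condition).
#' @export
plot_expression_by_class <- function(expr, gene_sets, pseudocount = 2^-5) {
  df <- bind_rows(lapply(names(gene_sets), function(cls) {
    x <- expr[expr$gene_id %in% gene_sets[[cls]], , drop = FALSE]
    x$class <- cls
    x
  })) |>
    group_by(.data$class, .data$condition, .data$gene_id) |>
    summarise(m = mean(.data$fpkm), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                   y = log2(.data$m + pseudocount),
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = sprintf("log2(mean FPKM + 2^%d)",
                                        round(log2(pseudocount)))) +
    ggplot2::theme_classic()
}
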