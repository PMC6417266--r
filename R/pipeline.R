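#' Write a complete synthetic input bundle to disk
#'
#' Generates the synthetic dataset for `seed` and writes every input the
#' pipeline consumes, in standard formats, plus ground-truth sidecars
#' (`synthetic_ground_truth.tsv`, `synthetic_se_adjacent_genes.txt`) naming
#' the planted regions and genes. The bundle feeds [run_all()] unchanged.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config Optional [sim_config()]; its seed is replaced by `seed`.
#' @return The dataset list from [simulate_enhancer_dataset()], invisibly.
#' @export
make_demo <- function(outdir, seed = 20190312, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  else { config$seed <- seed }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_enhancer_dataset(config)
  p <- function(f) file.path(outdir, f)
  write_bed(ds$peaks$h3k27ac, p("peaks_h3k27ac.bed"))
  write_bed(ds$peaks$h3k4me3, p("peaks_h3k4me3.bed"))
  write_bedgraph(ds$tracks$h3k27ac, p("track_h3k27ac.bedgraph"))
  write_bedgraph(ds$tracks$h4k8ac, p("track_h4k8ac.bedgraph"))
  write_bedgraph(ds$tracks$h3k4me3, p("track_h3k4me3.bedgraph"))
  write_gtf_genes(ds$genes, p("genes.gtf"))
  write_tsv_stable(ds$chrom_sizes, p("chrom_sizes.tsv"))
  write_expression_table(ds$expression, p("expression.tsv"))
  write_peptidoform_table(ds$peptidoforms, p("peptidoforms.tsv"))
  write_tsv_stable(ds$truth, p("synthetic_ground_truth.tsv"))
  writeLines(ds$se_adjacent_genes, p("synthetic_se_adjacent_genes.txt"))
  cfg <- ds$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p("demo_config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(ds)
}

#' Run the full enhancer analysis on an input bundle
#'
#' End-to-end orchestration over a directory laid out as written by
#' [make_demo()] (peaks, tracks, genes, optional expression and
#' peptidoform tables):
#'
#' 1. conventional super-enhancer call (H3K27ac peaks ranked by H3K27ac);
#' 2. H3K4me3-enriched super-enhancer call (H3K4me3 regions ranked by
#'    H3K27ac);
#' 3. enhancer-adjacent gene links with expression-change clusters and
#'    per-class expression summaries (skipped with a warning when the
#'    expression table is absent);
#' 4. genome-binned Spearman correlation across tracks and the
#'    per-enhancer H3K27ac-H4K8ac Pearson correlation;
#' 5. histone-mark abundance comparison (skipped when the peptidoform
#'    table is absent);
#' 6. a machine-readable JSON run summary (counts, cutoffs, parameters).
#'
#' All outputs are deterministic and byte-stable given identical inputs.
#'
#' @param input_dir Directory with the input bundle.
#' @param out_dir Output directory (created if needed).
#' @param stitch_gap,boundary_min,center_min Enhancer-calling parameters,
#'   bp.
#' @param bin_width Genome bin width for track correlation, bp.
#' @param fc_threshold,pseudocount Expression-change parameters.
#' @param alpha Significance level for the mark comparison.
#' @return A list with the main result tables, invisibly.
#' @export
run_all <- function(input_dir, out_dir,
                    stitch_gap = 12500, boundary_min = 1500,
                    center_min = 3000, bin_width = 2000,
                    fc_threshold = 1.5, pseudocount = 2^-5,
                    alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p_in <- function(f) file.path(input_dir, f)
  p_out <- function(f) file.path(out_dir, f)
  need <- c("peaks_h3k27ac.bed", "peaks_h3k4me3.bed",
            "track_h3k27ac.bedgraph", "track_h4k8ac.bedgraph",
            "genes.gtf", "chrom_sizes.tsv")
  missing_f <- need[!file.exists(p_in(need))]
  if (length(missing_f) > 0) {
    abort(sprintf("input bundle incomplete, missing: %s",
                  paste(missing_f, collapse = ", ")))
  }
  k27_peaks <- read_bed(p_in("peaks_h3k27ac.bed"))
  k4_peaks <- read_bed(p_in("peaks_h3k4me3.bed"))
  k27_track <- read_bedgraph(p_in("track_h3k27ac.bedgraph"))
  k8_track <- read_bedgraph(p_in("track_h4k8ac.bedgraph"))
  genes <- read_gtf_genes(p_in("genes.gtf"))
  chrom_sizes <- readr::read_tsv(p_in("chrom_sizes.tsv"),
                                 col_types = readr::cols(
                                   chrom = readr::col_character(),
                                   length = readr::col_integer()))

  # 1. conventional super-enhancers
  se <- call_super_enhancers(k27_peaks, genes, k27_track,
                             stitch_gap = stitch_gap,
                             boundary_min = boundary_min,
                             center_min = center_min)
  write_enhancer_table(se, p_out("enhancers_h3k27ac.tsv"))

  # 2. H3K4me3-enriched super-enhancers
  k4se <- call_h3k4me3_super_enhancers(k4_peaks, genes, k27_track,
                                       stitch_gap = stitch_gap,
                                       boundary_min = boundary_min,
                                       center_min = center_min)
  write_enhancer_table(k4se, p_out("enhancers_h3k4me3.tsv"))

  # 3. adjacent genes and expression clusters
  links <- NULL; expr_summary <- NULL
  if (file.exists(p_in("expression.tsv")) && nrow(genes) > 0) {
    expr <- read_expression_table(p_in("expression.tsv"))
    sup <- tidy(se) |> filter(.data$is_super)
    typ <- tidy(se) |> filter(!.data$is_super)
    links <- assign_adjacent_genes(sup, genes) |>
      classify_expression_change(expr, fc_threshold = fc_threshold,
                                 pseudocount = pseudocount)
    write_tsv_stable(links, p_out("gene_links.tsv"))
    typ_genes <- assign_adjacent_genes(typ, genes)$gene_id
    sets <- list(
      super_adjacent = unique(links$gene_id),
      typical_adjacent = setdiff(unique(typ_genes), links$gene_id),
      no_enhancer = setdiff(genes$gene_id,
                            c(links$gene_id, typ_genes))
    )
    expr_summary <- summarize_expression_by_class(expr, sets)
    write_tsv_stable(expr_summary, p_out("expression_by_class.tsv"))
  } else {
    warn("expression table absent; gene-linking stage skipped")
  }

  # 4. correlations
  tracks <- list(h3k27ac = k27_track, h4k8ac = k8_track)
  if (file.exists(p_in("track_h3k4me3.bedgraph"))) {
    tracks$h3k4me3 <- read_bedgraph(p_in("track_h3k4me3.bedgraph"))
  }
  bins <- bin_genome(chrom_sizes, width = bin_width)
  bm <- bin_matrix(tracks, bins)
  cm <- correlate_samples(bm, method = "spearman")
  cm_tbl <- as_tibble(cm, rownames = "track")
  write_tsv_stable(cm_tbl, p_out("bin_correlation_spearman.tsv"))
  enh_cor <- enhancer_correlation(k27_track, k8_track, tidy(se),
                                  method = "pearson")

  # 5. histone-mark comparison
  ptm_cmp <- NULL
  if (file.exists(p_in("peptidoforms.tsv"))) {
    recs <- read_peptidoform_table(p_in("peptidoforms.tsv"))
    marks <- recs |>
      peptidoform_relative_abundance() |>
      single_mark_abundance()
    ptm_cmp <- compare_conditions(marks, alpha = alpha)
    write_tsv_stable(ptm_cmp, p_out("ptm_comparison.tsv"))
    write_tsv_stable(volcano_table(ptm_cmp), p_out("ptm_volcano.tsv"))
  } else {
    warn("peptidoform table absent; mark-comparison stage skipped")
  }

  # 6. run summary
  summary <- list(
    parameters = list(stitch_gap = stitch_gap, boundary_min = boundary_min,
                      center_min = center_min, bin_width = bin_width,
                      fc_threshold = fc_threshold,
                      pseudocount = pseudocount, alpha = alpha),
    n_enhancers = nrow(se),
    n_super = sum(se$is_super),
    n_typical = sum(!se$is_super),
    cutoff_signal = attr(se, "cutoff_signal"),
    n_k4_regions = nrow(k4se),
    n_k4_super = sum(k4se$is_super),
    enhancer_h3k27ac_h4k8ac_pearson = enh_cor,
    n_linked_genes = if (is.null(links)) NA else
      length(unique(links$gene_id)),
    n_genes_increased = if (is.null(links)) NA else
      sum(links$cluster == "increased"),
    n_marks_tested = if (is.null(ptm_cmp)) NA else nrow(ptm_cmp),
    n_marks_significant = if (is.null(ptm_cmp)) NA else
      sum(ptm_cmp$significant),
    package_version = as.character(utils::packageVersion("enhancerscope"))
  )
  jsonlite::write_json(summary, p_out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(se = se, k4se = k4se, links = links,
                 expr_summary = expr_summary, bin_correlation = cm,
                 enhancer_correlation = enh_cor, ptm = ptm_cmp,
                 summary = summary))
}
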