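#' Configuration for the synthetic enhancer-epigenomics dataset
#'
#' Bundles every knob of the planted-truth generator. The defaults describe
#' a small genome carrying clearly separated enhancer classes: typical
#' enhancer clusters at a common baseline signal, super-enhancer clusters
#' boosted `se_signal_ratio`-fold, H3K4me3-marked clusters of which a
#' fraction `k4_overlap_fraction` sit on planted super-enhancers, an
#' H4K8ac track co-localized with H3K27ac at a planted correlation, and
#' expression/peptidoform tables with planted condition effects.
#'
#' Noise structure: per-peak heights and per-interval track values vary with
#' a heavy-tailed log-normal of sd `signal_sigma`, while cluster *totals*
#' vary with a narrow log-normal of sd `cluster_sigma`, so the ranked-signal
#' curve of a single enhancer class is close to linear and the hockey-stick
#' shape comes from the planted super-enhancer boost.
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Number of genes to place (uniformly, with minimum
#'   spacing).
#' @param gene_length_range Min/max gene length, bp.
#' @param min_gap Minimum spacing between placed elements (genes and
#'   enhancer clusters), bp; must exceed the stitching gap so clusters never
#'   merge across slots.
#' @param n_typical_clusters,n_super_clusters Planted H3K27ac enhancer
#'   clusters of each class.
#' @param n_k4_clusters High-H3K27ac clusters carrying distal H3K4me3
#'   peaks (candidate H3K4me3 super-enhancers).
#' @param n_k4_typical_clusters Distal H3K4me3 clusters at baseline
#'   H3K27ac.
#' @param k4_overlap_fraction Fraction of the `n_k4_clusters` placed on
#'   planted super-enhancers (the rest get their own high-H3K27ac sites
#'   without H3K27ac peak calls).
#' @param peaks_per_cluster,peak_width_range,intra_gap_range Cluster
#'   internal geometry, bp.
#' @param base_signal Expected H3K27ac cluster total for typical clusters
#'   (arbitrary area units).
#' @param se_signal_ratio Super-enhancer total over typical total (>= 1).
#' @param cluster_sigma Log-normal sd of cluster totals.
#' @param signal_sigma Log-normal sd of within-cluster structure.
#' @param mark_correlation Planted (empirical) correlation between the
#'   per-cluster H3K27ac and H4K8ac log multipliers; 1 gives exact
#'   proportionality.
#' @param k8_scale H4K8ac/H3K27ac total ratio.
#' @param promoter_peak_fraction Fraction of genes receiving
#'   promoter-proximal H3K27ac/H3K4me3 peaks (removed by the distal
#'   filter).
#' @param expr_boost_for_se_adjacent Tumor-condition fold boost of genes
#'   nearest to planted super-enhancers.
#' @param fpkm_shape,fpkm_scale Gamma parameters of per-gene baseline mean
#'   FPKM.
#' @param fpkm_rep_shape Gamma shape of replicate FPKM around the gene
#'   mean (larger = less replicate noise).
#' @param n_replicates Replicates per condition (expression and
#'   peptidoforms).
#' @param ptm_sigma Log-normal sd of peptidoform peak areas.
#' @param ptm_effects Named vector of tumor/normal area multipliers for the
#'   planted differential marks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 20190312,
                       n_chroms = 4, chrom_length = 4e6,
                       n_genes = 200, gene_length_range = c(2000, 8000),
                       min_gap = 15000,
                       n_typical_clusters = 60, n_super_clusters = 12,
                       n_k4_clusters = 20, n_k4_typical_clusters = 40,
                       k4_overlap_fraction = 0.6,
                       peaks_per_cluster = c(2, 6),
                       peak_width_range = c(400, 1200),
                       intra_gap_range = c(200, 2000),
                       base_signal = 100, se_signal_ratio = 20,
                       cluster_sigma = 0.05, signal_sigma = 0.3,
                       mark_correlation = 0.8, k8_scale = 0.8,
                       promoter_peak_fraction = 0.5,
                       expr_boost_for_se_adjacent = 4,
                       fpkm_shape = 2, fpkm_scale = 2.5,
                       fpkm_rep_shape = 20,
                       n_replicates = 3,
                       ptm_sigma = 0.2,
                       ptm_effects = c(H4K8ac = 3, H3K27ac = 2.5,
                                       H3K18ac = 2, H3K23me1 = 0.4,
                                       H3K36me3 = 0.4)) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$seed == round(cfg$seed), cfg$n_chroms >= 1, cfg$chrom_length > 0,
    cfg$n_genes >= 0, cfg$min_gap > 12500,
    cfg$n_typical_clusters >= 0, cfg$n_super_clusters >= 0,
    cfg$n_k4_clusters >= 0, cfg$n_k4_typical_clusters >= 0,
    cfg$k4_overlap_fraction >= 0, cfg$k4_overlap_fraction <= 1,
    cfg$se_signal_ratio >= 1, cfg$base_signal > 0,
    cfg$cluster_sigma >= 0, cfg$signal_sigma >= 0,
    cfg$mark_correlation >= -1, cfg$mark_correlation <= 1,
    cfg$k8_scale > 0,
    cfg$promoter_peak_fraction >= 0, cfg$promoter_peak_fraction <= 1,
    cfg$expr_boost_for_se_adjacent > 0, cfg$n_replicates >= 2
  )
  n_on_super <- round(cfg$k4_overlap_fraction * cfg$n_k4_clusters)
  if (n_on_super > cfg$n_super_clusters) {
    abort(sprintf(paste0(
      "k4_overlap_fraction %.2f needs %d super clusters to host H3K4me3 ",
      "peaks but only %d are planted"),
      cfg$k4_overlap_fraction, n_on_super, cfg$n_super_clusters))
  }
  cfg$n_k4_on_super <- n_on_super
  cfg$n_k4_only <- cfg$n_k4_clusters - n_on_super
  class(cfg) <- "sim_config"
  cfg
}

# run code under a derived seed, restoring the caller's RNG state
with_sim_seed <- function(config, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((config$seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Simulate the genome layout: chromosome sizes, genes and enhancer slots
#'
#' Lays out genes and enhancer-cluster slots along the chromosomes with at
#' least `min_gap` bp between consecutive elements, so every planted
#' cluster is distal to every TSS and no two clusters can stitch together.
#' Deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return A list with `chrom_sizes` (tibble `chrom`, `length`), `genes`
#'   (gene-model tibble as from [read_gtf_genes()]) and `slots` (tibble of
#'   cluster anchors with a planted `class` column).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 1L, {
    slot_classes <- c(rep("typical", config$n_typical_clusters),
                      rep("super", config$n_super_clusters),
                      rep("k4_only", config$n_k4_only),
                      rep("k4_typical", config$n_k4_typical_clusters))
    n_slots <- length(slot_classes)
    kinds <- sample(c(rep("gene", config$n_genes), rep("slot", n_slots)))
    slot_width <- max(config$peaks_per_cluster) *
      max(config$peak_width_range) +
      (max(config$peaks_per_cluster) - 1) * max(config$intra_gap_range)
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    chrom_of <- rep(chroms, length.out = max(length(kinds), 1))
    chrom_of <- sort(chrom_of)[seq_along(kinds)]  # contiguous chunks

    genes <- list(); slots <- list()
    cursor <- setNames(rep(20000, config$n_chroms), chroms)
    strand_pool <- sample(c("+", "-"), length(kinds), replace = TRUE)
    gi <- 0L; si <- 0L
    slot_class_order <- sample(slot_classes)
    for (j in seq_along(kinds)) {
      ch <- chrom_of[j]
      pos <- cursor[ch] + round(runif(1, config$min_gap, config$min_gap + 10000))
      if (kinds[j] == "gene") {
        gi <- gi + 1L
        len <- round(runif(1, config$gene_length_range[1],
                           config$gene_length_range[2]))
        strand <- strand_pool[j]
        genes[[gi]] <- tibble(
          gene_id = sprintf("gene_%03d", gi), chrom = ch, strand = strand,
          start = as.integer(pos), end = as.integer(pos + len))
        cursor[ch] <- pos + len
      } else {
        si <- si + 1L
        slots[[si]] <- tibble(slot_id = sprintf("slot_%03d", si), chrom = ch,
                              anchor = as.integer(pos),
                              class = slot_class_order[si])
        cursor[ch] <- pos + slot_width
      }
      if (cursor[ch] > config$chrom_length - 20000) {
        abort(sprintf("infeasible packing: %s overflows at element %d", ch, j))
      }
    }
    genes <- bind_rows(genes)
    if (nrow(genes) > 0) {
      genes$tss <- as.integer(ifelse(genes$strand == "+", genes$start,
                                     genes$end - 1L))
      genes$tes <- as.integer(ifelse(genes$strand == "+", genes$end - 1L,
                                     genes$start))
    } else {
      genes <- tibble(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), tss = integer(), tes = integer())
    }
    list(
      chrom_sizes = tibble(chrom = chroms,
                           length = as.integer(config$chrom_length)),
      genes = genes,
      slots = bind_rows(slots)
    )
  })
}

# standard-normal pair with EXACT sample correlation rho (Gram-Schmidt)
planted_normal_pair <- function(n, rho) {
  if (n < 3) return(list(u = rep(0, n), v = rep(0, n)))
  u <- rnorm(n); w <- rnorm(n)
  u <- (u - mean(u)) / sd(u)
  w <- w - u * sum(u * w) / sum(u * u)
  w <- (w - mean(w)) / sd(w)
  list(u = u, v = rho * u + sqrt(1 - rho^2) * w)
}

# split a peak into subintervals with heavy-tailed heights; exact total area
peak_intervals <- function(chrom, start, end, total, sigma, n_sub = 4) {
  bounds <- unique(round(seq(start, end, length.out = n_sub + 1)))
  s <- bounds[-length(bounds)]; e <- bounds[-1]
  h <- rlnorm(length(s), 0, sigma)
  area <- h * (e - s)
  tibble(chrom = chrom, start = as.integer(s), end = as.integer(e),
         value = h * total / sum(area))
}

#' Simulate peak calls, signal tracks and the planted ground truth
#'
#' Builds, per planted cluster, 2-6 peaks with heavy-tailed internal
#' structure whose summed track integral equals the planted cluster total:
#' baseline for typical clusters, `se_signal_ratio`-fold for
#' super-enhancer-class clusters. The H4K8ac track reuses the same peak
#' spans (co-localization) with totals whose log deviations have exactly
#' the planted sample correlation with H3K27ac's. H3K4me3 peaks are placed
#' on the K4-class clusters; promoter-proximal H3K27ac/H3K4me3 peaks are
#' added at a fraction of TSSs (and are removed later by the distal
#' filter). High-H3K27ac `k4_only` clusters get track signal but no
#' H3K27ac peak call, emulating enhancers visible by H3K4me3 only.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list with `peaks` (named list of BED-style tibbles: `h3k27ac`,
#'   `h3k4me3`), `tracks` (named list of [signal_track()]: `h3k27ac`,
#'   `h4k8ac`, `h3k4me3`) and `truth` (tibble of planted regions with
#'   class, planted totals and `has_k4`).
#' @export
simulate_peaks_and_tracks <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 2L, {
    slots <- genome$slots
    n <- nrow(slots)
    if (n == 0) abort("genome has no enhancer slots to simulate")
    high <- slots$class %in% c("super", "k4_only")
    base <- config$base_signal *
      ifelse(high, config$se_signal_ratio, 1)
    uv <- planted_normal_pair(n, config$mark_correlation)
    k27_total <- base * exp(config$cluster_sigma * uv$u)
    k8_total <- config$k8_scale * base * exp(config$cluster_sigma * uv$v)

    # which supers host H3K4me3 peaks (in slot order: deterministic)
    super_idx <- which(slots$class == "super")
    k4_on <- super_idx[seq_len(config$n_k4_on_super)]
    has_k4 <- slots$class %in% c("k4_only", "k4_typical") |
      seq_len(n) %in% k4_on

    k27_peaks <- list(); k4_peaks <- list()
    k27_iv <- list(); k8_iv <- list(); k4_iv <- list()
    hull_start <- integer(n); hull_end <- integer(n)
    for (i in seq_len(n)) {
      k <- sample(seq(config$peaks_per_cluster[1],
                      config$peaks_per_cluster[2]), 1)
      w <- round(runif(k, config$peak_width_range[1],
                       config$peak_width_range[2]))
      g <- round(runif(k, config$intra_gap_range[1],
                       config$intra_gap_range[2]))
      starts <- slots$anchor[i] + cumsum(c(0, head(w + g, -1)))
      ends <- starts + w
      hull_start[i] <- starts[1]; hull_end[i] <- ends[k]
      spans <- tibble(chrom = slots$chrom[i], start = as.integer(starts),
                      end = as.integer(ends))
      # partition cluster totals across peaks (heavy-tailed weights)
      wt27 <- rlnorm(k, 0, config$signal_sigma); wt27 <- wt27 / sum(wt27)
      wt8 <- rlnorm(k, 0, config$signal_sigma); wt8 <- wt8 / sum(wt8)
      k27_iv[[i]] <- bind_rows(lapply(seq_len(k), function(j) {
        peak_intervals(slots$chrom[i], starts[j], ends[j],
                       k27_total[i] * wt27[j], config$signal_sigma)
      }))
      k8_iv[[i]] <- bind_rows(lapply(seq_len(k), function(j) {
        peak_intervals(slots$chrom[i], starts[j], ends[j],
                       k8_total[i] * wt8[j], config$signal_sigma)
      }))
      if (slots$class[i] %in% c("typical", "super")) {
        k27_peaks[[i]] <- mutate(spans, name = slots$slot_id[i])
      }
      if (has_k4[i]) {
        k4_peaks[[i]] <- mutate(spans, name = slots$slot_id[i])
        wt4 <- rlnorm(k, 0, config$signal_sigma); wt4 <- wt4 / sum(wt4)
        k4_tot <- config$base_signal * exp(config$cluster_sigma * rnorm(1))
        k4_iv[[i]] <- bind_rows(lapply(seq_len(k), function(j) {
          peak_intervals(slots$chrom[i], starts[j], ends[j],
                         k4_tot * wt4[j], config$signal_sigma)
        }))
      }
    }

    # promoter-proximal peaks at a fraction of TSSs
    genes <- genome$genes
    if (nrow(genes) > 0 && config$promoter_peak_fraction > 0) {
      np <- round(config$promoter_peak_fraction * nrow(genes))
      pick <- sort(sample(nrow(genes), np))
      for (i in pick) {
        s <- max(genes$tss[i] - 400L, 0L); e <- genes$tss[i] + 400L
        span <- tibble(chrom = genes$chrom[i], start = as.integer(s),
                       end = as.integer(e),
                       name = paste0("prom_", genes$gene_id[i]))
        k27_peaks[[length(k27_peaks) + 1]] <- span
        k4_peaks[[length(k4_peaks) + 1]] <- span
        amp <- config$base_signal * 0.5
        k27_iv[[length(k27_iv) + 1]] <-
          peak_intervals(span$chrom, s, e, amp * rlnorm(1, 0, config$signal_sigma),
                         config$signal_sigma)
        k4_iv[[length(k4_iv) + 1]] <-
          peak_intervals(span$chrom, s, e,
                         2 * amp * rlnorm(1, 0, config$signal_sigma),
                         config$signal_sigma)
      }
    }

    truth <- tibble(slot_id = slots$slot_id, chrom = slots$chrom,
                    start = hull_start, end = hull_end,
                    class = slots$class, has_k4 = has_k4,
                    k27_total = k27_total, k8_total = k8_total)
    bind_peaks <- function(lst) {
      if (length(lst) == 0) {
        return(tibble(chrom = character(), start = integer(),
                      end = integer(), name = character()))
      }
      bind_rows(lst)
    }
    bind_iv <- function(lst) {
      if (length(lst) == 0) {
        return(tibble(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
      }
      bind_rows(lst)
    }
    list(
      peaks = list(h3k27ac = bind_peaks(k27_peaks),
                   h3k4me3 = bind_peaks(k4_peaks)),
      tracks = list(h3k27ac = signal_track(bind_iv(k27_iv)),
                    h4k8ac = signal_track(bind_iv(k8_iv)),
                    h3k4me3 = signal_track(bind_iv(k4_iv))),
      truth = truth
    )
  })
}

#' Simulate the gene expression table
#'
#' Per-gene baseline mean FPKM is gamma-distributed; replicate FPKM values
#' are gamma around the gene mean. In the tumor condition, the gene nearest
#' to each planted super-enhancer has its mean multiplied by
#' `expr_boost_for_se_adjacent`; the normal condition is unboosted.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Ground-truth tibble from [simulate_peaks_and_tracks()].
#' @return A list: `expression` (long tibble `gene_id`, `sample`,
#'   `condition`, `fpkm`) and `se_adjacent_genes` (character vector).
#' @export
simulate_expression <- function(config, genome, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 3L, {
    genes <- genome$genes
    if (nrow(genes) == 0) {
      return(list(expression = tibble(gene_id = character(),
                                      sample = character(),
                                      condition = character(),
                                      fpkm = numeric()),
                  se_adjacent_genes = character()))
    }
    supers <- truth[truth$class == "super", , drop = FALSE]
    se_genes <- character(0)
    for (i in seq_len(nrow(supers))) {
      g <- genes[genes$chrom == supers$chrom[i], , drop = FALSE]
      if (nrow(g) == 0) next
      mid <- (supers$start[i] + supers$end[i]) %/% 2
      se_genes <- c(se_genes, g$gene_id[which.min(abs(g$tss - mid))])
    }
    se_genes <- unique(se_genes)
    mu <- rgamma(nrow(genes), shape = config$fpkm_shape,
                 scale = config$fpkm_scale)
    samples <- c(sprintf("normal_%d", seq_len(config$n_replicates)),
                 sprintf("tumor_%d", seq_len(config$n_replicates)))
    condition <- rep(c("normal", "tumor"), each = config$n_replicates)
    expr <- tidyr::expand_grid(gene_id = genes$gene_id, sample = samples)
    expr$condition <- rep(condition, times = nrow(genes))
    m <- rep(mu, each = length(samples))
    boost <- ifelse(expr$condition == "tumor" &
                      expr$gene_id %in% se_genes,
                    config$expr_boost_for_se_adjacent, 1)
    m <- m * boost
    expr$fpkm <- rgamma(nrow(expr), shape = config$fpkm_rep_shape,
                        scale = m / config$fpkm_rep_shape)
    list(expression = expr, se_adjacent_genes = se_genes)
  })
}

# built-in histone peptide map: marks hosted by each Arg-C-like peptide
ptm_peptide_map <- function() {
  list(
    "H3 3-8" = c("H3K4me1", "H3K4me2", "H3K4me3", "H3K4ac"),
    "H3 9-17" = c("H3K9me1", "H3K9me2", "H3K9me3", "H3K9ac", "H3K14ac"),
    "H3 18-26" = c("H3K18ac", "H3K23ac", "H3K23me1"),
    "H3 27-40" = c("H3K27me1", "H3K27me2", "H3K27me3", "H3K27ac",
                   "H3K36me1", "H3K36me2", "H3K36me3"),
    "H4 4-17" = c("H4K5ac", "H4K8ac", "H4K12ac", "H4K16ac")
  )
}

#' Simulate histone peptidoform peak areas
#'
#' Emulates a DIA histone-PTM experiment over five H3/H4 peptides: each
#' peptide carries its unmodified form, every single-mark form and a few
#' two-mark forms, with log-normal peak areas around per-form base weights
#' and a global per-sample scale factor (which cancels in relative
#' abundance). In the tumor condition, forms carrying a mark listed in
#' `ptm_effects` have their areas multiplied by that effect.
#'
#' @param config A [sim_config()].
#' @return A long tibble (`peptide_id`, `ptm_combo`, `sample`, `condition`,
#'   `area`) with `n_replicates` samples per condition.
#' @export
simulate_peptidoform_areas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 4L, {
    pepmap <- ptm_peptide_map()
    forms <- bind_rows(lapply(names(pepmap), function(pep) {
      marks <- pepmap[[pep]]
      singles <- marks
      doubles <- if (length(marks) >= 4) {
        utils::combn(marks, 2)[, seq_len(min(3, ncol(utils::combn(marks, 2)))),
                               drop = FALSE]
      } else NULL
      combos <- c("", singles,
                  if (!is.null(doubles)) apply(doubles, 2, paste,
                                               collapse = "+"))
      tibble(peptide_id = pep, ptm_combo = combos)
    }))
    # per-form base weight: unmodified forms dominate
    forms$weight <- ifelse(forms$ptm_combo == "",
                           rlnorm(nrow(forms), log(30), 0.3),
                           rlnorm(nrow(forms), log(4), 0.6))
    samples <- c(sprintf("normal_%d", seq_len(config$n_replicates)),
                 sprintf("tumor_%d", seq_len(config$n_replicates)))
    condition <- rep(c("normal", "tumor"), each = config$n_replicates)
    sample_scale <- rlnorm(length(samples), log(1e6), 0.2)

    effect_of <- function(combo) {
      if (combo == "") return(1)
      prod(config$ptm_effects[intersect(strsplit(combo, "+", fixed = TRUE)[[1]],
                                        names(config$ptm_effects))],
           na.rm = TRUE)
    }
    form_effect <- vapply(forms$ptm_combo, effect_of, 1.0)

    out <- tidyr::expand_grid(forms[, c("peptide_id", "ptm_combo")],
                              sample = samples)
    out$condition <- rep(condition, times = nrow(forms))
    w <- rep(forms$weight, each = length(samples))
    eff <- ifelse(out$condition == "tumor",
                  rep(form_effect, each = length(samples)), 1)
    scl <- rep(sample_scale, times = nrow(forms))
    out$area <- w * eff * scl * rlnorm(nrow(out), 0, config$ptm_sigma)
    out
  })
}

#' Simulate the complete synthetic dataset
#'
#' Convenience wrapper running [simulate_genome()],
#' [simulate_peaks_and_tracks()], [simulate_expression()] and
#' [simulate_peptidoform_areas()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `chrom_sizes`, `genes`, `peaks`, `tracks`,
#'   `truth`, `expression`, `se_adjacent_genes`, `peptidoforms`.
#' @export
simulate_enhancer_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  pt <- simulate_peaks_and_tracks(config, genome)
  ex <- simulate_expression(config, genome, pt$truth)
  list(config = config,
       chrom_sizes = genome$chrom_sizes,
       genes = genome$genes,
       peaks = pt$peaks,
       tracks = pt$tracks,
       truth = pt$truth,
       expression = ex$expression,
       se_adjacent_genes = ex$se_adjacent_genes,
       peptidoforms = simulate_peptidoform_areas(config))
}
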