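# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Exhaustive scan for the ranked-curve cutoff: sort signals ascending,
# scale both axes to [0, 1], and walk every index recording the vertical
# distance to the diagonal; ties resolved to the largest index. Returns the
# 0-based cutoff rank and the number of regions strictly above it.
oracle_curve_cutoff <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(n)) {
    gap <- (i - 1) / (n - 1) - s[i] / s[n]
    if (gap >= best) {   # >= keeps the largest index on ties
      best <- gap
      best_i <- i
    }
  }
  list(cutoff_rank = best_i - 1L, n_super = sum(s > s[best_i]))
}

# Brute-force transitive-closure stitching: build the full pairwise
# adjacency graph (same chromosome, inter-peak gap < `gap`) and take its
# connected components via igraph.
oracle_stitch <- function(peaks, gap = 12500) {
  n <- nrow(peaks)
  if (n == 0) return(peaks[, c("chrom", "start", "end")])
  # full O(n^2) pairwise adjacency: same chromosome and pair gap < `gap`
  pair_gap <- outer(peaks$start, peaks$start, pmax) -
    outer(peaks$end, peaks$end, pmin)
  adj <- pair_gap < gap & outer(peaks$chrom, peaks$chrom, `==`)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = peaks$chrom[idx[1]],
               start = min(peaks$start[idx]),
               end = max(peaks$end[idx]),
               n_constituent_peaks = length(idx))
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Spearman via explicit average ranks + textbook Pearson formula.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Closed-form equal-variance two-sided t-test.
oracle_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), df = na + nb - 2)
}

# Random peak set on a couple of chromosomes, dense enough that stitching
# decisions are non-trivial.
random_peaks <- function(n, span = 3e5, chroms = c("chrA", "chrB")) {
  start <- sort(sample.int(span, n))
  width <- sample(100:5000, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + width)
}

# Tiny deterministic fixtures shared by several files.
toy_track <- function() {
  signal_track(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 10L, 0L),
    end = c(10L, 30L, 50L),
    value = c(2, 1, 0.5)))
}

toy_genes <- function() {
  tibble::tibble(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                 strand = c("+", "-"), start = c(1000L, 50000L),
                 end = c(2000L, 60000L), tss = c(1000L, 59999L),
                 tes = c(1999L, 50000L))
}
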