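make_expr <- function(genes, normal, tumor) {
  tibble::tibble(
    gene_id = rep(genes, each = 4),
    sample = rep(c("n1", "n2", "t1", "t2"), times = length(genes)),
    condition = rep(c("normal", "normal", "tumor", "tumor"),
                    times = length(genes)),
    fpkm = as.numeric(rbind(normal, normal, tumor, tumor)))
}

test_that("nearest-gene assignment uses midpoint distance with gene_id ties", {
  genes <- tibble::tibble(
    gene_id = c("gB", "gA", "gC"), chrom = "chr1", strand = "+",
    start = c(20000L, 40000L, 90000L), end = c(21000L, 41000L, 91000L),
    tss = c(20000L, 40000L, 90000L), tes = c(20999L, 40999L, 90999L))
  enh <- tibble::tibble(chrom = "chr1", start = 28000L, end = 32000L)
  # midpoint 30000: gB at 10 kb, gA at 10 kb -> lexicographic tie to gA
  link <- assign_adjacent_genes(enh, genes)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$distance, 40000 - 32000)

  closer <- tibble::tibble(chrom = "chr1", start = 22000L, end = 26000L)
  expect_equal(assign_adjacent_genes(closer, genes)$gene_id, "gB")

  # TSS exactly at the enhancer edge -> distance 0
  edge <- tibble::tibble(chrom = "chr1", start = 15000L, end = 20000L)
  expect_equal(assign_adjacent_genes(edge, genes)$distance, 0)

  # no genes on the chromosome -> no link, with a warning
  lonely <- tibble::tibble(chrom = "chrZ", start = 0L, end = 100L)
  expect_warning(out <- assign_adjacent_genes(lonely, genes), "no genes")
  expect_equal(nrow(out), 0)
})

test_that("window mode returns every gene within range of the span", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    start = c(1000L, 30000L, 200000L), end = c(2000L, 31000L, 201000L),
    tss = c(1000L, 30000L, 200000L), tes = c(1999L, 30999L, 200999L))
  enh <- tibble::tibble(chrom = "chr1", start = 10000L, end = 20000L)
  links <- assign_adjacent_genes(enh, genes, window = 50000, mode = "window")
  expect_setequal(links$gene_id, c("g1", "g2"))
  expect_true(all(links$distance <= 50000))
})

test_that("nearest assignment agrees with a brute-force scan", {
  set.seed(31)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30), chrom = "chr1", strand = "+",
    start = as.integer(sort(sample.int(5e5, 30))))
  genes$end <- genes$start + 1000L
  genes$tss <- genes$start
  genes$tes <- genes$end - 1L
  enh <- random_peaks(40, span = 5e5, chroms = "chr1")
  links <- assign_adjacent_genes(enh, genes)
  for (i in seq_len(nrow(enh))) {
    mid <- (enh$start[i] + enh$end[i]) %/% 2
    expect_equal(min(abs(genes$tss - mid)),
                 abs(genes$tss[genes$gene_id == links$gene_id[i]] - mid))
  }
})

test_that("expression-change classification follows the guarded ratio", {
  genes <- c("flat", "up", "both_zero")
  expr <- make_expr(genes, normal = c(2, 1, 0), tumor = c(2, 3, 0))
  links <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L,
                          gene_id = genes, distance = 0)
  got <- classify_expression_change(links, expr)
  expect_equal(got$cluster, c("no_change", "increased", "no_change"))
  expect_equal(got$fold_change[1], 1)
  expect_equal(got$fold_change[3], 1)   # pseudocount guards 0/0

  expect_error(
    classify_expression_change(
      tibble::tibble(chrom = "chr1", start = 0L, end = 1L,
                     gene_id = "ghost", distance = 0), expr),
    "ghost")
})

test_that("classification is antisymmetric under condition swap", {
  set.seed(32)
  genes <- sprintf("g%02d", 1:40)
  expr <- make_expr(genes, normal = rlnorm(40, 1, 1), tumor = rlnorm(40, 1, 1))
  links <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L,
                          gene_id = genes, distance = 0)
  fwd <- classify_expression_change(links, expr)
  rev <- classify_expression_change(links, expr, condition_a = "tumor",
                                    condition_b = "normal")
  expect_equal(rev$fold_change, 1 / fwd$fold_change)
  map <- c(increased = "decreased", decreased = "increased",
           no_change = "no_change")
  expect_equal(rev$cluster, unname(map[fwd$cluster]))
  # labels partition the links
  expect_true(all(fwd$cluster %in% names(map)))
})

test_that("four-cluster mode splits flat genes at the expression cutoff", {
  genes <- c("up", "down", "flat_lo", "flat_hi")
  expr <- make_expr(genes, normal = c(1, 4, 0.1, 6), tumor = c(4, 1, 0.1, 6))
  links <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L,
                          gene_id = genes, distance = 0)
  got <- classify_expression_change(links, expr, n_clusters = 4)
  expect_equal(got$cluster, c("up", "down", "flat_low", "flat_high"))
})

test_that("class summaries report n/median/quartiles, degenerate cases included", {
  genes <- c("a", "b", "c")
  expr <- make_expr(genes, normal = c(1, 2, 3), tumor = c(2, 4, 6))
  s <- summarize_expression_by_class(expr, list(all = genes, one = "b",
                                                none = character()))
  expect_equal(s$n[s$class == "none"], c(0, 0))
  one_t <- s[s$class == "one" & s$condition == "tumor", ]
  expect_equal(one_t$median, 4)
  all_n <- s[s$class == "all" & s$condition == "normal", ]
  expect_equal(all_n$median, 2)
  # identical gene sets -> identical summaries
  s2 <- summarize_expression_by_class(expr, list(x = genes, y = genes))
  expect_equal(s2[s2$class == "x", -1], s2[s2$class == "y", -1])
})

test_that("planted expression boost separates SE-adjacent genes", {
  ds <- simulate_enhancer_dataset(sim_config(seed = 61))
  sets <- list(se_adjacent = ds$se_adjacent_genes,
               other = setdiff(ds$genes$gene_id, ds$se_adjacent_genes))
  s <- summarize_expression_by_class(ds$expression, sets)
  med <- function(cls, cond) s$median[s$class == cls & s$condition == cond]
  expect_gt(med("se_adjacent", "tumor"), med("other", "tumor"))
  # and classification labels >= 90% of SE-adjacent genes as increased
  links <- tibble::tibble(chrom = "chr1", start = 0L, end = 1L,
                          gene_id = ds$se_adjacent_genes, distance = 0)
  got <- classify_expression_change(links, ds$expression)
  expect_gte(mean(got$cluster == "increased"), 0.9)
})
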