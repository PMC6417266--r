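rec <- function(combos, areas, sample = "s1", condition = "normal",
                peptide = "H3 27-40") {
  tibble::tibble(peptide_id = peptide, ptm_combo = combos, sample = sample,
                 condition = condition, area = areas)
}

test_that("peptidoform relative abundance is the percent of summed area", {
  r <- peptidoform_relative_abundance(rec(c("", "H3K27ac"), c(80, 20)))
  expect_equal(r$rel_abundance, c(80, 20))
  r <- peptidoform_relative_abundance(rec("H3K27me1", 42))
  expect_equal(r$rel_abundance, 100)
  r <- peptidoform_relative_abundance(rec(c("a", "b", "c"), c(1, 1, 2)))
  expect_equal(r$rel_abundance, c(25, 25, 50))
  expect_error(peptidoform_relative_abundance(rec(c("", "x"), c(0, 0))),
               "total area is 0")
})

test_that("percent conservation holds per peptide and sample", {
  set.seed(41)
  recs <- simulate_peptidoform_areas(sim_config(seed = 41))
  rel <- peptidoform_relative_abundance(recs)
  sums <- rel |>
    dplyr::group_by(peptide_id, sample) |>
    dplyr::summarise(total = sum(rel_abundance), .groups = "drop")
  expect_true(all(abs(sums$total - 100) < 1e-9))
})

test_that("single-mark abundance sums over modified forms carrying the mark", {
  r <- peptidoform_relative_abundance(
    rec(c("H3K27ac", "H3K27ac+H3K36me1", "H3K36me1", ""),
        c(10, 5, 20, 65)))
  ab <- single_mark_abundance(r, marks = c("H3K27ac", "H3K36me1"))
  expect_equal(ab$abundance[ab$mark == "H3K27ac"], 15)
  expect_equal(ab$abundance[ab$mark == "H3K36me1"], 25)
  # absent mark -> 0 with a warning
  expect_warning(ab0 <- single_mark_abundance(r, marks = "H4K8ac"),
                 "not observed")
  expect_equal(ab0$abundance, 0)
  # every combo carries the mark -> exactly 100
  r2 <- peptidoform_relative_abundance(
    rec(c("H3K27ac", "H3K27ac+H3K36me1"), c(30, 70)))
  ab2 <- single_mark_abundance(r2, marks = "H3K27ac")
  expect_equal(ab2$abundance, 100)
})

test_that("mark abundance stays within [0, 100] on simulated data", {
  recs <- simulate_peptidoform_areas(sim_config(seed = 42))
  ab <- recs |>
    peptidoform_relative_abundance() |>
    single_mark_abundance()
  expect_true(all(ab$abundance >= 0 & ab$abundance <= 100 + 1e-9))
})

abund <- function(mark, normal, tumor) {
  tibble::tibble(
    mark = mark,
    sample = c(sprintf("n%d", seq_along(normal)),
               sprintf("t%d", seq_along(tumor))),
    condition = rep(c("normal", "tumor"), c(length(normal), length(tumor))),
    abundance = c(normal, tumor))
}

test_that("condition comparison: identical groups and zero-variance sentinels", {
  same <- compare_conditions(abund("m", c(5, 6, 7), c(5, 6, 7)))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_false(same$significant)

  expect_warning(
    flat <- compare_conditions(abund("m", c(1, 1, 1), c(2, 2, 2))),
    "zero variance")
  expect_equal(flat$fold_change, 2)
  expect_equal(flat$p_value, 0)

  const <- compare_conditions(abund("m", c(3, 3), c(3, 3)))
  expect_equal(const$p_value, 1)
})

test_that("p-values match the closed-form homoscedastic t formula", {
  set.seed(43)
  for (rep in 1:50) {
    a <- rnorm(3, 10, 2)
    b <- rnorm(3, 11, 2)
    got <- compare_conditions(abund("m", a, b))
    expect_equal(got$p_value, oracle_t_p(a, b), tolerance = 1e-10)
  }
})

test_that("BH adjustment flag drives the significance call", {
  set.seed(44)
  tabs <- dplyr::bind_rows(lapply(1:30, function(i) {
    abund(sprintf("m%02d", i), rnorm(3, 10), rnorm(3, 10 + (i <= 3) * 8))
  }))
  plain <- compare_conditions(tabs)
  bh <- compare_conditions(tabs, adjust = "BH")
  expect_true(all(bh$p_adjusted >= bh$p_value - 1e-12))
  expect_lte(sum(bh$significant), sum(plain$significant))
})

test_that("volcano table flags one-condition marks instead of infinities", {
  cmp <- compare_conditions(dplyr::bind_rows(
    abund("both", c(4, 5, 6), c(9, 10, 11)),
    abund("tumor_only", c(0, 0, 0), c(2, 3, 4))))
  v <- volcano_table(cmp)
  expect_equal(v$log2_fc[v$mark == "both"],
               log2(10 / 5))
  expect_true(v$one_condition[v$mark == "tumor_only"])
  expect_true(is.na(v$log2_fc[v$mark == "tumor_only"]))
  expect_true(all(is.finite(v$neg_log10_p)))

  null_cmp <- compare_conditions(abund("m", c(5, 6, 7), c(5, 6, 7)))
  vv <- volcano_table(null_cmp)
  expect_equal(vv$log2_fc, 0, tolerance = 1e-12)
  expect_equal(vv$neg_log10_p, 0, tolerance = 1e-12)
  expect_s3_class(plot_volcano(cmp), "ggplot")
})

test_that("planted differential marks are detected on simulated areas", {
  cfg <- sim_config(seed = 45)
  cmp <- simulate_peptidoform_areas(cfg) |>
    peptidoform_relative_abundance() |>
    single_mark_abundance() |>
    compare_conditions()
  boosted <- cmp[cmp$mark == "H4K8ac", ]
  expect_gt(boosted$fold_change, 1.5)
  expect_true(boosted$significant)
  reduced <- cmp[cmp$mark == "H3K36me3", ]
  expect_lt(reduced$fold_change, 1)
})
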