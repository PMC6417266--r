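test_that("rank_and_scale sorts ascending, scales axes, breaks ties by position", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 100L, 200L),
                            end = c(50L, 150L, 250L),
                            signal = c(5, 1, 3))
  tab <- rank_and_scale(regions)
  expect_equal(tab$signal, c(1, 3, 5))
  expect_equal(tab$scaled_signal, c(0.2, 0.6, 1.0))
  expect_equal(tab$scaled_rank, c(0, 0.5, 1))
  expect_equal(tab$rank, 0:2)

  tied <- tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                         start = c(0L, 500L, 10L),
                         end = c(9L, 509L, 19L),
                         signal = c(2, 2, 7))
  tt <- rank_and_scale(tied)
  expect_equal(tt$chrom[1:2], c("chr1", "chr2"))  # position tie-break
  expect_equal(tt$start[1:2], c(500L, 0L))

  expect_error(rank_and_scale(regions[1:2, ]), "3 regions")
  zero <- regions; zero$signal <- 0
  expect_error(rank_and_scale(zero), "zero")
})

test_that("inflection point: linear curve yields zero supers, spike yields one", {
  linear <- tibble::tibble(chrom = "chr1",
                           start = as.integer((0:4) * 100),
                           end = as.integer((0:4) * 100 + 50),
                           signal = 1:5)   # scaled_signal == scaled_rank
  tab <- find_inflection(rank_and_scale(linear))
  expect_equal(attr(tab, "cutoff_rank"), 4L)
  expect_equal(sum(tab$is_super), 0)

  spike <- linear
  spike$signal <- c(1, 1, 1, 1, 100)
  tab <- find_inflection(rank_and_scale(spike))
  expect_equal(attr(tab, "cutoff_rank"), 3L)
  expect_equal(sum(tab$is_super), 1)
})

test_that("inflection matches the exhaustive vertical-gap oracle (geometric curve)", {
  geo <- tibble::tibble(chrom = "chr1",
                        start = as.integer((0:9) * 1000),
                        end = as.integer((0:9) * 1000 + 100),
                        signal = 2^(0:9))
  tab <- find_inflection(rank_and_scale(geo))
  want <- oracle_curve_cutoff(geo$signal)
  expect_equal(attr(tab, "cutoff_rank"), want$cutoff_rank)
  expect_equal(sum(tab$is_super), want$n_super)
})

test_that("cutoff and labels are invariant to rescaling all signals", {
  set.seed(21)
  regions <- tibble::tibble(chrom = "chr1",
                            start = as.integer((0:49) * 1000),
                            end = as.integer((0:49) * 1000 + 100),
                            signal = rlnorm(50, 0, 1))
  base <- find_inflection(rank_and_scale(regions))
  for (k in c(0.001, 7, 1e6)) {
    scaled <- regions
    scaled$signal <- regions$signal * k
    got <- find_inflection(rank_and_scale(scaled))
    expect_equal(attr(got, "cutoff_rank"), attr(base, "cutoff_rank"))
    expect_equal(got$is_super, base$is_super)
  }
})

test_that("a top region above the linear interpolation forces >= 1 super", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    s <- sort(rlnorm(n, 0, 0.5))
    s[n] <- s[n] * (1 + runif(1, 0.2, 3))   # strictly convex at the top
    regions <- tibble::tibble(chrom = "chr1",
                              start = as.integer((seq_len(n) - 1) * 1000),
                              end = as.integer((seq_len(n) - 1) * 1000 + 10),
                              signal = s)
    tab <- find_inflection(rank_and_scale(regions))
    want <- oracle_curve_cutoff(s)
    expect_equal(sum(tab$is_super), want$n_super)
    if (want$cutoff_rank < n - 1) expect_gte(sum(tab$is_super), 1)
  }
})

test_that("the full caller recovers planted super-enhancers exactly", {
  ds <- simulate_enhancer_dataset(sim_config(
    seed = 101, n_typical_clusters = 20, n_super_clusters = 3,
    n_k4_clusters = 3, n_k4_typical_clusters = 5,
    k4_overlap_fraction = 1))
  se <- call_super_enhancers(ds$peaks$h3k27ac, ds$genes, ds$tracks$h3k27ac)
  sup <- tidy(se)[tidy(se)$is_super, ]
  planted <- ds$truth[ds$truth$class == "super", ]
  expect_equal(nrow(sup), 3)
  expect_setequal(paste(sup$chrom, sup$start, sup$end),
                  paste(planted$chrom, planted$start, planted$end))
})

test_that("caller error paths: nothing distal, zero signal after control", {
  genes <- toy_genes()
  promoter_peaks <- tibble::tibble(chrom = "chr1",
                                   start = c(900L, 59500L),
                                   end = c(1100L, 60400L))
  tr <- toy_track()
  expect_error(call_super_enhancers(promoter_peaks, genes, tr),
               "no enhancers")

  far <- tibble::tibble(chrom = "chr1",
                        start = c(100000L, 120000L, 140000L),
                        end = c(101000L, 121000L, 141000L))
  start <- far$start
  sig <- signal_track(tibble::tibble(chrom = "chr1", start = start,
                                     end = start + 1000L,
                                     value = c(1, 2, 3)))
  expect_error(
    call_super_enhancers(far, genes, sig, control_track = sig,
                         subtract_control = TRUE),
    "zero")
})

test_that("H3K4me3 variant ranks H3K27ac over H3K4me3-defined regions", {
  ds <- simulate_enhancer_dataset(sim_config(seed = 55))
  k4 <- call_h3k4me3_super_enhancers(ds$peaks$h3k4me3, ds$genes,
                                     ds$tracks$h3k27ac)
  sup <- tidy(k4)[tidy(k4)$is_super, ]
  # supers must be the planted high-H3K27ac K4 clusters, and the ones
  # co-located with conventional supers must be contained in that set
  planted_high <- ds$truth[ds$truth$has_k4 &
                             ds$truth$class %in% c("super", "k4_only"), ]
  hits <- enhancerscope:::overlaps_any(sup, planted_high)
  expect_true(all(hits))
  # all-promoter K4 peaks -> no enhancers
  prom <- ds$genes |>
    dplyr::transmute(chrom, start = pmax(tss - 200L, 0L), end = tss + 200L)
  expect_error(call_h3k4me3_super_enhancers(prom, ds$genes,
                                            ds$tracks$h3k27ac),
               "no enhancers")
})

test_that("enhancer-set comparison counts overlap classes", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 20000L, 40000L),
                            end = c(1000L, 21000L, 46000L),
                            signal = c(1, 3, 50))
  a <- find_inflection(rank_and_scale(regions))
  cmp_self <- compare_enhancer_sets(a, a)
  expect_equal(cmp_self$n[cmp_self$class == "a_only"], 0)
  expect_equal(cmp_self$n[cmp_self$class == "overlapping_a"], sum(a$is_super))

  b <- a
  b$chrom <- "chr9"
  cmp_disj <- compare_enhancer_sets(a, b)
  expect_equal(cmp_disj$n[cmp_disj$class == "overlapping_a"], 0)
  expect_equal(cmp_disj$n[cmp_disj$class == "a_only"], sum(a$is_super))

  # one-bp overlap counts with min_overlap = 1
  c_tab <- a
  c_tab$start <- c_tab$start + (c_tab$end - c_tab$start) - 1L
  c_tab$end <- c_tab$end + 500L
  cmp_touch <- compare_enhancer_sets(a, c_tab, min_overlap = 1)
  expect_equal(cmp_touch$n[cmp_touch$class == "overlapping_a"],
               sum(a$is_super))
})

test_that("tidy/glance/autoplot expose the call results", {
  ds <- simulate_enhancer_dataset(sim_config(seed = 77,
                                             n_typical_clusters = 10,
                                             n_super_clusters = 2,
                                             n_k4_clusters = 2,
                                             n_k4_typical_clusters = 3,
                                             n_genes = 40))
  se <- call_super_enhancers(ds$peaks$h3k27ac, ds$genes, ds$tracks$h3k27ac)
  td <- tidy(se)
  expect_s3_class(td, "tbl_df")
  expect_false("constituents" %in% names(td))
  g <- glance(se)
  expect_equal(g$n_super + g$n_typical, g$n_enhancers)
  expect_s3_class(autoplot(se), "ggplot")
})
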