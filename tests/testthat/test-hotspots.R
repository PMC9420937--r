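# Support counting, hotspot calling, the Monte-Carlo null, and summaries.

pos_set <- function(labels) {
  # map letters to distinct positions on one chromosome, plus strand
  tibble::tibble(chrom = "chr1",
                 pos = as.integer(match(labels, LETTERS) * 10L),
                 strand = "+")
}

test_that("build_support counts exact multiplicity over the union", {
  reps <- list(r1 = pos_set(c("A", "B")), r2 = pos_set(c("B", "C")),
               r3 = pos_set(c("B", "D")))
  sup <- build_support(reps)
  got <- setNames(sup$support, LETTERS[sup$pos / 10L])
  expect_equal(got[c("A", "B", "C", "D")],
               c(A = 1L, B = 3L, C = 1L, D = 1L))
  expect_equal(attr(sup, "n_replicas"), 3L)
  expect_equal(sum(sup$support), sum(attr(sup, "totals")$t_i))

  # identical replicas -> all supports = n; disjoint -> all 1
  same <- build_support(list(a = pos_set(c("A", "B")),
                             b = pos_set(c("A", "B"))))
  expect_true(all(same$support == 2L))
  disj <- build_support(list(a = pos_set("A"), b = pos_set("B")))
  expect_true(all(disj$support == 1L))

  # brute-force multiset oracle on random replicas
  set.seed(5)
  for (i in 1:10) {
    reps <- lapply(1:4, function(r) {
      k <- sample(1:30, 1)
      tibble::tibble(chrom = "c", pos = sample(1:50, k), strand = "+")
    })
    names(reps) <- paste0("r", 1:4)
    sup <- build_support(reps)
    oracle <- table(unlist(lapply(reps, function(x) x$pos)))
    expect_equal(setNames(sup$support, sup$pos)[names(oracle)],
                 setNames(as.integer(oracle), names(oracle)))
  }
})

test_that("call_hotspots thresholds correctly and nests across k", {
  sup <- build_support(list(r1 = pos_set(c("A", "B")), r2 = pos_set(c("B", "C")),
                            r3 = pos_set(c("B", "D"))))
  hs <- call_hotspots(sup, 2)
  expect_equal(hs$pos, 20L)  # only B
  expect_error(call_hotspots(sup, 1), ">= 2")

  # nesting + monotone fractions on a generated support map
  set.seed(11)
  reps <- lapply(1:5, function(r) tibble::tibble(
    chrom = "c", pos = sample(1:200, 80), strand = "+"))
  names(reps) <- paste0("r", 1:5)
  sup <- build_support(reps)
  prev <- call_hotspots(sup, 2)
  prev_frac <- hotspot_fraction(sup, 2)
  for (k in 3:5) {
    cur <- call_hotspots(sup, k)
    expect_true(all(cur$pos %in% prev$pos))
    frac <- hotspot_fraction(sup, k)
    expect_lte(frac, prev_frac)
    prev <- cur
    prev_frac <- frac
  }
})

test_that("hotspot_fraction works on positions and on aggregated histograms", {
  sup <- build_support(list(r1 = pos_set(c("A", "B")),
                            r2 = pos_set(c("A", "B"))))
  expect_equal(hotspot_fraction(sup, 2), 1.0)
  disj <- build_support(list(r1 = pos_set("A"), r2 = pos_set("B")))
  expect_equal(hotspot_fraction(disj, 2), 0.0)

  hist <- tibble::tibble(support = c(1L, 2L), n = c(70L, 30L))
  expect_equal(hotspot_fraction(hist, 2), 0.3)
  expect_error(hotspot_fraction(tibble::tibble(support = integer(),
                                               n = integer())), "empty")
})

test_that("simulate_null matches saturation, sparse, and enumeration limits", {
  sat <- simulate_null(2, c(4, 4), space_size = 4, n_sim = 10, seed = 1)
  expect_true(all(sat$fractions == 1))

  sparse <- simulate_null(2, c(1, 1), space_size = 1e6, n_sim = 50, seed = 2)
  expect_lt(mean(sparse$fractions), 0.001)

  # exhaustive enumeration oracle: 2 replicas, b = 2 draws from S = 4
  combs <- utils::combn(4, 2, simplify = FALSE)
  fr <- c()
  for (a in combs) for (b in combs) {
    shared <- length(intersect(a, b))
    fr <- c(fr, shared / length(union(a, b)))
  }
  exact_mean <- mean(fr)
  null <- simulate_null(2, c(2, 2), space_size = 4, n_sim = 400, seed = 3)
  mc_se <- stats::sd(null$fractions) / sqrt(null$n_sim)
  expect_lt(abs(mean(null$fractions) - exact_mean), 3 * mc_se)

  # determinism
  again <- simulate_null(2, c(2, 2), space_size = 4, n_sim = 400, seed = 3)
  expect_identical(null$fractions, again$fractions)
  expect_error(simulate_null(2, c(5, 5), space_size = 4), "exceeds")
})

test_that("hotspot_significance behaves at the centre, far tail, and degenerate null", {
  null <- simulate_null(2, c(40, 40), space_size = 200, n_sim = 100, seed = 9)
  centre <- hotspot_significance(mean(null$fractions), null)
  expect_gt(centre$p_value, 0.9)

  far <- hotspot_significance(0.9, null)
  expect_lt(far$p_value, 1e-10)
  # t statistic recomputed from the simulated sample
  t_manual <- (mean(null$fractions) - 0.9) /
    (stats::sd(null$fractions) / sqrt(null$n_sim))
  expect_equal(far$statistic, t_manual, tolerance = 1e-12)

  const <- structure(list(fractions = rep(0.1, 10), n_sim = 10,
                          space_size = 100, min_support = 2, seed = NULL),
                     class = "null_distribution")
  expect_equal(hotspot_significance(0.1, const)$p_value, 1)
  expect_equal(hotspot_significance(0.2, const)$p_value, 0)
  expect_true(hotspot_significance(0.2, const)$degenerate)

  expect_s3_class(tidy(null), "tbl_df")
  expect_equal(nrow(tidy(null)), 100)
  expect_equal(glance(far)$p_value, far$p_value)
})

test_that("overlap_odds_ratio matches direct arithmetic and set semantics", {
  r <- overlap_odds_ratio(100, 100, universe_size = 1e4, overlap = 1)
  expect_equal(r$odds_ratio, 1.0)

  # counts from a published hotspot-sharing comparison; OR is pure arithmetic
  r2 <- overlap_odds_ratio(150052, 337664, universe_size = 1.6e9,
                           overlap = 1180)
  expect_equal(r2$odds_ratio, 1180 / (150052 * 337664 / 1.6e9),
               tolerance = 1e-12)

  a <- pos_set(c("A", "B", "C"))
  b <- pos_set(c("D", "E"))
  expect_equal(overlap_odds_ratio(a, b, 1000)$odds_ratio, 0)
  b2 <- pos_set(c("B", "C", "D"))
  expect_equal(overlap_odds_ratio(a, b2, 1000)$overlap, 2L)
})

test_that("per-gene hotspot count summary reproduces printed-style percentages", {
  counts <- rep(c(1L, 2L, 3L, 6L), c(1510L, 399L, 195L, 43L))  # 2147 genes
  tab <- summarize_hotspot_gene_counts(counts)
  expect_equal(tab$percent[tab$class == "1"], 70.3)
  expect_equal(tab$percent[tab$class == "2"], 18.6)
  expect_equal(sum(tab$n_genes), 2147L)

  all_one <- summarize_hotspot_gene_counts(rep(1L, 10))
  expect_equal(all_one$percent[all_one$class == "1"], 100.0)
  expect_error(summarize_hotspot_gene_counts(c(0L, 1L)), ">= 1")
})
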