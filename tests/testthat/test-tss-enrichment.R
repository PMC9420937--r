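# Nearest-TSS distances, binned density normalisation, enrichment ratios.

one_gene_tss <- function(strand = "+", tss = 5000L, chrom = "chr1") {
  tibble::tibble(gene_id = "g1", chrom = chrom, strand = strand,
                 annotated_tss = tss, tss = tss, peak_depth = 5L)
}

test_that("nearest_tss_distance signs distances by gene orientation", {
  tss <- one_gene_tss("+")
  at <- nearest_tss_distance(toy_positions("chr1", 5000), tss)
  expect_equal(at$distance, 0)

  up <- nearest_tss_distance(toy_positions("chr1", 4900), tss)
  expect_equal(up$distance, -100)
  down_m <- nearest_tss_distance(toy_positions("chr1", 4900),
                                 one_gene_tss("-"))
  expect_equal(down_m$distance, 100)

  # absolute-shortest wins
  two <- dplyr::bind_rows(one_gene_tss(tss = 1000L),
                          dplyr::mutate(one_gene_tss(tss = 1550L),
                                        gene_id = "g2"))
  near <- nearest_tss_distance(toy_positions("chr1", 1300), two)
  expect_equal(abs(near$distance), 250)  # |d| = 300 to g1, 250 to g2
  expect_equal(near$gene_id, "g2")

  none <- nearest_tss_distance(toy_positions("chr2", 10), tss)
  expect_true(is.na(none$distance))
})

test_that("bin grid computes NR_j from per-gene non-repeat fractions", {
  # clean genome: every bin fully non-repeat
  gm <- genome_model(c(chr1 = 20000))
  grid <- build_bin_grid(one_gene_tss(tss = 10000L), gm)
  expect_equal(nrow(grid), 500L)
  expect_true(all(grid$nr == 1))
  expect_equal(grid$offset_end - grid$offset_start, rep(20L, 500))
  expect_equal(grid$offset_start[1], -5000L)
  expect_equal(grid$offset_end[500], 5000L)

  # repeat covering exactly half of one bin: offsets [0,10) of the TSS bin
  gm2 <- genome_model(c(chr1 = 20000),
                      repeats = data.frame(chrom = "chr1", start = 10000,
                                           end = 10010))
  grid2 <- build_bin_grid(one_gene_tss(tss = 10000L), gm2)
  tss_bin <- which(grid2$offset_start == 0)
  expect_equal(grid2$nr[tss_bin], 0.5)
  expect_true(all(grid2$nr[-tss_bin] == 1))

  # two genes, one fully masked window, one clean -> NR_j = 0.5 everywhere
  gm3 <- genome_model(c(chr1 = 40000),
                      repeats = data.frame(chrom = "chr1", start = 25000,
                                           end = 35001))
  two <- dplyr::bind_rows(one_gene_tss(tss = 10000L),
                          dplyr::mutate(one_gene_tss(tss = 30000L),
                                        gene_id = "g2"))
  grid3 <- build_bin_grid(two, gm3)
  expect_true(all(abs(grid3$nr - 0.5) < 1e-12))

  # minus-strand gene: orientation reverses the masked bin. On the plus
  # gene, masked bases 10100..10119 are offsets 100..119 (one full bin); on
  # the minus gene offset o maps to base tss - o, so the fully masked bin is
  # the one covering offsets -101..-120, i.e. bases 10101..10120.
  gm4 <- genome_model(c(chr1 = 20000),
                      repeats = data.frame(chrom = "chr1", start = 10100,
                                           end = 10120))
  grid_p <- build_bin_grid(one_gene_tss("+", 10000L), gm4)
  expect_equal(grid_p$nr[grid_p$offset_start == 100], 0)
  gm5 <- genome_model(c(chr1 = 20000),
                      repeats = data.frame(chrom = "chr1", start = 10101,
                                           end = 10121))
  grid_m <- build_bin_grid(one_gene_tss("-", 10000L), gm5)
  expect_equal(grid_m$nr[grid_m$offset_start == -120], 0)
})

test_that("density profile applies the per-million, NR-corrected formula", {
  gm <- genome_model(c(chr1 = 20000))
  tss <- one_gene_tss(tss = 10000L)
  grid <- build_bin_grid(tss, gm)

  # one position in one bin, NR = 1, T = 10 -> D = 1e6 / 10 / 1 = 1e5
  prof <- density_profile(toy_positions("chr1", 10005), tss, grid, total = 10)
  hit <- prof[prof$n > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$density, 1e5)
  expect_equal(hit$strand_class, "non_template")

  # doubling T halves every density
  prof2 <- density_profile(toy_positions("chr1", 10005), tss, grid, total = 20)
  expect_equal(prof2$density[prof2$n > 0], 5e4)

  # no positions in the window -> all zero densities
  empty <- density_profile(toy_positions("chr1", 19000), tss, grid, total = 5)
  expect_true(all(empty$density == 0))

  # recomputation identity on a generated study
  st <- get_study("default")
  grid_s <- build_bin_grid(st$tss, st$genome)
  prof_s <- density_profile(st$pooled, st$tss, grid_s,
                            sample_id = "all_breaks")
  ok <- !is.na(prof_s$density)
  expect_equal(prof_s$density[ok],
               prof_s$n[ok] * 1e6 / (prof_s$nr[ok] * prof_s$total[ok]))
  d <- nearest_tss_distance(st$pooled, st$tss)
  in_window <- sum(!is.na(d$distance) & d$distance >= -5000 & d$distance < 5000)
  expect_equal(sum(prof_s$n), in_window)
})

test_that("enrichment ratio matches window arithmetic and the binomial test", {
  # single clean gene: L200 = 401, L5000 = 10001
  gm <- genome_model(c(chr1 = 20000))
  tss <- one_gene_tss(tss = 10000L)
  breaks <- toy_positions("chr1", c(seq(9901, 10100), seq(12000, 14999)))
  res <- enrichment_ratio(breaks, tss, gm, by_strand = FALSE)
  expect_equal(res$m_inner, 200L)
  expect_equal(res$m_outer, 3200L)
  expect_equal(res$l_inner, 401)
  expect_equal(res$l_outer, 10001)
  expect_equal(res$ratio, (200 / 3200) / (401 / 10001))
  expect_equal(res$p_value,
               stats::binom.test(200, 3200, 401 / 10001)$p.value)

  # recomputation identity + strand-flip symmetry on a generated study
  st <- get_study("default")
  enr <- enrichment_ratio(st$pooled, st$tss, st$genome)
  expect_equal(enr$ratio,
               (enr$m_inner / enr$m_outer) / (enr$l_inner / enr$l_outer))
  flip <- function(s) ifelse(s == "+", "-", "+")
  enr_f <- enrichment_ratio(
    dplyr::mutate(st$pooled, strand = flip(strand)),
    dplyr::mutate(st$tss, strand = flip(strand)), st$genome)
  expect_equal(enr_f$ratio, enr$ratio)
  expect_equal(enr_f$m_inner, enr$m_inner)

  # monotonicity: adding inner-window breaks never decreases R
  more <- dplyr::bind_rows(breaks, toy_positions("chr1", 9950:9999, "-"))
  res2 <- enrichment_ratio(more, tss, gm, by_strand = FALSE)
  expect_gte(res2$ratio, res$ratio)
})

test_that("per-gene and union L modes agree when gene windows are sparse", {
  gm <- genome_model(c(chr1 = 1e5))
  far <- dplyr::bind_rows(one_gene_tss(tss = 20000L),
                          dplyr::mutate(one_gene_tss(tss = 70000L),
                                        gene_id = "g2"))
  b <- toy_positions("chr1", c(19900, 20100, 22000, 69950, 71000))
  near_mode <- enrichment_ratio(b, far, gm, by_strand = FALSE)
  per_gene <- enrichment_ratio(b, far, gm, by_strand = FALSE,
                               l_mode = "per_gene")
  expect_equal(near_mode$ratio, per_gene$ratio)
  expect_equal(per_gene$l_outer, 2 * 10001)
})

test_that("treatment-group ratio comparison uses a two-sided Welch test", {
  same <- tibble::tibble(treatment = rep(c("dmso", "drugA"), each = 3),
                         ratio = rep(c(2, 2.5, 3), 2))
  cmp <- compare_ratio_groups(same, reference = "dmso")
  expect_equal(cmp$p_value, 1)

  shifted <- tibble::tibble(
    treatment = rep(c("dmso", "drugA"), each = 4),
    ratio = c(2.0, 2.1, 1.9, 2.0, 4.0, 4.1, 3.9, 4.0))
  cmp2 <- compare_ratio_groups(shifted, reference = "dmso")
  expect_lt(cmp2$p_value, 0.01)
  tt <- stats::t.test(shifted$ratio[5:8], shifted$ratio[1:4])
  expect_equal(cmp2$statistic, unname(tt$statistic))

  three <- tibble::tibble(
    treatment = rep(c("dmso", "a", "b", "c"), each = 2),
    ratio = c(1, 1.2, 1.1, 1.3, 2, 2.2, 0.5, 0.6))
  expect_equal(nrow(compare_ratio_groups(three, "dmso")), 3L)
  expect_error(compare_ratio_groups(
    tibble::tibble(treatment = c("dmso", "dmso", "a"), ratio = c(1, 2, 3)),
    "dmso"), ">= 2")
})
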