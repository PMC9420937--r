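# Genome model, interval algebra, and BED/TSV round-trips.

test_that("interval merging has coverage semantics, including book-ended pairs", {
  merged <- merge_intervals(tibble::tibble(
    chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L)))
  expect_equal(merged$start, 10L)
  expect_equal(merged$end, 30L)

  booked <- merge_intervals(tibble::tibble(
    chrom = "chr1", start = c(10L, 20L), end = c(20L, 30L)))
  expect_equal(nrow(booked), 1L)

  # bitmap oracle on random interval sets
  set.seed(101)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    s <- sample(0:80, n, replace = TRUE)
    raw <- tibble::tibble(chrom = "c", start = s,
                          end = s + sample(1:15, n, replace = TRUE))
    merged <- merge_intervals(raw)
    expect_equal(coverage_bitmap(merged, "c", 120),
                 coverage_bitmap(raw, "c", 120))
    # merged output is disjoint and sorted with gaps
    if (nrow(merged) > 1) {
      expect_true(all(merged$start[-1] > merged$end[-nrow(merged)]))
    }
  }

  expect_error(merge_intervals(tibble::tibble(chrom = "c", start = 5, end = 5)),
               "start")
})

test_that("genome model merges repeats, bounds-checks, and computes LG", {
  gm <- toy_genome(with_sequence = FALSE)
  expect_equal(gm$lg, 1600 - 150)
  expect_equal(genome_lg(gm), gm$lg)

  expect_error(genome_model(c(chr1 = 100),
                            repeats = data.frame(chrom = "chr1", start = 50,
                                                 end = 150)),
               "bounds")
  expect_error(genome_model(c(chr1 = 100),
                            repeats = data.frame(chrom = "chrX", start = 0,
                                                 end = 10)),
               "unknown")

  # LG recomputation invariant over random models
  set.seed(7)
  for (i in 1:10) {
    len <- sample(500:2000, 1)
    n <- sample(0:10, 1)
    reps <- if (n > 0) {
      s <- sample(0:(len - 20), n, replace = TRUE)
      tibble::tibble(chrom = "c", start = s, end = s + sample(1:20, n, TRUE))
    } else NULL
    gm <- genome_model(c(c = len), repeats = reps)
    expect_equal(gm$lg, sum(!coverage_bitmap(gm$repeats, "c", len)))
    expect_equal(genome_lg(gm), gm$lg)
  }
})

test_that("complement_intervals returns exactly the uncovered bases", {
  gm <- toy_genome(with_sequence = FALSE)
  comp <- complement_intervals(gm$repeats, gm$chromosomes)
  expect_equal(coverage_bitmap(comp, "chr1", 1000),
               !coverage_bitmap(gm$repeats, "chr1", 1000))
  expect_equal(sum(coverage_bitmap(comp, "chr2", 600)), 600)
})

test_that("read_breaks deduplicates, keeps strand identity, and validates", {
  gm <- toy_genome(with_sequence = FALSE)
  p <- withr::local_tempfile(fileext = ".bed")

  write_bed6(p, c("chr1", "chr1"), c(100L, 100L), c("+", "+"))
  expect_equal(nrow(read_breaks(p, gm)), 1L)

  write_bed6(p, c("chr1", "chr1"), c(100L, 100L), c("+", "-"))
  expect_equal(nrow(read_breaks(p, gm)), 2L)

  write_bed6(p, "chr9", 5L, "+")
  expect_error(read_breaks(p, gm), "chr9")

  writeLines("chr1\t10\t12\tx\t0\t+", p)
  expect_error(read_breaks(p, gm), "single-base")

  writeLines("chr1\tten\t11\tx\t0\t+", p)
  expect_error(read_breaks(p, gm), "line 1")

  writeLines(c("chr1\t10\t11\tx\t0\t+", "chr1\t20"), p)
  expect_error(read_breaks(p, gm), "line 2")
})

test_that("filter_repeats uses half-open per-base containment and is idempotent", {
  gm <- genome_model(c(chr1 = 500),
                     repeats = data.frame(chrom = "chr1", start = 100, end = 200))
  b <- toy_positions("chr1", c(99, 100, 199, 200))
  kept <- filter_repeats(b, gm)
  expect_equal(kept$pos, c(99L, 200L))
  expect_equal(filter_repeats(kept, gm), kept)

  expect_equal(filter_repeats(b, genome_model(c(chr1 = 500))), b)
  all_in <- toy_positions("chr1", 100:199)
  expect_equal(nrow(filter_repeats(all_in, gm)), 0L)
})

test_that("read_intervals merges and rejects malformed records", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t20\t30", "chr1\t15\t25"), p)
  out <- read_intervals(p)
  expect_equal(out, tibble::tibble(chrom = "chr1", start = 10L, end = 30L))

  writeLines("chr1\t30\t20", p)
  expect_error(read_intervals(p), "start must be < end")

  writeLines(character(0), p)
  expect_equal(nrow(read_intervals(p)), 0L)
})

test_that("write_positions round-trips breaks and carries hotspot support", {
  gm <- toy_genome(with_sequence = FALSE)
  p <- withr::local_tempfile(fileext = ".bed")

  b <- toy_positions(c("chr1", "chr1", "chr2"), c(5, 900, 10), c("+", "-", "+"))
  write_positions(b, p)
  back <- read_breaks(p, gm)
  expect_equal(back[c("chrom", "pos", "strand")],
               b[c("chrom", "pos", "strand")])

  hs <- tibble::tibble(chrom = "chr1", pos = 42L, strand = "+", support = 4L)
  write_positions(hs, p)
  fields <- strsplit(readLines(p)[2], "\t")[[1]]
  expect_equal(fields[4], "hotspot")
  expect_equal(fields[5], "4")

  write_positions(b[0, ], p)
  lines <- readLines(p)
  expect_length(lines, 1)
  expect_match(lines, "^#")
  expect_equal(nrow(read_breaks(p, gm)), 0L)
})

test_that("CAGE, gene, and expression readers validate their tables", {
  gm <- toy_genome(with_sequence = FALSE)
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t11\ttag\t3\t+", "chr1\t10\t11\ttag\t-1\t-"), p)
  expect_error(read_cage(p, gm), "negative")
  writeLines("chr1\t10\t11\ttag\t3\t+", p)
  tags <- read_cage(p, gm)
  expect_equal(tags$depth, 3L)

  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                                  tss = 10L, tts = 200L,
                                  exon_starts = "10,100",
                                  exon_ends = "50,201"), tf)
  g <- read_genes(tf, gm)
  expect_equal(nrow(g), 1L)
  readr::write_tsv(tibble::tibble(gene_id = "g1", chrom = "chr1"), tf)
  expect_error(read_genes(tf), "missing")

  readr::write_tsv(tibble::tibble(gene_id = c("a", "b"),
                                  fpkm_r1 = c(1, 4), fpkm_r2 = c(3, 6)), tf)
  e <- read_expression(tf)
  expect_equal(e$expression, c(2, 5))
})
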