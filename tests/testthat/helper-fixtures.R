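# Shared fixtures, all built in code.

# Tiny deterministic genome: two chromosomes with hand-placed repeats and a
# fixed sequence (chr1 period-4 ACGT; chr2 all G on the plus strand).
toy_genome <- function(len1 = 1000, len2 = 600, with_sequence = TRUE) {
  seqs <- NULL
  if (with_sequence) {
    seqs <- c(
      chr1 = paste(rep(c("A", "C", "G", "T"), length.out = len1), collapse = ""),
      chr2 = paste(rep("G", len2), collapse = "")
    )
  }
  genome_model(
    tibble::tibble(chrom = c("chr1", "chr2"), length = c(len1, len2)),
    repeats = tibble::tibble(chrom = c("chr1", "chr1"),
                             start = c(100L, 400L), end = c(200L, 450L)),
    sequence = seqs
  )
}

toy_positions <- function(chrom, pos, strand = "+", replica = "r1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 strand = rep_len(strand, length(pos)),
                 replica = rep_len(replica, length(pos)))
}

# Write a BED6 file of single-base break records.
write_bed6 <- function(path, chrom, start, strand, name = "r1", score = 0) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", chrom, start, start + 1L,
                   rep_len(name, length(start)), rep_len(score, length(start)),
                   rep_len(strand, length(start)))
  writeLines(lines, path)
  path
}

# Brute-force membership oracle: base-level coverage bitmap of an interval set.
coverage_bitmap <- function(intervals, chrom, len) {
  v <- rep(FALSE, len)
  sub <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$end[i] > sub$start[i]) {
      v[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
  }
  v
}
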