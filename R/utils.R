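# Internal interval and position helpers.
#
# All coordinates in the package are 0-based half-open (BED native): an
# interval [start, end) covers bases start .. end-1, and a single-nucleotide
# break at base N has pos = N. IRanges (1-based closed) is used behind the
# scenes for merging, overlap queries and coverage.

.as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

.check_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame", arg))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf("`%s` row %d: start (%s) must be < end (%s)",
                  arg, bad, x$start[bad], x$end[bad]))
  }
  invisible(x)
}

.check_positions <- function(x, arg = "positions") {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame", arg))
  need <- c("chrom", "pos", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  bad <- !x$strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("`%s` row %d: strand must be '+' or '-'", arg, which(bad)[1]))
  }
  invisible(x)
}

#' Merge genomic intervals
#'
#' Sorts and merges a set of 0-based half-open intervals per chromosome.
#' Overlapping and book-ended intervals (`[10,20)` + `[20,30)`) are merged,
#' giving coverage semantics: the merged set covers a base iff some input
#' interval covered it.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A tibble `chrom`, `start`, `end` of disjoint sorted intervals.
#' @export
merge_intervals <- function(intervals) {
  .check_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- split(intervals, intervals$chrom)
  out <- lapply(names(parts), function(ch) {
    r <- IRanges::reduce(.as_iranges(parts[[ch]]$start, parts[[ch]]$end))
    tibble(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

# Total base count covered by a merged interval set.
.interval_length <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  sum(as.numeric(intervals$end) - as.numeric(intervals$start))
}

#' Complement of an interval set within chromosome bounds
#'
#' @param intervals Merged intervals (`chrom`, `start`, `end`).
#' @param chromosomes Data frame with `chrom`, `length`.
#' @return Tibble of intervals covering every base not covered by `intervals`.
#' @export
complement_intervals <- function(intervals, chromosomes) {
  .check_intervals(intervals)
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    ch <- chromosomes$chrom[i]
    len <- chromosomes$length[i]
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble(chrom = ch, start = 0L, end = as.integer(len)))
    }
    r <- IRanges::reduce(.as_iranges(sub$start, sub$end))
    gaps <- IRanges::gaps(r, start = 1L, end = as.integer(len))
    tibble(chrom = ch, start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
  })
  out <- bind_rows(out)
  out[out$end > out$start, , drop = FALSE]
}

# Logical: is each position's base covered by the interval set?
.pos_in_intervals <- function(positions, intervals) {
  if (nrow(positions) == 0) return(logical(0))
  hit <- logical(nrow(positions))
  if (nrow(intervals) == 0) return(hit)
  for (ch in unique(positions$chrom)) {
    idx <- which(positions$chrom == ch)
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    q <- .as_iranges(positions$pos[idx], positions$pos[idx] + 1L)
    s <- .as_iranges(sub$start, sub$end)
    hit[idx] <- IRanges::overlapsAny(q, s)
  }
  hit
}

# Per-query non-repeat base count: for each query interval (clipped to its
# chromosome), the number of covered bases NOT covered by `repeats`.
.nonrepeat_widths <- function(queries, genome) {
  n <- nrow(queries)
  out <- numeric(n)
  chrlen <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  nonrep <- complement_intervals(genome$repeats, genome$chromosomes)
  for (ch in unique(queries$chrom)) {
    idx <- which(queries$chrom == ch)
    len <- chrlen[[ch]]
    s <- pmax(queries$start[idx], 0L)
    e <- pmin(queries$end[idx], len)
    keep <- e > s
    sub <- nonrep[nonrep$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0 || !any(keep)) next
    q <- .as_iranges(s[keep], e[keep])
    subj <- .as_iranges(sub$start, sub$end)
    hits <- IRanges::findOverlaps(q, subj)
    if (length(hits) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], subj[S4Vectors::subjectHits(hits)]
    ))
    acc <- tapply(w, S4Vectors::queryHits(hits), sum)
    tmp <- numeric(sum(keep))
    tmp[as.integer(names(acc))] <- as.numeric(acc)
    out[idx[keep]] <- tmp
  }
  out
}

# Key uniquely identifying a stranded position.
.pos_key <- function(x) paste(x$chrom, x$pos, x$strand, sep = ":")
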