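# Readers and writers for the plain-text formats the pipeline touches.
# Breaks and CAGE tags are BED6; repeat and promoter tracks BED3+; gene
# annotation and expression are TSV with a header. All files are read into
# tibbles with 0-based half-open coordinates.

.read_bed_fields <- function(path, min_fields) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- which(nf < min_fields)[1]
    abort(sprintf("%s line %d: expected >= %d tab-separated fields, found %d",
                  path, lineno[bad], min_fields, nf[bad]))
  }
  list(fields = fields, lineno = lineno)
}

.bed_int <- function(values, path, lineno, what) {
  suppressWarnings(out <- as.integer(values))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(sprintf("%s line %d: %s '%s' is not an integer",
                  path, lineno[bad], what, values[bad]))
  }
  out
}

.check_chroms <- function(chrom, genome, path, lineno) {
  if (is.null(genome)) return(invisible())
  unknown <- !chrom %in% genome$chromosomes$chrom
  if (any(unknown)) {
    bad <- which(unknown)[1]
    abort(sprintf("%s line %d: chromosome '%s' absent from genome",
                  path, lineno[bad], chrom[bad]))
  }
  invisible()
}

#' Read single-nucleotide break positions from BED6
#'
#' Each record must be a single-base interval (`end == start + 1`) with a
#' strand; the break sits between that base and the next base toward the
#' strand's 3' end. Duplicate (chromosome, position, strand) records are
#' collapsed: every analysis in the package works on unique positions,
#' irrespective of how many reads supported a break.
#'
#' @param path BED6 file.
#' @param genome A [genome_model()]; records on chromosomes absent from it are
#'   rejected.
#' @param replica_id Optional replica label; defaults to the BED name column
#'   (or the file name if the name column is ".").
#' @return Tibble with columns `chrom`, `pos` (0-based), `strand`, `replica`.
#' @export
read_breaks <- function(path, genome, replica_id = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  parsed <- .read_bed_fields(path, 6L)
  f <- parsed$fields
  ln <- parsed$lineno
  if (length(f) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  replica = character()))
  }
  chrom <- vapply(f, `[[`, "", 1L)
  start <- .bed_int(vapply(f, `[[`, "", 2L), path, ln, "start")
  end <- .bed_int(vapply(f, `[[`, "", 3L), path, ln, "end")
  name <- vapply(f, `[[`, "", 4L)
  strand <- vapply(f, `[[`, "", 6L)
  if (any(end != start + 1L)) {
    bad <- which(end != start + 1L)[1]
    abort(sprintf("%s line %d: break records must be single-base (end = start + 1)",
                  path, ln[bad]))
  }
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    abort(sprintf("%s line %d: strand must be '+' or '-'", path, ln[bad]))
  }
  .check_chroms(chrom, genome, path, ln)
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  oob <- start < 0L | start >= lens[chrom]
  if (any(oob)) {
    bad <- which(oob)[1]
    abort(sprintf("%s line %d: position %d outside chromosome %s",
                  path, ln[bad], start[bad], chrom[bad]))
  }
  if (is.null(replica_id)) {
    replica_id <- if (all(name == ".") || all(name == "")) {
      sub("\\.bed$", "", basename(path))
    } else NA_character_
  }
  out <- tibble(
    chrom = chrom, pos = start, strand = strand,
    replica = if (is.na(replica_id %||% NA_character_)) name else replica_id
  )
  distinct(out, .data$chrom, .data$pos, .data$strand, .keep_all = TRUE)
}

#' Drop break positions falling in repeat regions
#'
#' A position overlaps a repeat iff its single assigned base lies inside a
#' repeat interval. Idempotent; the input is not modified.
#'
#' @param breaks Position tibble (`chrom`, `pos`, `strand`).
#' @param genome A [genome_model()] carrying merged repeat intervals.
#' @return The subset of `breaks` outside all repeats.
#' @export
filter_repeats <- function(breaks, genome) {
  .check_positions(breaks, "breaks")
  stopifnot(inherits(genome, "genome_model"))
  breaks[!.pos_in_intervals(breaks, genome$repeats), , drop = FALSE]
}

#' Read an interval track (BED3+) as merged intervals
#'
#' @param path BED file with at least chrom/start/end.
#' @param genome Optional [genome_model()] for chromosome validation.
#' @return Merged interval tibble (`chrom`, `start`, `end`).
#' @export
read_intervals <- function(path, genome = NULL) {
  parsed <- .read_bed_fields(path, 3L)
  f <- parsed$fields
  ln <- parsed$lineno
  if (length(f) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  chrom <- vapply(f, `[[`, "", 1L)
  start <- .bed_int(vapply(f, `[[`, "", 2L), path, ln, "start")
  end <- .bed_int(vapply(f, `[[`, "", 3L), path, ln, "end")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    abort(sprintf("%s line %d: start must be < end", path, ln[bad]))
  }
  .check_chroms(chrom, genome, path, ln)
  merge_intervals(tibble(chrom = chrom, start = start, end = end))
}

#' Write break or hotspot positions as BED6
#'
#' The name column holds the replica label (or "hotspot" when a `support`
#' column is present); the score column holds the replica-support count for
#' hotspots, 0 otherwise. Round-trips through [read_breaks()] losslessly.
#'
#' @param positions Tibble with `chrom`, `pos`, `strand`, and optionally
#'   `replica` and/or `support`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  .check_positions(positions, "positions")
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(positions) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  name <- if ("support" %in% names(positions)) {
    "hotspot"
  } else if ("replica" %in% names(positions)) {
    positions$replica
  } else "break"
  score <- if ("support" %in% names(positions)) positions$support else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   positions$chrom, positions$pos, positions$pos + 1L,
                   name, score, positions$strand)
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Write an interval set as BED3
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  .check_intervals(intervals)
  lines <- sprintf("%s\t%d\t%d", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read CAGE tags from BED6 (depth in the score column)
#'
#' @param path BED6 file; `pos` is the 0-based 5' position of the capped
#'   transcript, score the supporting read count.
#' @param genome Optional [genome_model()] for validation.
#' @return Tibble `chrom`, `pos`, `strand`, `depth`.
#' @export
read_cage <- function(path, genome = NULL) {
  parsed <- .read_bed_fields(path, 6L)
  f <- parsed$fields
  ln <- parsed$lineno
  if (length(f) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  depth = integer()))
  }
  chrom <- vapply(f, `[[`, "", 1L)
  start <- .bed_int(vapply(f, `[[`, "", 2L), path, ln, "start")
  depth <- .bed_int(vapply(f, `[[`, "", 5L), path, ln, "score")
  strand <- vapply(f, `[[`, "", 6L)
  if (any(depth < 0)) {
    bad <- which(depth < 0)[1]
    abort(sprintf("%s line %d: negative CAGE depth", path, ln[bad]))
  }
  .check_chroms(chrom, genome, path, ln)
  tibble(chrom = chrom, pos = start, strand = strand, depth = depth)
}

#' Read gene annotation from TSV
#'
#' Expects a header with columns `gene_id`, `chrom`, `strand`, `tss`, `tts`,
#' `exon_starts`, `exon_ends` — the longest-transcript structure of each
#' gene. `tss`/`tts` are 0-based coordinates of the transcription start and
#' termination bases; exon columns are comma-separated 0-based half-open
#' boundaries.
#'
#' @param path TSV file.
#' @param genome Optional [genome_model()] for validation.
#' @return Tibble, one row per gene.
#' @export
read_genes <- function(path, genome = NULL) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tts", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing gene column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(g$chrom), genome$chromosomes$chrom)
    if (length(unknown) > 0) {
      abort(sprintf("%s: unknown chromosome(s): %s", path,
                    paste(unknown, collapse = ", ")))
    }
  }
  as_tibble(g)
}

#' Read a per-gene expression table
#'
#' Expects `gene_id` plus one or more numeric replicate columns; the returned
#' `expression` is their row mean (FPKM-like).
#'
#' @param path TSV file with a header.
#' @return Tibble `gene_id`, `expression`, plus the replicate columns.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(x)) abort(sprintf("%s: missing `gene_id`", path))
  num <- names(x)[vapply(x, is.numeric, TRUE)]
  if (length(num) == 0) abort(sprintf("%s: no numeric expression columns", path))
  x$expression <- rowMeans(x[num])
  as_tibble(x)
}

# Exon tibble (gene_id, chrom, start, end) from comma-separated columns.
.gene_exons <- function(genes) {
  starts <- strsplit(as.character(genes$exon_starts), ",", fixed = TRUE)
  ends <- strsplit(as.character(genes$exon_ends), ",", fixed = TRUE)
  n <- lengths(starts)
  if (!all(n == lengths(ends))) abort("exon_starts/exon_ends length mismatch")
  tibble(
    gene_id = rep(genes$gene_id, n),
    chrom = rep(genes$chrom, n),
    start = as.integer(unlist(starts)),
    end = as.integer(unlist(ends))
  )
}
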