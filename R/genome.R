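#' Build an in-memory genome model
#'
#' A genome model carries the chromosome table, the merged repeat intervals
#' (RepeatMasker-style), the total non-repeat genome length `LG`, and
#' optionally the genome sequence. `LG` is the normalising denominator for
#' all length-based enrichment statistics in the package.
#'
#' @param chromosomes Data frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param repeats Optional data frame of repeat intervals (`chrom`, `start`,
#'   `end`, 0-based half-open). Merged on construction; must lie within
#'   chromosome bounds.
#' @param sequence Optional [Biostrings::DNAStringSet] (or named character
#'   vector) with one entry per chromosome, required by sequence-context
#'   analyses.
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes`, `repeats` (merged), `lg`, and `sequence`.
#' @examples
#' gm <- genome_model(c(chr1 = 1000), repeats = data.frame(
#'   chrom = "chr1", start = 100, end = 200))
#' gm$lg  # 900
#' @export
genome_model <- function(chromosomes, repeats = NULL, sequence = NULL) {
  if (!is.data.frame(chromosomes)) {
    chromosomes <- tibble(chrom = names(chromosomes),
                          length = as.numeric(chromosomes))
  }
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `chrom` and `length`")
  }
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$chrom)) abort("duplicated chromosome names")
  chromosomes <- as_tibble(chromosomes[c("chrom", "length")])

  if (is.null(repeats)) {
    repeats <- tibble(chrom = character(), start = integer(), end = integer())
  }
  repeats <- merge_intervals(repeats)
  unknown <- setdiff(unique(repeats$chrom), chromosomes$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("repeat intervals on unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  lens <- setNames(chromosomes$length, chromosomes$chrom)
  if (nrow(repeats) > 0 &&
      any(repeats$end > lens[repeats$chrom] | repeats$start < 0)) {
    abort("repeat intervals extend beyond chromosome bounds")
  }

  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    miss <- setdiff(chromosomes$chrom, names(sequence))
    if (length(miss) > 0) {
      abort(sprintf("sequence missing for chromosome(s): %s",
                    paste(miss, collapse = ", ")))
    }
    seqlen <- Biostrings::width(sequence)[match(chromosomes$chrom, names(sequence))]
    if (!all(seqlen == chromosomes$length)) {
      abort("sequence lengths disagree with chromosome table")
    }
  }

  lg <- sum(chromosomes$length) - .interval_length(repeats)
  structure(
    list(chromosomes = chromosomes, repeats = repeats, lg = lg,
         sequence = sequence),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %s bp total\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ",")))
  cat(sprintf("  repeats: %d interval(s), %s bp masked\n",
              nrow(x$repeats), format(.interval_length(x$repeats), big.mark = ",")))
  cat(sprintf("  non-repeat length LG = %s bp; sequence %s\n",
              format(x$lg, big.mark = ","),
              if (is.null(x$sequence)) "absent" else "attached"))
  invisible(x)
}

#' Total non-repeat genome length
#'
#' Recomputes `LG` from the chromosome table and the merged repeat intervals.
#' Always equals the `lg` field of a valid model.
#'
#' @param genome A [genome_model()].
#' @return Numeric scalar, bp.
#' @export
genome_lg <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sum(genome$chromosomes$length) - .interval_length(genome$repeats)
}

#' Read a genome from FASTA (plus optional repeat track)
#'
#' @param fasta Path to a FASTA file; sequence names are the first
#'   whitespace-delimited word of each header.
#' @param repeats Optional path to a BED file of repeat intervals, or a data
#'   frame.
#' @return A [genome_model()] with sequence attached.
#' @export
read_fasta_genome <- function(fasta, repeats = NULL) {
  seq <- Biostrings::readDNAStringSet(fasta)
  names(seq) <- sub("\\s.*$", "", names(seq))
  chromosomes <- tibble(chrom = names(seq), length = Biostrings::width(seq))
  if (is.character(repeats)) repeats <- read_intervals(repeats)
  genome_model(chromosomes, repeats = repeats, sequence = seq)
}

#' Write a genome model's sequence to FASTA
#'
#' @param genome A [genome_model()] with sequence attached.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(genome$sequence)) abort("genome has no sequence attached")
  Biostrings::writeXStringSet(genome$sequence, path, width = 70L)
  invisible(path)
}
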