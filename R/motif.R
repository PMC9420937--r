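# Sequence context around breaks.
#
# A break sits between bases N and M (5'-NM-3' on its strand); position 0 is
# base N immediately 5' of the nick, negative labels run further 5', and
# position 1 is the first base 3' of the nick. A +/-`flank` window therefore
# spans labels -(flank-1) .. flank, i.e. 2*flank bases, read 5'->3' on the
# break's strand (reverse-complemented for minus-strand breaks).

#' Extract stranded sequence contexts around break positions
#'
#' Windows running past a chromosome end are dropped and counted. Lowercase
#' (soft-masked) bases are uppercased; ambiguity codes are kept here and
#' excluded later by [frequency_matrix()].
#'
#' @param breaks Position tibble (`chrom`, `pos`, `strand`).
#' @param genome A [genome_model()] with sequence attached.
#' @param flank Half-window in bp (default 5).
#' @return Tibble `chrom`, `pos`, `strand`, `context` (2*`flank`-base
#'   string); attribute `n_edge_dropped` counts removed edge windows.
#' @export
extract_contexts <- function(breaks, genome, flank = 5) {
  .check_positions(breaks, "breaks")
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(genome$sequence)) abort("genome has no sequence attached")
  flank <- as.integer(flank)
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  plus <- breaks$strand == "+"
  lo <- ifelse(plus, breaks$pos - (flank - 1L), breaks$pos - flank)
  hi <- ifelse(plus, breaks$pos + flank, breaks$pos + flank - 1L)
  ok <- lo >= 0L & hi <= lens[breaks$chrom] - 1L
  kept <- breaks[ok, , drop = FALSE]
  lo <- lo[ok]
  hi <- hi[ok]
  ctx <- character(nrow(kept))
  for (ch in unique(kept$chrom)) {
    idx <- which(kept$chrom == ch)
    v <- Biostrings::Views(genome$sequence[[ch]], start = lo[idx] + 1L,
                           end = hi[idx] + 1L)
    s <- Biostrings::DNAStringSet(v)
    minus <- kept$strand[idx] == "-"
    if (any(minus)) s[minus] <- Biostrings::reverseComplement(s[minus])
    ctx[idx] <- toupper(as.character(s))
  }
  out <- kept[c("chrom", "pos", "strand")]
  out$context <- ctx
  attr(out, "n_edge_dropped") <- sum(!ok)
  attr(out, "flank") <- flank
  out
}

#' Position frequency matrix of break contexts
#'
#' Contexts containing any base other than A/C/G/T are excluded and counted.
#' Information content per position is `2 + sum(f * log2 f)` bits, the usual
#' sequence-logo height.
#'
#' @param contexts Character vector of equal-length context strings, or the
#'   tibble returned by [extract_contexts()].
#' @return Object of class `context_matrix`: tibble `position` (labels
#'   `-(flank-1) .. flank`), counts `a`,`c`,`g`,`t`, frequencies
#'   `f_a`..`f_t`, and `information` (bits); attributes `n_contexts`,
#'   `n_ambiguous`.
#' @export
frequency_matrix <- function(contexts) {
  if (is.data.frame(contexts)) contexts <- contexts$context
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) == 0) abort("no contexts")
  width <- unique(nchar(contexts))
  if (length(width) != 1) abort("contexts must have equal length")
  if (width %% 2 != 0) abort("context width must be even (2 * flank)")
  clean <- grepl("^[ACGT]+$", contexts)
  n_ambiguous <- sum(!clean)
  contexts <- contexts[clean]
  if (length(contexts) == 0) abort("all contexts ambiguous")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(contexts))
  counts <- t(cm[c("A", "C", "G", "T"), , drop = FALSE])
  n <- length(contexts)
  freqs <- counts / n
  info <- apply(freqs, 1, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  flank <- width %/% 2
  out <- tibble(
    position = seq(-(flank - 1L), flank),
    a = counts[, "A"], c = counts[, "C"], g = counts[, "G"], t = counts[, "T"],
    f_a = freqs[, "A"], f_c = freqs[, "C"], f_g = freqs[, "G"],
    f_t = freqs[, "T"],
    information = info
  )
  attr(out, "n_contexts") <- n
  attr(out, "n_ambiguous") <- n_ambiguous
  class(out) <- c("context_matrix", class(out))
  out
}

#' Cytosine/guanine frequency ratio at selected context positions
#'
#' @param matrix A `context_matrix` from [frequency_matrix()].
#' @param positions Context positions to query (default -1 and 0, the two
#'   bases immediately 5' of the nick).
#' @return Tibble `position`, `f_c`, `f_g`, `cg_ratio` (`Inf` when the
#'   guanine frequency is zero).
#' @export
cg_ratio <- function(matrix, positions = c(-1, 0)) {
  stopifnot(inherits(matrix, "context_matrix"))
  miss <- setdiff(positions, matrix$position)
  if (length(miss) > 0) {
    abort(sprintf("position(s) not in matrix: %s", paste(miss, collapse = ", ")))
  }
  rows <- matrix[match(positions, matrix$position), , drop = FALSE]
  tibble(
    position = rows$position,
    f_c = rows$f_c,
    f_g = rows$f_g,
    cg_ratio = ifelse(rows$f_g > 0, rows$f_c / rows$f_g,
                      ifelse(rows$f_c > 0, Inf, NA_real_))
  )
}

#' Median C/G ratio across several context matrices
#'
#' Aggregates [cg_ratio()] over an explicit list of matrices (e.g. all-break
#' and hotspot tracks across cell types).
#'
#' @param matrices List of `context_matrix` objects.
#' @param positions Context positions to query.
#' @return Tibble `position`, `median_cg_ratio`, `n_matrices`.
#' @export
median_cg_ratio <- function(matrices, positions = c(-1, 0)) {
  ratios <- bind_rows(lapply(matrices, cg_ratio, positions = positions))
  summarise(group_by(ratios, .data$position),
            median_cg_ratio = median(.data$cg_ratio),
            n_matrices = dplyr::n(), .groups = "drop")
}
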