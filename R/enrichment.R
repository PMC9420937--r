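# Break density and enrichment around operative TSSs.
#
# Every break is assigned the signed distance to its nearest operative TSS
# (negative upstream of the gene, positive downstream, in gene orientation).
# Aggregate densities over +/-5,000 bp are normalised per 20-bp bin by the
# average non-repeat fraction of that bin across expressed genes (NR_j), and
# the promoter-proximal enrichment ratio R compares break rates within
# +/-200 bp to the +/-5,000 bp background, correcting for non-repeat length.

#' Signed distance from each break to its nearest operative TSS
#'
#' Keeps the absolute-shortest distance per break; the sign is negative when
#' the break lies 5' (upstream) of the TSS in gene orientation and positive
#' 3' (downstream). Distance ties between two TSSs are broken toward the
#' lower genomic coordinate for determinism.
#'
#' @param breaks Position tibble (`chrom`, `pos`, `strand`).
#' @param tss Operative TSS tibble from [assign_tss()] (`gene_id`, `chrom`,
#'   `strand`, `tss`).
#' @return `breaks` with added columns `distance` (signed bp; `NA` when the
#'   chromosome has no TSS), `gene_id`, and `strand_class`
#'   ("template"/"non_template" via [classify_strand()]).
#' @export
nearest_tss_distance <- function(breaks, tss) {
  .check_positions(breaks, "breaks")
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(tss)))
  n <- nrow(breaks)
  distance <- rep(NA_real_, n)
  gene_id <- rep(NA_character_, n)
  gene_strand <- rep(NA_character_, n)
  for (ch in unique(breaks$chrom)) {
    idx <- which(breaks$chrom == ch)
    sub <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(sub$tss, sub$gene_id), , drop = FALSE]
    p <- breaks$pos[idx]
    i <- findInterval(p, sub$tss)
    dl <- ifelse(i >= 1, p - sub$tss[pmax(i, 1L)], Inf)
    dr <- ifelse(i < nrow(sub), sub$tss[pmin(i + 1L, nrow(sub))] - p, Inf)
    use_left <- dl <= dr   # tie -> lower coordinate
    j <- ifelse(use_left, i, i + 1L)
    d_gen <- p - sub$tss[j]
    sgn <- ifelse(sub$strand[j] == "+", 1, -1)
    distance[idx] <- d_gen * sgn
    gene_id[idx] <- sub$gene_id[j]
    gene_strand[idx] <- sub$strand[j]
  }
  out <- breaks
  out$distance <- distance
  out$gene_id <- gene_id
  out$strand_class <- ifelse(
    is.na(gene_strand), NA_character_,
    classify_strand(breaks$strand, ifelse(is.na(gene_strand), "+", gene_strand))
  )
  out
}

# Per-chromosome logical vectors: TRUE where the base is outside all repeats.
.nonrepeat_flags <- function(genome) {
  out <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$chrom[i]
    len <- as.integer(genome$chromosomes$length[i])
    v <- rep(TRUE, len)
    sub <- genome$repeats[genome$repeats$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 0) {
      idx <- sequence(sub$end - sub$start, from = sub$start + 1L)
      v[idx] <- FALSE
    }
    out[[ch]] <- v
  }
  out
}

# Gene-oriented non-repeat indicator at offsets lo..hi around each TSS.
# Returns a (hi-lo+1) x n_genes matrix; bases beyond chromosome ends count
# as unavailable (FALSE).
.tss_window_nonrepeat <- function(tss, genome, lo, hi) {
  flags <- .nonrepeat_flags(genome)
  width <- hi - lo + 1L
  m <- matrix(FALSE, nrow = width, ncol = nrow(tss))
  offs <- lo:hi
  for (k in seq_len(nrow(tss))) {
    v <- flags[[tss$chrom[k]]]
    g <- if (tss$strand[k] == "+") tss$tss[k] + offs else tss$tss[k] - offs
    ok <- g >= 0L & g < length(v)
    col <- rep(FALSE, width)
    col[ok] <- v[g[ok] + 1L]
    m[, k] <- col
  }
  m
}

#' Average non-repeat ratio per bin around TSSs
#'
#' Splits the +/-`window` bp region around each operative TSS into
#' non-overlapping `bin_width`-bp bins in gene orientation (bin `j` covers
#' offsets `[-window + bin_width*(j-1), -window + bin_width*j)`; the TSS base
#' sits at offset 0). For each bin, `NR_j` is the mean non-repeat fraction
#' across all expressed genes — the mappability-style normaliser for
#' [density_profile()].
#'
#' @param tss Operative TSS tibble from [assign_tss()].
#' @param genome A [genome_model()].
#' @param window Half-window (bp, default 5000).
#' @param bin_width Bin width (bp, default 20; must divide `2 * window`).
#' @return Object of class `bin_grid`: tibble `bin`, `offset_start`,
#'   `offset_end`, `nr`, with attributes `window`, `bin_width`, `n_genes`.
#' @export
build_bin_grid <- function(tss, genome, window = 5000, bin_width = 20) {
  if (nrow(tss) == 0) abort("no expressed genes")
  if ((2 * window) %% bin_width != 0) abort("`bin_width` must divide 2 * window")
  n_bins <- as.integer(2 * window / bin_width)
  m <- .tss_window_nonrepeat(tss, genome, -window, window - 1L)
  per_gene_bin <- rowsum(m * 1, group = rep(seq_len(n_bins), each = bin_width))
  nr <- unname(rowMeans(per_gene_bin)) / bin_width
  out <- tibble(
    bin = seq_len(n_bins),
    offset_start = as.integer(-window + bin_width * (seq_len(n_bins) - 1L)),
    offset_end = as.integer(-window + bin_width * seq_len(n_bins)),
    nr = nr
  )
  attr(out, "window") <- window
  attr(out, "bin_width") <- bin_width
  attr(out, "n_genes") <- nrow(tss)
  class(out) <- c("bin_grid", class(out))
  out
}

#' Normalised break density profile around TSSs
#'
#' Bins breaks by signed nearest-TSS distance and normalises counts as
#' `D_j = N_j * 1e6 / (NR_j * T)` where `T` is the sample's total unique
#' position count and `NR_j` the bin's average non-repeat ratio. Profiles are
#' returned separately for template and non-template strand matches. Bins
#' with `NR_j = 0` have `NA` density (no mappable sequence), not zero.
#'
#' @param breaks Position tibble.
#' @param tss Operative TSS tibble.
#' @param grid A `bin_grid` from [build_bin_grid()] built from the same TSS
#'   set.
#' @param total Sample total `T` (unique positions genome-wide); defaults to
#'   `nrow(breaks)`.
#' @param sample_id Optional label carried into the output.
#' @return Object of class `density_profile`: tibble `sample`,
#'   `strand_class`, `bin`, `offset_start`, `n`, `nr`, `density`.
#' @export
density_profile <- function(breaks, tss, grid, total = NULL, sample_id = NA) {
  stopifnot(inherits(grid, "bin_grid"))
  total <- total %||% nrow(breaks)
  if (total <= 0) abort("`total` must be positive")
  window <- attr(grid, "window")
  bin_width <- attr(grid, "bin_width")
  d <- nearest_tss_distance(breaks, tss)
  d <- d[!is.na(d$distance) & d$distance >= -window & d$distance < window, ,
         drop = FALSE]
  d$bin <- as.integer((d$distance + window) %/% bin_width + 1L)
  out <- tidyr::crossing(strand_class = c("template", "non_template"),
                         bin = grid$bin)
  counts <- count(d, .data$strand_class, .data$bin, name = "n")
  out <- left_join(out, counts, by = c("strand_class", "bin"))
  out$n <- ifelse(is.na(out$n), 0L, out$n)
  out <- left_join(out, select(grid, "bin", "offset_start", "nr"),
                   by = "bin")
  out$density <- ifelse(out$nr > 0, out$n * 1e6 / (out$nr * total), NA_real_)
  out <- mutate(out, sample = sample_id, total = total, .before = 1)
  class(out) <- c("density_profile", class(out))
  out
}

# Non-repeat length of TSS windows at half-width x.
# mode "nearest": merged union of all per-gene windows (each base counted
# once; membership matches "nearest-TSS distance <= x").
# mode "per_gene": sum over genes without deduplication (mirrors the per-gene
# NR_j construction).
.tss_window_length <- function(tss, genome, x, mode = "nearest") {
  win <- tibble(chrom = tss$chrom, start = tss$tss - as.integer(x),
                end = tss$tss + as.integer(x) + 1L)
  if (mode == "nearest") {
    win <- merge_intervals(win)
  }
  sum(.nonrepeat_widths(win, genome))
}

#' TSS-proximal break enrichment ratio
#'
#' Computes `R = (M_inner / M_outer) / (L_inner / L_outer)` where `M` counts
#' breaks whose absolute nearest-TSS distance is at most `inner` (or `outer`)
#' bp, and `L` is the non-repeat base count of the corresponding TSS windows.
#' `R > 1` means breaks concentrate in the immediate TSS vicinity beyond what
#' mappable sequence predicts. The p-value is a two-sided binomial test of
#' `M_inner` successes in `M_outer` trials at probability
#' `L_inner / L_outer`.
#'
#' By default `L` is measured on the union of per-gene windows, the same
#' position set the nearest-distance `M` counts live on, so that uniform
#' breaks give `R = 1` regardless of how densely gene windows overlap.
#' `l_mode = "per_gene"` instead sums window lengths gene by gene.
#'
#' @param breaks Position tibble.
#' @param tss Operative TSS tibble.
#' @param genome A [genome_model()].
#' @param inner,outer Window half-widths in bp (inclusive; defaults 200 and
#'   5000).
#' @param by_strand Also report template/non-template rows (default TRUE).
#' @param l_mode `"nearest"` (union windows, default) or `"per_gene"`.
#' @param sample_id Optional label.
#' @return Object of class `enrichment_result`: tibble with rows per strand
#'   class plus `"combined"`, columns `sample`, `strand_class`, `m_inner`,
#'   `m_outer`, `l_inner`, `l_outer`, `ratio`, `p_value`.
#' @export
enrichment_ratio <- function(breaks, tss, genome, inner = 200, outer = 5000,
                             by_strand = TRUE, l_mode = c("nearest", "per_gene"),
                             sample_id = NA) {
  l_mode <- match.arg(l_mode)
  if (nrow(tss) == 0) abort("no expressed genes")
  l_inner <- .tss_window_length(tss, genome, inner, l_mode)
  l_outer <- .tss_window_length(tss, genome, outer, l_mode)
  if (l_outer == 0) abort("no non-repeat sequence within the outer window")
  d <- nearest_tss_distance(breaks, tss)
  d <- d[!is.na(d$distance), , drop = FALSE]
  one <- function(sub, label) {
    m_in <- sum(abs(sub$distance) <= inner)
    m_out <- sum(abs(sub$distance) <= outer)
    ratio <- if (m_out == 0) NA_real_ else
      (m_in / m_out) / (l_inner / l_outer)
    p <- if (m_out == 0) NA_real_ else
      binom.test(m_in, m_out, p = l_inner / l_outer,
                 alternative = "two.sided")$p.value
    tibble(sample = sample_id, strand_class = label, m_inner = m_in,
           m_outer = m_out, l_inner = l_inner, l_outer = l_outer,
           ratio = ratio, p_value = p)
  }
  rows <- list(one(d, "combined"))
  if (by_strand) {
    rows <- c(rows, list(
      one(d[d$strand_class == "template", , drop = FALSE], "template"),
      one(d[d$strand_class == "non_template", , drop = FALSE], "non_template")
    ))
  }
  out <- bind_rows(rows)
  attr(out, "inner") <- inner
  attr(out, "outer") <- outer
  attr(out, "l_mode") <- l_mode
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Recover a planted promoter break-rate factor from an enrichment ratio
#'
#' A uniform breakome whose rate is multiplied by `f` inside the inner window
#' yields an expected ratio `R = f / (1 + (f - 1) * p)` with
#' `p = L_inner / L_outer`, because the outer (background) window contains
#' the enriched inner window. This inverts that mapping:
#' `f = R * (1 - p) / (1 - R * p)`.
#'
#' @param result An `enrichment_result` from [enrichment_ratio()].
#' @param strand_class Which row to invert (default "combined").
#' @return Numeric estimate of the rate factor.
#' @export
recover_enrichment_factor <- function(result, strand_class = "combined") {
  stopifnot(inherits(result, "enrichment_result"))
  row <- result[result$strand_class == strand_class, , drop = FALSE]
  if (nrow(row) != 1) abort("strand class not present in result")
  p <- row$l_inner / row$l_outer
  r <- row$ratio
  if (is.na(r) || r * p >= 1) return(NA_real_)
  r * (1 - p) / (1 - r * p)
}

#' Compare per-sample enrichment ratios between treatment groups
#'
#' Two-sided Welch t-test of each treatment's per-sample ratios against the
#' reference group's.
#'
#' @param ratios Tibble with columns `treatment` and `ratio` (one row per
#'   sample).
#' @param reference Label of the reference treatment (e.g. the vehicle
#'   control).
#' @return Tibble `treatment`, `n`, `mean_ratio`, `reference_mean`,
#'   `statistic`, `p_value`, one row per non-reference treatment.
#' @export
compare_ratio_groups <- function(ratios, reference) {
  stopifnot(all(c("treatment", "ratio") %in% names(ratios)))
  ref <- ratios$ratio[ratios$treatment == reference]
  if (length(ref) < 2) abort("reference group needs >= 2 ratio values")
  others <- setdiff(unique(ratios$treatment), reference)
  out <- lapply(others, function(tr) {
    x <- ratios$ratio[ratios$treatment == tr]
    if (length(x) < 2) abort(sprintf("group '%s' needs >= 2 ratio values", tr))
    if (stats::sd(x) == 0 && stats::sd(ref) == 0) {
      p <- if (mean(x) == mean(ref)) 1 else 0
      stat <- NA_real_
    } else {
      tt <- t.test(x, ref, alternative = "two.sided", var.equal = FALSE)
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    tibble(treatment = tr, n = length(x), mean_ratio = mean(x),
           reference_mean = mean(ref), statistic = stat, p_value = p)
  })
  bind_rows(out)
}
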