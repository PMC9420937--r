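# Promoter-proximal breaks vs gene expression rank.
#
# Genes are ranked by expression and cut into nested top strata; observed
# fractions of breaks near each stratum's TSSs are compared to the fractions
# expected for uniformly random positions in non-repeat space, giving an
# observed/expected odds ratio per stratum and distance bin.

#' Nested top-expression gene strata
#'
#' Ranks genes by descending expression (ties broken by `gene_id` for
#' determinism) and returns the top fractions as nested strata. Stratum
#' sizes are `round(fraction * n)` (half-up).
#'
#' @param expr Expression tibble with `gene_id` and `expression`.
#' @param fractions Numeric fractions in (0, 1] (default 5, 10, 25, 50
#'   percent).
#' @return Tibble `stratum` (ordered factor, e.g. "top5"), `gene_id`; a gene
#'   appears in every stratum that contains it.
#' @export
rank_strata <- function(expr, fractions = c(0.05, 0.10, 0.25, 0.50)) {
  stopifnot(all(c("gene_id", "expression") %in% names(expr)))
  if (nrow(expr) == 0) abort("empty expression table")
  fractions <- sort(fractions)
  ord <- order(-expr$expression, expr$gene_id)
  ids <- expr$gene_id[ord]
  labels <- paste0("top", .round_half_up(100 * fractions, 1))
  out <- lapply(seq_along(fractions), function(i) {
    k <- max(1L, as.integer(floor(fractions[i] * length(ids) + 0.5)))
    tibble(stratum = labels[i], gene_id = ids[seq_len(min(k, length(ids)))])
  })
  out <- bind_rows(out)
  out$stratum <- factor(out$stratum, levels = labels, ordered = TRUE)
  out
}

#' Sample uniform stranded positions from non-repeat space
#'
#' @param genome A [genome_model()].
#' @param n Number of positions to draw (with replacement across draws;
#'   positions may repeat).
#' @param seed Optional integer seed.
#' @return Position tibble `chrom`, `pos`, `strand`.
#' @export
sample_positions <- function(genome, n, seed = NULL) {
  nonrep <- complement_intervals(genome$repeats, genome$chromosomes)
  if (nrow(nonrep) == 0) abort("no non-repeat space to sample from")
  w <- as.numeric(nonrep$end - nonrep$start)
  draw <- function() {
    i <- sample.int(nrow(nonrep), n, replace = TRUE, prob = w)
    offs <- floor(runif(n) * w[i])
    tibble(chrom = nonrep$chrom[i],
           pos = as.integer(nonrep$start[i] + offs),
           strand = sample(c("+", "-"), n, replace = TRUE))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Fractions of positions falling in each distance bin of each stratum's TSSs.
.stratum_bin_fractions <- function(positions, tss, strata, inner = 200,
                                   outer = 5000) {
  total <- nrow(positions)
  if (total == 0) abort("no positions")
  out <- lapply(levels(strata$stratum), function(s) {
    sub_tss <- semi_join(tss, strata[strata$stratum == s, , drop = FALSE],
                         by = "gene_id")
    if (nrow(sub_tss) == 0) {
      return(tibble(stratum = s, bin = c("inner", "annulus"), fraction = 0))
    }
    d <- nearest_tss_distance(positions, sub_tss)
    ad <- abs(d$distance)
    tibble(
      stratum = s,
      bin = c("inner", "annulus"),
      fraction = c(sum(!is.na(ad) & ad <= inner) / total,
                   sum(!is.na(ad) & ad > inner & ad <= outer) / total)
    )
  })
  out <- bind_rows(out)
  out$stratum <- factor(out$stratum, levels = levels(strata$stratum),
                        ordered = TRUE)
  out
}

#' Expected fractions of random breaks near stratified TSSs
#'
#' Draws `n_random` uniform stranded positions from the genome's non-repeat
#' space and records, per expression stratum, the fraction within the inner
#' window (+/-`inner` bp of the stratum's TSSs) and within the annulus
#' (`inner` < |d| <= `outer`).
#'
#' @param genome A [genome_model()].
#' @param tss Operative TSS tibble.
#' @param strata Strata from [rank_strata()].
#' @param n_random Number of random positions (a desk-scale stand-in for the
#'   much larger counts used at genome scale; recorded in the output).
#' @param inner,outer Window half-widths (bp).
#' @param seed Optional integer seed.
#' @return Tibble `stratum`, `bin` ("inner"/"annulus"), `expected`,
#'   `n_random`.
#' @export
expected_fractions <- function(genome, tss, strata, n_random = 1e5,
                               inner = 200, outer = 5000, seed = NULL) {
  if (n_random < 1) abort("`n_random` must be positive")
  pos <- sample_positions(genome, n_random, seed = seed)
  out <- .stratum_bin_fractions(pos, tss, strata, inner, outer)
  out <- rename(out, expected = "fraction")
  out$n_random <- n_random
  out
}

#' Observed/expected odds ratios of breaks near stratified TSSs
#'
#' @param positions Observed break or hotspot positions.
#' @param tss Operative TSS tibble.
#' @param strata Strata from [rank_strata()].
#' @param expected Expected fractions from [expected_fractions()] for the
#'   same strata and windows.
#' @param inner,outer Window half-widths (bp; must match `expected`).
#' @return Tibble `stratum`, `bin`, `observed`, `expected`, `odds_ratio`.
#'   A zero expected fraction with observed > 0 yields `Inf`.
#' @export
expression_odds_ratios <- function(positions, tss, strata, expected,
                                   inner = 200, outer = 5000) {
  obs <- .stratum_bin_fractions(positions, tss, strata, inner, outer)
  obs <- rename(obs, observed = "fraction")
  out <- left_join(obs, select(expected, "stratum", "bin", "expected"),
                   by = c("stratum", "bin"))
  out$odds_ratio <- ifelse(
    out$expected > 0, out$observed / out$expected,
    ifelse(out$observed > 0, Inf, NA_real_)
  )
  out
}

#' One-sided comparison of two odds-ratio series
#'
#' One-sided two-sample Student t-test that `series_a` exceeds `series_b`
#' (equal-variance; symmetric under argument swap: p' = 1 - p).
#'
#' @param series_a,series_b Numeric vectors of odds ratios (>= 2 values
#'   each).
#' @return One-row tibble `statistic`, `df`, `p_value`, `degenerate`.
#' @export
compare_or_series <- function(series_a, series_b) {
  if (length(series_a) < 2 || length(series_b) < 2) {
    abort("each series needs >= 2 values")
  }
  if (stats::sd(series_a) == 0 && stats::sd(series_b) == 0) {
    p <- if (mean(series_a) > mean(series_b)) 0 else
      if (mean(series_a) == mean(series_b)) 0.5 else 1
    return(tibble(statistic = NA_real_, df = NA_real_, p_value = p,
                  degenerate = TRUE))
  }
  tt <- t.test(series_a, series_b, alternative = "greater", var.equal = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}
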