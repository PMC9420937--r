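# Recurrent break positions across biological replicas.
#
# A hotspot is a single-nucleotide stranded position carrying breaks in at
# least `min_support` independent replicas of a cell type (default 2). The
# chance level of sharing is estimated by Monte-Carlo simulation: replicas of
# the same sizes drawn uniformly without replacement from the detectable
# position space.

#' Count replica support per break position
#'
#' @param breaks Either a tibble of pooled positions with a `replica` column,
#'   or a list of per-replica position tibbles. Each replica must already be
#'   deduplicated (as produced by [read_breaks()]).
#' @return Tibble `chrom`, `pos`, `strand`, `support` (number of replicas
#'   containing the position), with attributes `n_replicas` and `totals`
#'   (per-replica unique-position counts `T_i`).
#' @export
build_support <- function(breaks) {
  if (is.data.frame(breaks)) {
    .check_positions(breaks)
    if (!"replica" %in% names(breaks)) {
      abort("pooled `breaks` need a `replica` column")
    }
    pooled <- breaks
  } else {
    if (length(breaks) == 0) abort("empty replica list")
    ids <- names(breaks) %||% as.character(seq_along(breaks))
    if (is.null(names(breaks))) names(breaks) <- ids
    pooled <- bind_rows(lapply(ids, function(id) {
      b <- breaks[[id]]
      .check_positions(b)
      b$replica <- id
      b[c("chrom", "pos", "strand", "replica")]
    }))
  }
  pooled <- distinct(pooled, .data$chrom, .data$pos, .data$strand, .data$replica)
  totals <- count(pooled, .data$replica, name = "t_i")
  out <- count(pooled, .data$chrom, .data$pos, .data$strand, name = "support")
  out <- arrange(out, .data$chrom, .data$pos, .data$strand)
  attr(out, "n_replicas") <- nrow(totals)
  attr(out, "totals") <- totals
  out
}

#' Call hotspots at a support threshold
#'
#' @param support Support tibble from [build_support()].
#' @param min_support Minimum number of replicas (k >= 2; the hotspot
#'   definition starts at two).
#' @return The positions with `support >= min_support`, same columns as the
#'   input.
#' @export
call_hotspots <- function(support, min_support = 2) {
  if (min_support < 2) abort("`min_support` must be >= 2 for hotspot calling")
  n_rep <- attr(support, "n_replicas")
  if (!is.null(n_rep) && min_support > n_rep) {
    warn("`min_support` exceeds the number of replicas; no position can qualify")
  }
  out <- support[support$support >= min_support, , drop = FALSE]
  attr(out, "min_support") <- min_support
  out
}

#' Fraction of positions qualifying as hotspots
#'
#' The number of positions shared by at least `min_support` replicas divided
#' by the number of positions found in at least one replica.
#'
#' @param support Either a position-level support tibble from
#'   [build_support()], or an aggregated histogram with columns `support` and
#'   `n` (number of positions at that support level).
#' @param min_support Support threshold.
#' @return Numeric scalar in `[0, 1]`.
#' @export
hotspot_fraction <- function(support, min_support = 2) {
  if (!is.data.frame(support) || !"support" %in% names(support)) {
    abort("`support` must have a `support` column")
  }
  w <- if ("n" %in% names(support) && !"pos" %in% names(support)) {
    as.numeric(support$n)
  } else rep(1, nrow(support))
  total <- sum(w[support$support >= 1])
  if (total == 0) abort("empty support map")
  sum(w[support$support >= min_support]) / total
}

#' Monte-Carlo null for the shared-position fraction
#'
#' Each simulation draws every replica uniformly without replacement from a
#' position space of `space_size` stranded non-repeat positions and records
#' the hotspot fraction at the given threshold. The default 100 simulations
#' mirror common practice for this statistic.
#'
#' @param n_replicas Number of replicas per simulation.
#' @param breaks_per_replica Integer vector (recycled to `n_replicas`) of
#'   unique positions per replica.
#' @param space_size Size of the sampling space (e.g. `2 * LG` stranded
#'   positions).
#' @param n_sim Number of simulations.
#' @param min_support Support threshold for the recorded fraction.
#' @param seed Optional integer seed; the simulation is deterministic given it.
#' @return Object of class `null_distribution`: list with `fractions`,
#'   `n_sim`, `space_size`, `min_support`, `seed`.
#' @export
simulate_null <- function(n_replicas, breaks_per_replica, space_size,
                          n_sim = 100, min_support = 2, seed = NULL) {
  if (space_size <= 0) abort("`space_size` must be positive")
  b <- as.integer(rep_len(breaks_per_replica, n_replicas))
  if (any(b > space_size)) abort("`breaks_per_replica` exceeds `space_size`")
  run <- function() {
    fr <- vapply(seq_len(n_sim), function(i) {
      draws <- sort(unlist(lapply(b, function(bi) sample.int(space_size, bi))))
      runs <- rle(draws)$lengths
      sum(runs >= min_support) / length(runs)
    }, numeric(1))
    fr
  }
  fractions <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(fractions = fractions, n_sim = n_sim, space_size = space_size,
         min_support = min_support, seed = seed),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d simulations, space %s, support >= %d\n  mean fraction %.3g (sd %.3g)\n",
    x$n_sim, format(x$space_size, big.mark = ","), x$min_support,
    mean(x$fractions), stats::sd(x$fractions)))
  invisible(x)
}

#' Test an observed hotspot fraction against the simulated null
#'
#' Two-sided one-sample Student t-test of the simulated fractions against the
#' observed value. A zero-variance null degenerates to an exact comparison:
#' p = 1 if the observed value equals the constant, else p = 0 (below any
#' representable t-test floor), flagged in the result.
#'
#' @param observed Observed hotspot fraction.
#' @param null A `null_distribution` from [simulate_null()].
#' @return Object of class `hotspot_test`: observed value, null mean/sd,
#'   `statistic`, `df`, `p_value`, `degenerate` flag.
#' @export
hotspot_significance <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  fr <- null$fractions
  if (length(fr) < 2) abort("need at least 2 simulations")
  if (stats::sd(fr) == 0) {
    res <- list(observed = observed, null_mean = mean(fr), null_sd = 0,
                statistic = NA_real_, df = NA_real_,
                p_value = if (observed == fr[1]) 1 else 0, degenerate = TRUE)
  } else {
    tt <- t.test(fr, mu = observed, alternative = "two.sided")
    res <- list(observed = observed, null_mean = mean(fr), null_sd = stats::sd(fr),
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, degenerate = FALSE)
  }
  structure(res, class = "hotspot_test")
}

#' @export
print.hotspot_test <- function(x, ...) {
  cat(sprintf(
    "<hotspot_test> observed %.4g vs null %.4g (sd %.3g)\n  t = %.3g, p = %.3g%s\n",
    x$observed, x$null_mean, x$null_sd, x$statistic, x$p_value,
    if (x$degenerate) " [degenerate null: exact comparison]" else ""))
  invisible(x)
}

#' Overlap odds ratio between two hotspot sets
#'
#' Enrichment of the observed overlap over the expectation
#' `|A| * |B| / U` for two sets drawn independently from a universe of `U`
#' positions, with a two-sided binomial test (successes = overlap, trials =
#' `|A|`, success probability `|B| / U`).
#'
#' @param set_a,set_b Position tibbles (overlap computed on
#'   chromosome/position/strand identity), or scalar counts, in which case
#'   `overlap` must be supplied.
#' @param universe_size Number of positions in the universe.
#' @param overlap Observed overlap count (only with scalar `set_a`/`set_b`).
#' @return One-row tibble: `n_a`, `n_b`, `overlap`, `expected`, `odds_ratio`,
#'   `p_value`.
#' @export
overlap_odds_ratio <- function(set_a, set_b, universe_size, overlap = NULL) {
  if (universe_size <= 0) abort("`universe_size` must be positive")
  if (is.data.frame(set_a)) {
    .check_positions(set_a, "set_a")
    .check_positions(set_b, "set_b")
    n_a <- nrow(set_a)
    n_b <- nrow(set_b)
    overlap <- length(intersect(.pos_key(set_a), .pos_key(set_b)))
  } else {
    n_a <- set_a
    n_b <- set_b
    if (is.null(overlap)) abort("`overlap` required with count inputs")
  }
  if (universe_size < max(n_a, n_b)) abort("universe smaller than a set")
  expected <- n_a * (n_b / universe_size)
  or <- if (expected == 0) NA_real_ else overlap / expected
  p <- if (n_a == 0) {
    NA_real_
  } else {
    binom.test(overlap, n_a, p = n_b / universe_size,
               alternative = "two.sided")$p.value
  }
  tibble(n_a = n_a, n_b = n_b, overlap = overlap, expected = expected,
         odds_ratio = or, p_value = p)
}

# Round half-up to `digits` decimals (reporting convention for percentages).
.round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Distribution of hotspot counts per gene
#'
#' Tabulates how many genes carry exactly one, two, three-to-five, or more
#' than five hotspots near their TSS, with percentages rounded half-up to one
#' decimal.
#'
#' @param gene_counts Tibble with a `n_hotspots` column (one row per gene
#'   carrying at least one hotspot), or a bare numeric vector of per-gene
#'   counts.
#' @return Tibble `class`, `n_genes`, `percent`.
#' @export
summarize_hotspot_gene_counts <- function(gene_counts) {
  x <- if (is.data.frame(gene_counts)) gene_counts$n_hotspots else gene_counts
  if (any(x < 1)) abort("per-gene hotspot counts must be >= 1")
  cls <- cut(x, breaks = c(0, 1, 2, 5, Inf),
             labels = c("1", "2", "3-5", ">5"))
  tab <- table(cls)
  tibble(
    class = names(tab),
    n_genes = as.integer(tab),
    percent = .round_half_up(100 * as.integer(tab) / length(x), 1)
  )
}
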