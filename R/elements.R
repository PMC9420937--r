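# Hierarchical assignment of breaks to genomic elements.
#
# Seven element classes, consulted strictly in order: TSS +/-200 bp,
# CAGE peak +/-200 bp, chromatin-state promoter, TTS +/-200 bp, exon,
# intron, intergenic. A position takes the first class whose intervals cover
# it; class 7 is the complement, so the classes partition every position.

.element_classes <- c("tss_200", "cage_200", "promoter", "tts_200",
                      "exon", "intron", "intergenic")

.window_intervals <- function(chrom, center, window) {
  merge_intervals(tibble(chrom = chrom,
                         start = as.integer(center) - as.integer(window),
                         end = as.integer(center) + as.integer(window) + 1L))
}

.clip_intervals <- function(intervals, genome) {
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  intervals$start <- pmax(intervals$start, 0L)
  intervals$end <- pmin(intervals$end, as.integer(lens[intervals$chrom]))
  intervals[intervals$end > intervals$start, , drop = FALSE]
}

.empty_intervals <- function() {
  tibble(chrom = character(), start = integer(), end = integer())
}

# Set difference a \ b on merged interval tibbles.
.setdiff_intervals <- function(a, b) {
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  out <- lapply(unique(a$chrom), function(ch) {
    ra <- .as_iranges(a$start[a$chrom == ch], a$end[a$chrom == ch])
    sb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(sb) == 0) {
      r <- ra
    } else {
      r <- IRanges::setdiff(ra, .as_iranges(sb$start, sb$end))
    }
    tibble(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  bind_rows(out)
}

#' Build the 7-class genomic element hierarchy
#'
#' Interval sets are built from the operative TSSs (class 1), all called CAGE
#' peaks (class 2), merged chromatin-state promoter tracks (class 3), and the
#' longest-transcript structure of every annotated gene irrespective of
#' expression: TTS windows (class 4), exons (class 5), introns (class 6).
#' Class 7 (intergenic) is the complement of classes 1-6. Windows are
#' inclusive (+/-`window` bp). Missing inputs yield empty classes with a
#' warning.
#'
#' Each class's non-repeat length is measured two ways: `l_element` on the
#' class's own merged interval set, and `l_disjoint` after subtracting all
#' higher-priority classes (so that the disjoint lengths partition `LG`
#' exactly as the assignments partition the positions).
#'
#' @param genome A [genome_model()].
#' @param genes Gene annotation tibble ([read_genes()] format).
#' @param tss Operative TSS tibble from [assign_tss()] (or NULL).
#' @param cage_peaks Called CAGE peaks (or NULL).
#' @param promoters Promoter interval tibble (or NULL).
#' @param window Half-width for TSS/CAGE/TTS windows (bp, default 200).
#' @return Object of class `element_hierarchy`: list with `classes` (named
#'   list of merged interval tibbles in priority order), `lengths` (tibble
#'   `class`, `l_element`, `l_disjoint`), and `lg`.
#' @export
build_hierarchy <- function(genome, genes, tss = NULL, cage_peaks = NULL,
                            promoters = NULL, window = 200) {
  stopifnot(inherits(genome, "genome_model"))
  cls <- list()
  cls$tss_200 <- if (is.null(tss) || nrow(tss) == 0) {
    warn("no TSS input; class tss_200 built empty")
    .empty_intervals()
  } else .window_intervals(tss$chrom, tss$tss, window)
  cls$cage_200 <- if (is.null(cage_peaks) || nrow(cage_peaks) == 0) {
    warn("no CAGE peaks; class cage_200 built empty")
    .empty_intervals()
  } else .window_intervals(cage_peaks$chrom, cage_peaks$pos, window)
  cls$promoter <- if (is.null(promoters) || nrow(promoters) == 0) {
    warn("no promoter track; class promoter built empty")
    .empty_intervals()
  } else merge_intervals(promoters)
  cls$tts_200 <- .window_intervals(genes$chrom, genes$tts, window)
  exons <- .gene_exons(genes)
  cls$exon <- merge_intervals(exons[c("chrom", "start", "end")])
  spans <- tibble(chrom = genes$chrom,
                  start = pmin(genes$tss, genes$tts),
                  end = pmax(genes$tss, genes$tts) + 1L)
  introns <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    .setdiff_intervals(merge_intervals(spans[i, ]),
                       merge_intervals(ex[c("chrom", "start", "end")]))
  })
  cls$intron <- merge_intervals(bind_rows(c(introns, list(.empty_intervals()))))
  cls <- lapply(cls, .clip_intervals, genome = genome)
  genic <- merge_intervals(bind_rows(cls))
  cls$intergenic <- complement_intervals(genic, genome$chromosomes)

  l_element <- vapply(cls, function(x) sum(.nonrepeat_widths(x, genome)),
                      numeric(1))
  seen <- .empty_intervals()
  l_disjoint <- numeric(length(cls))
  for (i in seq_along(cls)) {
    own <- .setdiff_intervals(cls[[i]], seen)
    l_disjoint[i] <- sum(.nonrepeat_widths(own, genome))
    seen <- merge_intervals(bind_rows(seen, cls[[i]]))
  }
  structure(
    list(classes = cls,
         lengths = tibble(class = .element_classes, l_element = l_element,
                          l_disjoint = l_disjoint),
         lg = genome$lg),
    class = "element_hierarchy"
  )
}

#' @export
print.element_hierarchy <- function(x, ...) {
  cat("<element_hierarchy> 7 classes, LG =",
      format(x$lg, big.mark = ","), "bp\n")
  print(x$lengths)
  invisible(x)
}

#' Assign positions to genomic element classes
#'
#' Each position takes the first class in priority order whose intervals
#' cover its base; a position matching nothing is intergenic. The resulting
#' labels partition the input.
#'
#' @param positions Position tibble (repeat-filtered breaks or hotspots).
#' @param hierarchy An `element_hierarchy` from [build_hierarchy()].
#' @return `positions` with an added `element` factor column (levels in
#'   priority order).
#' @export
assign_elements <- function(positions, hierarchy) {
  .check_positions(positions)
  stopifnot(inherits(hierarchy, "element_hierarchy"))
  element <- rep(NA_character_, nrow(positions))
  unassigned <- rep(TRUE, nrow(positions))
  for (cl in setdiff(.element_classes, "intergenic")) {
    if (!any(unassigned)) break
    idx <- which(unassigned)
    hit <- .pos_in_intervals(positions[idx, , drop = FALSE],
                             hierarchy$classes[[cl]])
    element[idx[hit]] <- cl
    unassigned[idx[hit]] <- FALSE
  }
  element[unassigned] <- "intergenic"
  out <- positions
  out$element <- factor(element, levels = .element_classes)
  out
}

#' Element odds ratio with binomial test
#'
#' `OR = (M / T) / (L / LG)`: the fraction of positions in an element class
#' over the class's share of non-repeat genome length. The p-value is a
#' two-sided binomial test of `M` successes in `T` trials at probability
#' `L / LG`.
#'
#' @param m Positions in the class (vectorised).
#' @param t_total Total positions.
#' @param l Non-repeat length of the class.
#' @param lg Total non-repeat genome length.
#' @return Tibble `m`, `t_total`, `l`, `lg`, `odds_ratio`, `p_value`.
#'   `L = 0` with `M > 0` yields an infinite odds ratio.
#' @export
element_odds_ratio <- function(m, t_total, l, lg) {
  if (any(t_total <= 0)) abort("`t_total` must be positive")
  if (any(lg <= 0)) abort("`lg` must be positive")
  n <- max(length(m), length(l))
  m <- rep_len(m, n)
  l <- rep_len(l, n)
  t_total <- rep_len(t_total, n)
  lg <- rep_len(lg, n)
  or <- ifelse(l > 0, (m / t_total) / (l / lg),
               ifelse(m > 0, Inf, NA_real_))
  p <- vapply(seq_len(n), function(i) {
    pr <- l[i] / lg[i]
    if (pr < 0 || pr > 1) return(NA_real_)
    binom.test(m[i], t_total[i], p = pr, alternative = "two.sided")$p.value
  }, numeric(1))
  tibble(m = m, t_total = t_total, l = l, lg = lg, odds_ratio = or, p_value = p)
}

#' Per-class enrichment of positions across the element hierarchy
#'
#' Assigns positions hierarchically, then computes each class's odds ratio.
#' `mode = "element"` (default) uses each class's own non-repeat length, as
#' in the OR formula; `mode = "disjoint"` uses priority-subtracted lengths,
#' under which the class lengths partition `LG` exactly like the counts
#' partition `T` (uniform positions then give OR = 1 for every class).
#'
#' @param positions Position tibble.
#' @param hierarchy An `element_hierarchy`.
#' @param mode Length convention, `"element"` or `"disjoint"`.
#' @return Tibble `class`, `m`, `t_total`, `l`, `lg`, `odds_ratio`,
#'   `p_value`.
#' @export
element_enrichment <- function(positions, hierarchy,
                               mode = c("element", "disjoint")) {
  mode <- match.arg(mode)
  assigned <- assign_elements(positions, hierarchy)
  counts <- table(assigned$element)
  l <- if (mode == "element") hierarchy$lengths$l_element else
    hierarchy$lengths$l_disjoint
  res <- element_odds_ratio(as.integer(counts[.element_classes]),
                            nrow(positions), l, hierarchy$lg)
  out <- mutate(res, class = .element_classes, .before = 1)
  attr(out, "mode") <- mode
  out
}
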