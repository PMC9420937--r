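# Operative TSS assignment from CAGE tags.
#
# CAGE tags mark 5' ends of capped transcripts; tags supported by >= 2 reads
# are peaks. For each annotated gene, the operative TSS is the max-depth CAGE
# peak on the gene's strand within +/-200 bp of the annotated start; genes
# without a qualifying peak are considered not expressed and dropped.

#' Combine CAGE tag sets, summing depths at identical positions
#'
#' @param tags A CAGE tag tibble (`chrom`, `pos`, `strand`, `depth`), a list
#'   of them, or a character vector of BED6 paths (read via [read_cage()]).
#' @param genome Optional [genome_model()] passed to [read_cage()] for paths.
#' @return Tibble `chrom`, `pos`, `strand`, `depth` with one row per stranded
#'   position.
#' @export
merge_cage <- function(tags, genome = NULL) {
  if (is.character(tags)) tags <- lapply(tags, read_cage, genome = genome)
  if (is.data.frame(tags)) tags <- list(tags)
  all <- bind_rows(tags)
  if (any(all$depth < 0)) abort("negative CAGE depth")
  out <- summarise(group_by(all, .data$chrom, .data$pos, .data$strand),
                   depth = sum(.data$depth), .groups = "drop")
  arrange(out, .data$chrom, .data$pos, .data$strand)
}

#' Call CAGE peaks by read depth
#'
#' @param tags Merged CAGE tags from [merge_cage()].
#' @param min_depth Minimum supporting read count (default 2).
#' @return The subset of tags with `depth >= min_depth`.
#' @export
call_cage_peaks <- function(tags, min_depth = 2) {
  tags[tags$depth >= min_depth, , drop = FALSE]
}

#' Assign each expressed gene its operative TSS
#'
#' For each gene, qualifying peaks are CAGE peaks on the gene's strand whose
#' position lies within `window` bp (inclusive) of the annotated TSS. The
#' operative TSS is the qualifying peak of maximum depth; depth ties are
#' broken by minimal distance to the annotated TSS, then by the 5'-most
#' coordinate on the gene strand. Genes with no qualifying peak are absent
#' from the result (not expressed).
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `strand`, `tss`
#'   (annotated, 0-based).
#' @param peaks CAGE peaks from [call_cage_peaks()].
#' @param window Maximum distance to the annotated TSS (bp, inclusive).
#' @return Tibble `gene_id`, `chrom`, `strand`, `annotated_tss`, `tss`
#'   (operative), `peak_depth`; one row per expressed gene.
#' @export
assign_tss <- function(genes, peaks, window = 200) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(genes)))
  cand <- left_join(
    select(genes, "gene_id", "chrom", "strand", annotated_tss = "tss"),
    rename(peaks, peak_pos = "pos"),
    by = c("chrom", "strand"),
    relationship = "many-to-many"
  )
  cand <- filter(cand, !is.na(.data$peak_pos),
                 abs(.data$peak_pos - .data$annotated_tss) <= window)
  if (nrow(cand) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), annotated_tss = integer(),
                  tss = integer(), peak_depth = integer()))
  }
  cand <- mutate(cand,
                 dist = abs(.data$peak_pos - .data$annotated_tss),
                 five_prime = ifelse(.data$strand == "+", .data$peak_pos,
                                     -.data$peak_pos))
  cand <- arrange(cand, .data$gene_id, dplyr::desc(.data$depth), .data$dist,
                  .data$five_prime)
  best <- slice(group_by(cand, .data$gene_id), 1L)
  out <- select(ungroup(best), "gene_id", "chrom", "strand",
                "annotated_tss", tss = "peak_pos", peak_depth = "depth")
  arrange(out, .data$chrom, .data$tss)
}

#' Classify break strands as template or non-template
#'
#' Relative to a TSS (or CAGE peak), a break on the opposite strand matches
#' the template strand of the transcript; a break on the same strand matches
#' the non-template (mRNA-like) strand.
#'
#' @param break_strand,tss_strand Character vectors of "+"/"-" (recycled).
#' @return Character vector of "template"/"non_template".
#' @export
classify_strand <- function(break_strand, tss_strand) {
  if (any(!break_strand %in% c("+", "-")) || any(!tss_strand %in% c("+", "-"))) {
    abort("strands must be '+' or '-'")
  }
  ifelse(break_strand == tss_strand, "non_template", "template")
}
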