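# Synthetic breakome study generator.
#
# Emulates the statistical structure of a single-strand-break mapping study:
# a small random genome with RepeatMasker-style masked intervals, genes with
# CAGE-defined TSSs and an expression table, and multiple break replicas
# drawn from a position weight field with (i) a shared set of planted
# hotspot positions at elevated rate, (ii) a promoter-proximal rate boost
# within +/-200 bp of TSSs, and (iii) an optional preference for breaking
# immediately 3' of cytosines, implemented by rejection resampling against
# the generated sequence so that motif analysis sees a genuine signal.

#' Simulation configuration
#'
#' Desk-scale defaults: a 2 x 5 Mb genome, 500 genes, 4 replicas of 1e5
#' unique breaks each — sized so a full synthetic study runs in minutes.
#'
#' @param seed Root integer seed; fixes every emitted object.
#' @param n_chromosomes,chromosome_length Genome dimensions (bp).
#' @param repeat_fraction Fraction of each chromosome masked as repeats.
#' @param repeat_mean_length Mean masked-interval length (bp).
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max gene length (bp).
#' @param exon_count_range Min/max exons per gene.
#' @param n_replicas Break replicas per study.
#' @param breaks_per_replica Unique stranded break positions per replica.
#' @param hotspot_count Number of planted recurrent positions shared across
#'   replicas.
#' @param hotspot_gain Multiplicative sampling weight of a planted position
#'   (>= 1).
#' @param tss_enrichment_factor Multiplicative break-rate boost within
#'   +/-200 bp of each TSS (>= 1).
#' @param cytosine_bias Probability that a sampled break is relocated (by
#'   rejection resampling) to sit immediately 3' of a cytosine on its strand.
#' @param cage_peak_depth_mean Mean depth of each gene's main CAGE peak
#'   (minimum 3).
#' @param cage_noise_tags Low-depth noise CAGE tags per gene.
#' @param expression_coupling Correlation knob in `[0, 1]` between a gene's
#'   promoter break weight and its expression rank.
#' @param expression_log_mean,expression_log_sd Log-normal expression
#'   parameters (FPKM-like).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chromosome_length = 5e6,
                       repeat_fraction = 0.3,
                       repeat_mean_length = 400,
                       n_genes = 500,
                       gene_length_range = c(2000, 20000),
                       exon_count_range = c(1, 6),
                       n_replicas = 4,
                       breaks_per_replica = 1e5,
                       hotspot_count = 2000,
                       hotspot_gain = 1000,
                       tss_enrichment_factor = 2,
                       cytosine_bias = 0.25,
                       cage_peak_depth_mean = 8,
                       cage_noise_tags = 3,
                       expression_coupling = 0.5,
                       expression_log_mean = 2,
                       expression_log_sd = 1.5) {
  cfg <- as.list(environment())
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1) {
    abort("`repeat_fraction` must be in [0, 1]")
  }
  if (cfg$cytosine_bias < 0 || cfg$cytosine_bias > 1) {
    abort("`cytosine_bias` must be in [0, 1]")
  }
  if (cfg$expression_coupling < 0 || cfg$expression_coupling > 1) {
    abort("`expression_coupling` must be in [0, 1]")
  }
  if (cfg$hotspot_gain < 1) abort("`hotspot_gain` must be >= 1")
  if (cfg$tss_enrichment_factor < 1) abort("`tss_enrichment_factor` must be >= 1")
  for (fld in c("n_chromosomes", "chromosome_length", "n_genes", "n_replicas",
                "breaks_per_replica")) {
    if (cfg[[fld]] < 1) abort(sprintf("`%s` must be positive", fld))
  }
  if (cfg$hotspot_count < 0) abort("`hotspot_count` must be >= 0")
  if (cfg$repeat_fraction >= 1 && cfg$n_genes > 0) {
    abort("infeasible config: fully masked genome cannot hold genes")
  }
  structure(cfg, class = "sim_config")
}

# Random composition of `total` into `parts` positive integers.
.composition_pos <- function(total, parts) {
  if (parts == 1) return(total)
  diff(c(0, sort(sample.int(total - 1L, parts - 1L)), total))
}

# Random composition of `total` into `parts` non-negative integers.
.composition_nonneg <- function(total, parts) {
  if (parts == 1) return(total)
  if (total == 0) return(rep(0L, parts))
  cuts <- sort(sample.int(total + parts - 1L, parts - 1L))
  diff(c(0L, cuts, total + parts)) - 1L
}

#' Generate a random genome with masked repeats
#'
#' Repeat intervals are placed by a broken-stick construction so the merged
#' masked length per chromosome equals `round(repeat_fraction *
#' chromosome_length)` exactly. The sequence is i.i.d. uniform over ACGT.
#' Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_model()] with sequence attached.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    len <- as.integer(config$chromosome_length)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    reps <- list()
    seqs <- character(length(chroms))
    for (i in seq_along(chroms)) {
      r_total <- as.integer(round(config$repeat_fraction * len))
      if (r_total > 0) {
        n_int <- max(1L, as.integer(round(r_total / config$repeat_mean_length)))
        n_int <- min(n_int, r_total)
        lens_r <- .composition_pos(r_total, n_int)
        gaps <- .composition_nonneg(len - r_total, n_int + 1L)
        starts <- cumsum(c(gaps[1], head(lens_r, -1) + gaps[-1][seq_len(n_int - 1)]))
        reps[[i]] <- tibble(chrom = chroms[i], start = as.integer(starts),
                            end = as.integer(starts + lens_r))
      }
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
    }
    names(seqs) <- chroms
    genome_model(
      tibble(chrom = chroms, length = len),
      repeats = bind_rows(c(reps, list(.empty_intervals()))),
      sequence = Biostrings::DNAStringSet(seqs)
    )
  })
}

# Draw n distinct positions from intervals, uniform per base, optionally
# keeping accepted positions at least `min_dist` bp apart.
.sample_interval_positions <- function(intervals, n, min_dist = 0,
                                       max_tries = 50) {
  w <- as.numeric(intervals$end - intervals$start)
  acc_chrom <- character(0)
  acc_pos <- integer(0)
  sorted <- list()  # per-chrom sorted accepted positions
  for (try in seq_len(max_tries)) {
    need <- n - length(acc_pos)
    if (need <= 0) break
    m <- ceiling(need * 1.3)
    i <- sample.int(nrow(intervals), m, replace = TRUE, prob = w)
    cand_chrom <- intervals$chrom[i]
    cand_pos <- as.integer(intervals$start[i] + floor(runif(m) * w[i]))
    for (j in seq_len(m)) {
      if (length(acc_pos) >= n) break
      ch <- cand_chrom[j]
      p <- cand_pos[j]
      s <- sorted[[ch]] %||% integer(0)
      k <- findInterval(p, s)
      ok <- (k == 0 || p - s[k] >= max(min_dist, 1L)) &&
        (k == length(s) || s[k + 1L] - p >= max(min_dist, 1L))
      if (ok) {
        sorted[[ch]] <- append(s, p, after = k)
        acc_chrom <- c(acc_chrom, ch)
        acc_pos <- c(acc_pos, p)
      }
    }
  }
  if (length(acc_pos) < n) {
    abort("placement failure: could not draw enough distinct positions")
  }
  tibble(chrom = acc_chrom, pos = acc_pos)
}

#' Generate gene annotation, CAGE tags, expression, and a promoter track
#'
#' Places `n_genes` TSSs in non-repeat space (away from chromosome ends so
#' +/-5 kb windows fit), assigns strands, gene spans and exon structures,
#' and emits: a CAGE tag set whose max-depth peak per gene lies within
#' +/-200 bp of the annotated TSS (depth >= 3, with depth-1/2 noise tags); a
#' chromatin-state-style promoter track (+/-1 kb of each TSS, merged); and a
#' two-replicate log-normal expression table whose rank is coupled to the
#' gene's latent promoter break weight with strength `expression_coupling`.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @return List with `genes`, `cage`, `expression`, `promoters`, and
#'   `gene_truth` (latent promoter weights).
#' @export
simulate_annotation <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_model"))
  withr::with_seed(config$seed + 1L, {
    margin <- 5500L
    nonrep <- complement_intervals(genome$repeats, genome$chromosomes)
    lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    nonrep$start <- pmax(nonrep$start, margin)
    nonrep$end <- pmin(nonrep$end, as.integer(lens[nonrep$chrom]) - margin)
    nonrep <- nonrep[nonrep$end > nonrep$start, , drop = FALSE]
    if (nrow(nonrep) == 0) abort("no non-repeat space for gene placement")
    # TSSs at least 600 bp apart so one gene's CAGE peaks cannot qualify for
    # a neighbour's +/-200 bp window
    tss_pos <- .sample_interval_positions(nonrep, config$n_genes,
                                          min_dist = 600L)
    n <- config$n_genes
    strand <- sample(c("+", "-"), n, replace = TRUE)
    glen <- as.integer(round(runif(n, config$gene_length_range[1],
                                   config$gene_length_range[2])))
    tss <- tss_pos$pos
    chrom <- tss_pos$chrom
    tts <- ifelse(strand == "+", pmin(tss + glen - 1L, lens[chrom] - 1L),
                  pmax(tss - glen + 1L, 0L))
    gene_id <- sprintf("gene%04d", seq_len(n))

    exon_starts <- character(n)
    exon_ends <- character(n)
    for (i in seq_len(n)) {
      s <- min(tss[i], tts[i])
      e <- max(tss[i], tts[i]) + 1L   # half-open span
      n_ex <- sample(seq(config$exon_count_range[1],
                         config$exon_count_range[2]), 1)
      if (n_ex > 1 && (e - s) > 2L * n_ex) {
        bp <- sort(sample((s + 1L):(e - 1L), 2L * (n_ex - 1L)))
        bounds <- c(s, bp, e)
        ex_s <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ex_e <- bounds[seq(2, length(bounds), by = 2)]
      } else {
        ex_s <- s
        ex_e <- e
      }
      exon_starts[i] <- paste(ex_s, collapse = ",")
      exon_ends[i] <- paste(ex_e, collapse = ",")
    }
    genes <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                    tss = tss, tts = as.integer(tts),
                    exon_starts = exon_starts, exon_ends = exon_ends)

    # Latent promoter break weight (mean-1 log-normal) and coupled expression.
    z_w <- rnorm(n)
    promoter_weight <- exp(0.5 * z_w - 0.125)
    rho <- config$expression_coupling
    z_e <- rho * z_w + sqrt(1 - rho^2) * rnorm(n)
    fpkm <- exp(config$expression_log_mean + config$expression_log_sd * z_e)
    expression <- tibble(
      gene_id = gene_id,
      fpkm_r1 = fpkm * exp(rnorm(n, 0, 0.1)),
      fpkm_r2 = fpkm * exp(rnorm(n, 0, 0.1))
    )
    expression$expression <- rowMeans(expression[c("fpkm_r1", "fpkm_r2")])

    # CAGE: one dominant peak near each annotated TSS plus noise tags.
    main_off <- pmax(pmin(as.integer(round(rnorm(n, 0, 60))), 200L), -200L)
    main_pos <- pmin(pmax(tss + main_off, 0L), as.integer(lens[chrom]) - 1L)
    # floor 5 keeps the planted peak dominant even if two depth-2 noise tags
    # collide at one position
    main_depth <- 5L + rpois(n, max(config$cage_peak_depth_mean - 5, 0))
    k <- config$cage_noise_tags
    noise_chrom <- rep(chrom, k)
    noise_pos <- pmin(pmax(rep(tss, k) +
                             as.integer(round(rnorm(n * k, 0, 400))), 0L),
                      as.integer(lens[noise_chrom]) - 1L)
    noise <- tibble(
      chrom = noise_chrom,
      pos = noise_pos,
      strand = rep(strand, k),
      depth = 1L + rbinom(n * k, 1L, 0.15)
    )
    cage <- bind_rows(
      tibble(chrom = chrom, pos = main_pos, strand = strand,
             depth = main_depth),
      noise
    )
    cage <- merge_cage(cage)

    promoters <- merge_intervals(tibble(
      chrom = chrom, start = pmax(tss - 1000L, 0L),
      end = pmin(tss + 1001L, as.integer(lens[chrom]))
    ))

    list(
      genes = genes, cage = cage, expression = expression,
      promoters = promoters,
      gene_truth = tibble(gene_id = gene_id, z_w = z_w,
                          promoter_weight = promoter_weight, fpkm = fpkm,
                          main_cage_pos = main_pos)
    )
  })
}

# Base at position 0 of each break (the base 5' of the nick, on the break's
# strand).
.base_at_break <- function(genome, chrom, pos, strand) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- Biostrings::Views(genome$sequence[[ch]], start = pos[idx] + 1L,
                           width = 1L)
    b <- toupper(as.character(v))
    minus <- strand[idx] == "-"
    b[minus] <- chartr("ACGT", "TGCA", b[minus])
    out[idx] <- b
  }
  out
}

#' Generate multi-replica breakomes with planted structure
#'
#' Each replica draws `breaks_per_replica` unique stranded positions from a
#' weight field over non-repeat space: baseline 1, multiplied by
#' `tss_enrichment_factor` times the gene's latent promoter weight within
#' +/-200 bp of each gene's operative TSS (dominant CAGE peak), and
#' `hotspot_gain` on `hotspot_count` planted
#' stranded positions shared by all replicas. With probability
#' `cytosine_bias`, a (non-hotspot) draw is relocated by redrawing until its
#' position-0 base is a cytosine on its strand. Draws are deduplicated and
#' topped up until the replica holds exactly its unique-position quota.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @param annotation Annotation from [simulate_annotation()].
#' @return List with `replicas` (named list of position tibbles) and `truth`
#'   (planted hotspot positions with weights).
#' @export
simulate_breakome <- function(config, genome, annotation) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_model"))
  nonrep <- complement_intervals(genome$repeats, genome$chromosomes)
  if (2 * genome$lg < config$breaks_per_replica) {
    abort("`breaks_per_replica` exceeds available stranded non-repeat positions")
  }
  genes <- annotation$genes
  gw <- annotation$gene_truth$promoter_weight
  # Boost is centred on the gene's operative TSS (its dominant CAGE peak):
  # breaks concentrate at the start site actually used, which is what the
  # downstream enrichment measures.
  center <- annotation$gene_truth$main_cage_pos
  # Window weight 1 + (f-1) * m_g: exactly uniform at f = 1, mean f across
  # genes, with per-gene heterogeneity m_g (mean 1) carrying the expression
  # coupling.
  windows <- tibble(chrom = genes$chrom,
                    start = pmax(center - 200L, 0L),
                    end = center + 201L,
                    weight = 1 + (config$tss_enrichment_factor - 1) * gw)

  # Disjoint weighted segments: window pieces override baseline; the first
  # gene claims any (rare) window overlap.
  segs <- list()
  claimed <- .empty_intervals()
  for (i in seq_len(nrow(windows))) {
    piece <- .setdiff_intervals(
      merge_intervals(windows[i, c("chrom", "start", "end")]), claimed)
    piece <- .clip_intervals(piece, genome)
    if (nrow(piece) > 0) {
      # keep only non-repeat bases
      kept <- bind_rows(lapply(seq_len(nrow(piece)), function(j) {
        sub <- nonrep[nonrep$chrom == piece$chrom[j], , drop = FALSE]
        r <- IRanges::intersect(
          .as_iranges(piece$start[j], piece$end[j]),
          .as_iranges(sub$start, sub$end))
        tibble(chrom = piece$chrom[j], start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
      }))
      if (nrow(kept) > 0) {
        kept$weight <- windows$weight[i]
        segs[[length(segs) + 1]] <- kept
      }
      claimed <- merge_intervals(bind_rows(claimed,
                                           piece[c("chrom", "start", "end")]))
    }
  }
  base <- .setdiff_intervals(nonrep, claimed)
  base$weight <- 1
  segs <- bind_rows(c(segs, list(base)))
  seg_w <- segs$weight * as.numeric(segs$end - segs$start) * 2  # two strands

  draw_segments <- function(m) {
    i <- sample.int(nrow(segs), m, replace = TRUE, prob = seg_w)
    w <- as.numeric(segs$end[i] - segs$start[i])
    tibble(chrom = segs$chrom[i],
           pos = as.integer(segs$start[i] + floor(runif(m) * w)),
           strand = sample(c("+", "-"), m, replace = TRUE))
  }

  apply_cytosine_bias <- function(draws) {
    if (config$cytosine_bias == 0 || nrow(draws) == 0) return(draws)
    relocate <- runif(nrow(draws)) < config$cytosine_bias
    idx <- which(relocate)
    tries <- 0
    while (length(idx) > 0 && tries < 20) {
      b <- .base_at_break(genome, draws$chrom[idx], draws$pos[idx],
                          draws$strand[idx])
      bad <- idx[b != "C"]
      if (length(bad) == 0) break
      repl <- draw_segments(length(bad))
      draws[bad, c("chrom", "pos", "strand")] <- repl
      idx <- bad
      tries <- tries + 1
    }
    draws
  }

  out <- withr::with_seed(config$seed + 2L, {
    hotspots <- if (config$hotspot_count > 0) {
      hp <- .sample_interval_positions(nonrep, config$hotspot_count)
      hp$strand <- sample(c("+", "-"), nrow(hp), replace = TRUE)
      hp
    } else tibble(chrom = character(), pos = integer(), strand = character())
    hot_keys <- .pos_key(hotspots)

    replicas <- lapply(seq_len(config$n_replicas), function(r) {
      b <- config$breaks_per_replica
      have <- tibble(chrom = character(), pos = integer(), strand = character())
      for (round in seq_len(60)) {
        need <- b - nrow(have)
        if (need <= 0) break
        m <- ceiling(need * 1.05)
        # only hotspots not yet drawn keep their weight (sampling is without
        # replacement within a replica)
        undrawn <- which(!hot_keys %in% .pos_key(have))
        hot_w <- config$hotspot_gain * length(undrawn)
        n_hot <- if (hot_w > 0) {
          min(rbinom(1, m, hot_w / (hot_w + sum(seg_w))), m)
        } else 0L
        cand <- draw_segments(m - n_hot)
        cand <- apply_cytosine_bias(cand)
        if (n_hot > 0) {
          hi <- undrawn[sample.int(length(undrawn), n_hot, replace = TRUE)]
          cand <- bind_rows(cand, hotspots[hi, , drop = FALSE])
        }
        have <- distinct(bind_rows(have, cand),
                         .data$chrom, .data$pos, .data$strand)
      }
      if (nrow(have) < b) abort("could not reach breaks_per_replica unique positions")
      have <- have[seq_len(b), , drop = FALSE]
      have$replica <- sprintf("replica_%d", r)
      arrange(have, .data$chrom, .data$pos, .data$strand)
    })
    names(replicas) <- sprintf("replica_%d", seq_len(config$n_replicas))
    truth <- hotspots
    truth$weight <- config$hotspot_gain
    truth$is_hotspot <- TRUE
    list(replicas = replicas, truth = truth)
  })
  out
}

#' Run the full synthetic study
#'
#' Convenience wrapper: genome, annotation, breakome; optionally writes every
#' artifact in the formats the readers consume (FASTA, BED, TSV).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if missing.
#' @return List `config`, `genome`, `annotation`, `replicas`, `truth`, and
#'   (when written) `files`.
#' @export
simulate_breakome_study <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(config, genome)
  breakome <- simulate_breakome(config, genome, annotation)
  out <- list(config = config, genome = genome, annotation = annotation,
              replicas = breakome$replicas, truth = breakome$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      fasta = file.path(dir, "genome.fa"),
      repeats = file.path(dir, "repeats.bed"),
      genes = file.path(dir, "genes.tsv"),
      cage = file.path(dir, "cage.bed"),
      expression = file.path(dir, "expression.tsv"),
      promoters = file.path(dir, "promoters.bed"),
      truth = file.path(dir, "truth.tsv")
    )
    write_fasta_genome(genome, files$fasta)
    write_intervals(genome$repeats, files$repeats)
    readr::write_tsv(annotation$genes, files$genes)
    cage_bed <- sprintf("%s\t%d\t%d\ttag\t%d\t%s", annotation$cage$chrom,
                        annotation$cage$pos, annotation$cage$pos + 1L,
                        annotation$cage$depth, annotation$cage$strand)
    readr::write_lines(cage_bed, files$cage)
    readr::write_tsv(annotation$expression, files$expression)
    write_intervals(annotation$promoters, files$promoters)
    readr::write_tsv(out$truth, files$truth)
    for (r in names(out$replicas)) {
      f <- file.path(dir, paste0(r, ".bed"))
      write_positions(out$replicas[[r]], f)
      files[[r]] <- f
    }
    out$files <- files
  }
  out
}
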