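---
title: "Methods: hotspot calling and TSS enrichment for single-strand breakomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot calling and TSS enrichment for single-strand breakomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakome)
```

## The analysis

`breakome` analyses genome-wide maps of single-strand DNA breaks (SSBs)
called at single-nucleotide resolution, as produced by 3'-OH-tagging assays.
Each break record is a stranded base: a nick between bases N and M in
5'-NM-3' on a strand is assigned to base N (0-based coordinate of N,
BED-native half-open intervals throughout). All statistics operate on
*unique* positions per biological replica — a position is counted once no
matter how many reads supported it — and positions inside RepeatMasker-style
repeat intervals are removed first. Position identity includes the strand:
the same base on opposite strands is two positions, because the downstream
template/non-template analysis needs stranded breaks.

The pipeline has six analytical stages, each usable on its own tibbles:

1. **Hotspots.** A hotspot is a position carrying breaks in at least
   `min_support` (default 2) replicas of a cell type. `build_support()`
   counts replica multiplicity over the union of positions;
   `call_hotspots()` thresholds it. Chance-level sharing is estimated by
   `simulate_null()`: each of (default) 100 simulations redraws every
   replica uniformly *without replacement* from the detectable position
   space and records the shared fraction. `hotspot_significance()` runs a
   two-sided one-sample Student t-test of the 100 simulated fractions
   against the observed fraction — the only arrangement with 100
   exchangeable values. A zero-variance null degenerates to an exact
   comparison (p = 1 on equality, else p = 0), flagged in the result.
2. **Operative TSSs.** CAGE tags with summed depth >= 2 are peaks; a gene's
   operative TSS is the maximum-depth peak on the gene's own strand within
   +/-200 bp (inclusive) of its annotated start. Genes without a qualifying
   peak are treated as not expressed and dropped. Depth ties break by
   distance to the annotated start, then by the 5'-most coordinate on the
   gene strand; these tie-breaks are conventions fixed for determinism. A
   break on the strand opposite a TSS is a *template*-strand match; on the
   same strand, *non-template*.
3. **TSS density and enrichment.** Every break gets the signed distance to
   its nearest operative TSS (negative upstream in gene orientation;
   distance ties resolve toward the lower genomic coordinate). The
   +/-5,000 bp window is split into 500 20-bp bins — bin boundaries are
   half-open with the TSS base at offset 0 in the bin covering [0, 20) —
   and per-bin densities are normalised by the average non-repeat fraction
   of the bin across expressed genes (`NR_j`) and by the sample's total
   unique-position count `T`: `D_j = N_j * 1e6 / (NR_j * T)`. `T` counts
   positions genome-wide, not in-window, so profiles are comparable across
   samples with different TSS proximity. Bins with `NR_j = 0` are reported
   as missing, not zero. The enrichment ratio is
   `R = (M200 / M5000) / (L200 / L5000)` with a two-sided binomial test of
   `M200` successes in `M5000` trials at probability `L200 / L5000` —
   conditioning on in-window breaks matches the ratio's structure.
4. **Element hierarchy.** Seven classes consulted strictly in order —
   TSS+/-200, CAGE-peak+/-200, chromatin-state promoter, TTS+/-200, exon,
   intron, intergenic — partition every position; exon/intron/TTS come from
   the longest transcript of every annotated gene irrespective of
   expression. Per class, `OR = (M/T) / (L/LG)` with a two-sided binomial
   test; `L` is the class's own non-repeat length by default, with a
   priority-subtracted ("disjoint") variant for calibration (below).
5. **Expression link.** Genes are ranked by mean expression and cut into
   nested top-5/10/25/50% strata (stratum sizes round half-up; ties break by
   gene id). Observed fractions of breaks within +/-200 bp and within the
   200-5,000 bp annulus of each stratum's TSSs are divided by the fractions
   expected for uniform random positions in non-repeat space, giving
   observed/expected odds ratios. Series of odds ratios are compared by a
   one-sided equal-variance t-test.
6. **Sequence context.** The +/-5 bp context of a break spans labels -4..5,
   with 0 the base immediately 5' of the nick on the break's strand
   (minus-strand contexts are reverse-complemented). Contexts with
   ambiguity codes are dropped and counted; soft-masked lowercase is
   uppercased, since repeat handling belongs to the repeat filter.
   `frequency_matrix()` emits counts, frequencies and information content
   (`2 + sum f log2 f` bits); `cg_ratio()` reports the C/G frequency ratio
   at positions -1 and 0, where cytosine preference concentrates.

## Choices where the design was genuinely open

**Null sampling space.** The Monte-Carlo null draws from `S = 2 * LG`
stranded non-repeat positions — the full detectable space, the
least-assuming choice. `S` is an explicit argument so a pool restricted to
observed positions can be swapped in for sensitivity analysis.

**L-window accounting.** `M200`/`M5000` count positions by *nearest*-TSS
distance, i.e. on the union of per-gene windows. The default `L` lengths
(`l_mode = "nearest"`) are measured on that same union, so uniform breaks
give `R = 1` at any gene density. The alternative (`l_mode = "per_gene"`)
sums window lengths gene by gene, mirroring the per-gene construction of
`NR_j`; the two agree when gene windows rarely overlap (true at mammalian
genome scale, not at desk scale, where +/-5 kb windows tile a small genome
densely). The per-gene mode exists because both conventions are defensible
readings of the ratio's length terms.

**Recovering a planted rate factor.** If the break rate is multiplied by
`f` inside the +/-200 bp window, the expected ratio is
`R = f / (1 + (f - 1) p)` with `p = L200/L5000`, because the background
window contains the enriched window. `recover_enrichment_factor()` inverts
this mapping (`f = R (1 - p) / (1 - R p)`); comparing `R` itself to `f`
would conflate the estimator's built-in saturation (about 14% at `f = 5`)
with estimation error.

**Element-OR calibration mode.** Hierarchical assignment moves positions
from low-priority classes into high-priority ones, so with own-class
lengths a uniform breakome yields ORs slightly below 1 for exon-like
classes — a property of the formula, not a bug. The `"disjoint"` length
mode subtracts higher-priority intervals from each class, making class
lengths partition `LG` exactly as counts partition `T`; uniform breaks then
give OR = 1 for every class. Calibration checks use the disjoint mode;
reported analyses default to own-class lengths, matching the OR formula's
definition of an element's length.

**Treatment comparisons.** Per-sample enrichment ratios pool both strands;
groups are compared to the reference by a two-sided Welch t-test (robust to
unequal spread across treatment groups, with so few samples per group).

## The synthetic-data generator

`sim_config()` fixes the study conditions; every emitted object is a pure
function of the seed. Desk-scale defaults: 2 chromosomes x 5 Mb, 30% of
each chromosome masked as repeats (mean masked interval 400 bp; the masked
total per chromosome is hit exactly by a broken-stick construction), 500
genes (TSSs >= 600 bp apart in non-repeat space, away from chromosome
ends), 4 replicas of 1e5 unique stranded breaks. These sizes keep a full
study in the low minutes on one core while leaving binomial noise on the
headline statistics at the percent level.

Planted structure, each independently tunable:

* **Recurrence.** `hotspot_count = 2000` positions (about 1-2% of the
  unique positions a study yields, the order observed in real breakomes)
  carry `hotspot_gain = 1000` times the baseline sampling weight in every
  replica. Within a replica, sampling is without replacement: draws are
  deduplicated and topped up, and already-drawn planted positions lose
  their excess weight.
* **Promoter enrichment.** Within +/-200 bp of each gene's *operative* TSS
  (its dominant CAGE peak — the quantity downstream analyses measure), the
  break rate is multiplied by `1 + (f - 1) m_g`, where
  `f = tss_enrichment_factor` (default 2) and `m_g` is a mean-1 log-normal
  per-gene weight. At `f = 1` the field is exactly uniform; the mean boost
  is exactly `f`.
* **Expression coupling.** Gene expression is log-normal with its latent
  Gaussian correlated to `m_g` at strength `expression_coupling` (default
  0.5); at 0 the two are independent.
* **Cytosine preference.** With probability `cytosine_bias` (default
  0.25), a non-hotspot draw is redrawn until its position-0 base is a
  cytosine on its strand — rejection resampling against the emitted
  sequence, so the motif module sees a genuine sequence signal rather than
  a label.
* **CAGE.** Each gene gets one dominant peak (depth >= 5, within
  +/-200 bp of the annotated TSS, offset sd 60 bp) plus low-depth noise
  tags (depth 1-2); the dominant peak is guaranteed to win peak calling,
  so the planted operative TSS is recoverable exactly.

What the generator does **not** emulate: library chemistry, PCR and
sequencing error, mappability structure beyond repeat masking, realistic
gene/isoform architecture (one transcript per gene, uniform base
composition), chromatin-state heterogeneity, or inter-replica batch
effects. Passing tests on synthetic data therefore demonstrate the
*statistical machinery* — counting, normalisation, calibration, recovery of
planted effects — not robustness to the full messiness of real sequencing
data.

## Numerical conventions and degenerate inputs

* "Within +/-200 bp" is inclusive (|d| <= 200) everywhere: TSS assignment,
  M counts, element windows.
* Percentages in summary tables round half-up to one decimal.
* Degenerate nulls (zero variance) and zero-variance group comparisons
  return exact-comparison p-values with a `degenerate` flag rather than
  erroring.
* `L = 0` with breaks present yields an infinite odds ratio, flagged by
  value; expected fraction 0 with observed > 0 likewise.
* Windows running past a chromosome end are clipped (lengths) or dropped
  and counted (sequence contexts).

## Problem sizes used by the tests and the acceptance script

Formula identities and oracle-equivalence checks run on toy genomes (kilo-
to megabase scale, exhaustive enumeration where the oracle demands it).
Calibration and recovery checks run at the generator's default scale:
4 x 1e5 breaks on a 10 Mb genome with 500 genes, 100 null simulations, 1e5
random positions for expected fractions. At that scale the neutral
enrichment ratio sits within ~1% of 1, planted factors 2 and 5 are
recovered within a few percent, and all 2,000 planted hotspots are
recovered at support >= 2.

## Known limitations

* The Monte-Carlo null assumes uniform breakability of the non-repeat
  genome; real nulls likely carry sequence- and chromatin-composition
  structure.
* Sharing a single genome-wide `T` between strand classes means per-class
  densities are comparable within a sample but are not per-class rates.
* At extreme `hotspot_gain`, the without-replacement topping-up makes the
  realised per-position inclusion probabilities saturate; planted weights
  are recovered as presence/recurrence, not as exact rates.
* The expression link treats strata odds ratios as the unit of comparison;
  per-gene paired designs would need the underlying per-gene indicator
  data, which the module does not retain.
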