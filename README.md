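# breakome

Analysis of genome-wide single-strand DNA break (SSB) maps at
single-nucleotide resolution — for labs running 3′-OH-tagging break-mapping
assays (SSiNGLe, GLOE-seq and kin) who want to ask: *do breaks recur at the
same genomic positions across biological replicas, and do those recurrent
positions concentrate around transcription start sites?*

The package takes already-called, stranded break positions (BED) plus the
usual annotation sidecars — RepeatMasker intervals, CAGE tags, gene models,
a chromatin-state promoter track, a per-gene expression table, the genome
FASTA — and provides, as pipeable tibble-in/tibble-out functions:

* **Hotspot calling.** A hotspot is a unique position carrying breaks in
  ≥ 2 replicas. Sharing is tested against a Monte-Carlo null: 100
  simulations redraw each replica uniformly without replacement from the
  2·L<sub>G</sub> stranded non-repeat positions (L<sub>G</sub> = non-repeat
  genome length), followed by a two-sided one-sample Student t-test.
* **Operative TSSs from CAGE.** Tags with depth ≥ 2 are peaks; a gene's
  operative TSS is the max-depth peak on its strand within ±200 bp of the
  annotated start. Breaks on the strand opposite a TSS are
  *template*-strand matches; same strand, *non-template*.
* **TSS metagene densities and enrichment.** Signed nearest-TSS distances,
  binned into 500 × 20-bp bins over ±5 kb and normalised per bin by the
  average non-repeat fraction NR<sub>j</sub> and the sample total
  T<sub>i</sub>:
  D<sub>ij</sub> = N<sub>ij</sub>·10⁶ / (NR<sub>j</sub>·T<sub>i</sub>).
  The promoter enrichment ratio
  R<sub>i</sub> = (M<sub>i</sub><sup>200</sup>/M<sub>i</sub><sup>5000</sup>) /
  (L<sup>200</sup>/L<sup>5000</sup>)
  compares break rates within ±200 bp to the ±5 kb background, with a
  two-sided binomial test.
* **Hierarchical element odds ratios.** Every break takes the first
  matching class of TSS±200 → CAGE-peak±200 → promoter → TTS±200 → exon →
  intron → intergenic;
  OR<sub>i</sub> = (M<sub>i</sub>/T<sub>i</sub>) / (L<sub>i</sub>/L<sub>G</sub>)
  per class with binomial tests.
* **Expression link.** Observed/expected odds ratios of breaks within
  ±200 bp and 200–5,000 bp of the TSSs of the top 5/10/25/50% expressed
  genes, against uniform random positions in non-repeat space.
* **Break sequence context.** Stranded ±5 bp context matrices (position 0
  = the base 5′ of the nick), information content for logo rendering, and
  C/G ratios at positions −1 and 0, where cytosine preference concentrates.
* **A synthetic-study generator** (`sim_config()`,
  `simulate_breakome_study()`) that plants recurrent hotspots, promoter
  enrichment, expression coupling and a genuine sequence-level cytosine
  bias into a seeded model genome, so the whole pipeline is testable
  without downloads, and `run_pipeline()` to drive every stage from one
  YAML config with a checksummed manifest.

## Worked example

A small synthetic study — one 2 Mb chromosome, 120 genes, three replicas of
40,000 unique breaks, 500 planted hotspots:

```r
library(breakome)
library(dplyr)

cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 2e6,
                  n_genes = 120, n_replicas = 3, breaks_per_replica = 4e4,
                  hotspot_count = 500)
study <- simulate_breakome_study(cfg)

breaks   <- bind_rows(study$replicas)
support  <- build_support(breaks)
hotspots <- call_hotspots(support, min_support = 2)
nrow(hotspots)                     # 2412
hotspot_fraction(support)          # 0.0206

null <- simulate_null(3, sapply(study$replicas, nrow),
                      space_size = 2 * study$genome$lg, seed = 2)
glance(hotspot_significance(hotspot_fraction(support), null))
#>   observed null_mean  null_sd statistic    df   p_value degenerate
#> 1   0.0206    0.0143 0.000329     -191.    99 7.53e-129 FALSE
```

2.1% of unique positions recur in ≥ 2 replicas against a chance level of
1.43% — the planted 500 hotspots plus the coincidental overlaps a 2 Mb
genome inevitably produces; the excess is wildly significant.

```r
tss <- study$annotation$genes |>
  assign_tss(call_cage_peaks(study$annotation$cage))
enrichment_ratio(breaks, tss, study$genome)
#>   strand_class m_inner m_outer    ratio       p_value
#> 1     combined    6968   58681 1.845851 4.940656e-324
#> 2     template    3423   29532 1.801772 1.117022e-234
#> 3 non_template    3545   29149 1.890508 2.453639e-280
```

Breaks within ±200 bp of operative TSSs run at ~1.85× the ±5 kb background
rate on both strands — the generator's planted factor is 2, and
`recover_enrichment_factor()` inverts the ratio's built-in background
dilution to read it back.

```r
frequency_matrix(extract_contexts(hotspots, study$genome)) |> cg_ratio()
#>   position   f_c   f_g cg_ratio
#> 1       -1 0.262 0.233     1.13
#> 2        0 0.542 0.149     3.63
```

Hotspot breaks sit immediately 3′ of a cytosine far more often than the
uniform-sequence background (f(C) = 0.54 at position 0, C/G = 3.6): the
planted 25% cytosine relocation bias, concentrated in recurrent positions.

See `vignettes/breakome-methods.Rmd` for the model details, parameter
semantics and the reasoning behind the numerical conventions.

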