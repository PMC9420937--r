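# Lazily built synthetic studies shared across test files. Configurations
# are the generator's study conditions; seeds are fixed fixture seeds.

.study_cache <- new.env(parent = emptyenv())

get_study <- function(name = c("default", "neutral", "f5")) {
  name <- match.arg(name)
  if (!is.null(.study_cache[[name]])) return(.study_cache[[name]])
  cfg <- switch(name,
    default = sim_config(seed = 42),
    neutral = sim_config(seed = 43, tss_enrichment_factor = 1,
                         hotspot_gain = 1, cytosine_bias = 0,
                         expression_coupling = 0),
    f5 = sim_config(seed = 44, tss_enrichment_factor = 5, hotspot_gain = 1,
                    cytosine_bias = 0)
  )
  st <- simulate_breakome_study(cfg)
  st$pooled <- dplyr::bind_rows(st$replicas)
  st$dedup <- dplyr::distinct(st$pooled, chrom, pos, strand)
  st$peaks <- call_cage_peaks(st$annotation$cage)
  st$tss <- assign_tss(st$annotation$genes, st$peaks)
  .study_cache[[name]] <- st
  st
}
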