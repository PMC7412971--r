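# Reduced-size generator configuration for fast unit tests; the
# acceptance suite uses the full default study conditions.
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_tumor = 80L, n_normal = 12L, n_genes = 40L,
             n_probes_per_gene = 2L, n_tfs = 4L,
             n_planted_triplets = 2L, ...)
}
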