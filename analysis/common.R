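# Shared setup for the analysis drivers: two synthetic Alu-like libraries,
# assay-scale simulation settings, and output locations. Sourced by every
# numbered script so each stage can be rerun independently.

library(alujump)

an_seed <- 20250919L
an_dir <- "results/analysis"
dir.create(an_dir, recursive = TRUE, showWarnings = FALSE)

an_refs <- list(
  AluSyn1 = synthetic_alu_reference("AluSyn1", seed = 20240517L),
  AluSyn2 = synthetic_alu_reference("AluSyn2", seed = 20240518L))

an_sheet <- default_sample_sheet(2L)

# library-scale settings: 800 clones per element, 20,000 reads per sample,
# two replicates, 2.2% index hopping, 1% short-fragment artifacts
an_config <- function(reference, offset) {
  sim_config(reference,
             n_clones = 800L, depth = 2e4, dispersion = 0.01,
             effect_in_region = c(mean = 0, sd = 2),
             effect_out_region = c(mean = 0, sd = 0.25),
             hop_rate = 0.022, short_frag_rate = 0.01,
             seed = an_seed + offset)
}

an_path <- function(...) file.path(an_dir, paste0(...))
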