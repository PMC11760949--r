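#!/usr/bin/env Rscript
# Molecule-level quality control and IPD threshold deconvolution on the
# wild-type batch: passes >= 20, removal of globally dispersed molecules
# (SD of unmethylated-adenine IPD ratios >= 0.35 on either strand) and of
# molecules with high-density N* clusters, then a 2-component mixture fit
# on ln(IPD) of ApT-context adenines to place the 6mA calling cutoff.

suppressPackageStartupMessages({
  library(sixma)
  library(data.table)
})
dir.create("results", showWarnings = FALSE)

genome <- make_genome(seed = 101, chrom_len = 30000, n_genes = 8,
                      apt_density = 100)
sim <- simulate_molecules(genome, preset_6ma("WT"), n_molecules = 3000,
                          mean_len = 800, seed = 102)

qc <- run_qc(sim$molecules)
print(qc$report)
flags <- sim$truth$molecules
removed <- qc$per_molecule[reason != "retained", molecule_id]
cat(sprintf("recall of injected dispersed molecules: %.3f\n",
            mean(flags[dispersed == TRUE, molecule_id] %in% removed)))
cat(sprintf("recall of injected N* molecules: %.3f\n",
            mean(flags[nstar == TRUE, molecule_id] %in% removed)))
fwrite(qc$report, "results/qc_report.tsv", sep = "\t")
fwrite(qc$per_molecule, "results/qc_per_molecule.tsv", sep = "\t")

pool <- apt_adenine_ipds(qc$molecules, genome)
cat(sprintf("threshold fit on %d ApT adenine IPD observations\n", length(pool)))
thr <- fit_ipd_threshold(pool, seed = 103)
print(thr)
fwrite(data.table(cutoff = thr$cutoff, bimodal = thr$bimodal,
                  loglik = thr$loglik, n_used = thr$n_used),
       "results/threshold.tsv", sep = "\t")
fwrite(thr$components, "results/threshold_components.tsv", sep = "\t")
cat("wrote results/qc_report.tsv, qc_per_molecule.tsv, threshold*.tsv\n")
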