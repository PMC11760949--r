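#!/usr/bin/env Rscript
# Build the synthetic study inputs: an AT-rich genome with known ApT sites,
# gene models, and a wild-type batch of SMRT-CCS single molecules with
# per-position IPD ratios. Writes the annotation (BED), a down-sampled
# molecule table (TSV) and the ground-truth summaries under results/.

suppressPackageStartupMessages({
  library(sixma)
  library(data.table)
})
dir.create("results", showWarnings = FALSE)
set.seed(NULL)

genome <- make_genome(seed = 101, chrom_len = 30000, n_genes = 8,
                      apt_density = 100)
print(genome)
write_genome_beds(genome, "results/genes.bed", "results/apt_sites.bed")

wt <- preset_6ma("WT")
print(wt)

sim <- simulate_molecules(genome, wt, n_molecules = 3000, mean_len = 800,
                          seed = 102)
print(sim)

truth_sites <- sim$truth$sites
cat(sprintf("methylation sites: %d of %d ApT duplexes (true 6mApT/ApT %.2f%%)\n",
            sum(truth_sites$meth), nrow(truth_sites),
            100 * sim$truth$genome_fraction))
cat(sprintf("molecule artifacts injected: %d dispersed, %d with N* clusters\n",
            sum(sim$truth$molecules$dispersed), sum(sim$truth$molecules$nstar)))

# a readable slice of the long molecule table (first 200 molecules)
write_molecules_tsv(sim$molecules[molecule_id <= 200],
                    "results/molecules_sample.tsv")
fwrite(sim$truth$sites, "results/truth_sites.tsv", sep = "\t")
fwrite(sim$truth$genes, "results/truth_genes.tsv", sep = "\t")
fwrite(sim$truth$molecules, "results/truth_molecules.tsv", sep = "\t")
cat("wrote results/genes.bed, apt_sites.bed, molecules_sample.tsv, truth_*.tsv\n")
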