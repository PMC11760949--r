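test_that("generated genomes satisfy the ApT and gene-packing invariants", {
  g <- make_genome(seed = 1, chrom_len = 50000, n_genes = 10, apt_density = 100)
  seqv <- g$chroms$chr1
  # every ApT site is A followed by T, and these are the only ApT dinucleotides
  expect_true(all(seqv[g$apt$pos + 1L] == "A"))
  expect_true(all(seqv[g$apt$pos + 2L] == "T"))
  all_apt <- which(seqv[-length(seqv)] == "A" & seqv[-1L] == "T") - 1L
  expect_setequal(all_apt, g$apt$pos)
  expect_equal(nrow(g$apt), round(100 * 50000 / 1000))
  # genes: inside bounds, non-overlapping
  gs <- g$genes[order(start)]
  expect_equal(nrow(gs), 10L)
  expect_true(all(gs$start >= 0 & gs$end <= 50000))
  expect_true(all(gs$start[-1] >= gs$end[-10]))
})

test_that("genome generation is deterministic in the seed and flags no-ApT genomes", {
  g1 <- make_genome(seed = 7, chrom_len = 20000, n_genes = 5, apt_density = 50)
  g2 <- make_genome(seed = 7, chrom_len = 20000, n_genes = 5, apt_density = 50)
  expect_identical(g1$chroms, g2$chroms)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$apt, g2$apt)
  g3 <- make_genome(seed = 7, chrom_len = 20000, n_genes = 5, apt_density = 60)
  expect_false(identical(g1$apt, g3$apt))

  g0 <- make_genome(seed = 3, chrom_len = 5000, n_genes = 1, apt_density = 0)
  expect_equal(nrow(g0$apt), 0L)
  sim <- simulate_molecules(g0, preset_6ma("WT"), 10, mean_len = 600, seed = 1)
  res <- analyze_molecules(sim, g0, seed = 1)
  expect_true(is.na(res$fraction))
})

test_that("molecule simulation is a pure function of its seed", {
  g <- make_genome(seed = 2, chrom_len = 10000, n_genes = 3, apt_density = 80)
  s1 <- simulate_molecules(g, preset_6ma("WT"), 50, mean_len = 600, seed = 9)
  s2 <- simulate_molecules(g, preset_6ma("WT"), 50, mean_len = 600, seed = 9)
  expect_identical(s1$molecules, s2$molecules)
  expect_identical(s1$truth$sites, s2$truth$sites)
  s3 <- simulate_molecules(g, preset_6ma("WT"), 50, mean_len = 600, seed = 10)
  expect_false(identical(s1$molecules, s3$molecules))

  empty <- simulate_molecules(g, preset_6ma("WT"), 0, mean_len = 600, seed = 1)
  expect_equal(nrow(empty$molecules), 0L)

  # a shared site_seed pins the methylation-site model across batches while
  # molecules stay independent
  b1 <- simulate_molecules(g, preset_6ma("WT"), 50, mean_len = 600,
                           seed = 9, site_seed = 77)
  b2 <- simulate_molecules(g, preset_6ma("WT"), 50, mean_len = 600,
                           seed = 10, site_seed = 77)
  expect_identical(b1$truth$sites, b2$truth$sites)
  expect_false(identical(b1$molecules, b2$molecules))
})

test_that("degenerate presets produce the boundary methylation patterns", {
  g <- make_genome(seed = 4, chrom_len = 8000, n_genes = 2, apt_density = 80)

  # no methylation at all
  p0 <- methylation_preset("unmethylated", site_fraction = 0, full_hemi_ratio = 1,
                           dispersion = list(rate = 0, sd_normal = c(0.02, 0.05),
                                             sd_dispersed = c(0.4, 0.5)),
                           nstar_rate = 0)
  s0 <- simulate_molecules(g, p0, 200, mean_len = 600, seed = 5)
  expect_equal(s0$truth$genome_fraction, 0)
  res0 <- analyze_molecules(s0, g, seed = 1)
  expect_equal(res0$fraction, 0)
  expect_false(res0$threshold$bimodal)  # unimodal input falls back
  expect_equal(res0$threshold$cutoff, 2.8)

  # everything fully methylated (tight emissions so no strand drops below
  # the cutoff): full/hemi ratio is the Inf sentinel
  p1 <- methylation_preset("full", site_fraction = 1, full_hemi_ratio = Inf,
                           p_un_site = 0,
                           emission = list(meanlog_unmeth = 0,
                                           meanlog_meth = log(6), sdlog = 0.05),
                           dispersion = list(rate = 0, sd_normal = c(0, 0.01),
                                             sd_dispersed = c(0.4, 0.5)),
                           nstar_rate = 0)
  s1 <- simulate_molecules(g, p1, 200, mean_len = 600, seed = 6)
  expect_equal(s1$truth$genome_fraction, 1)
  expect_true(all(s1$truth$states$state == "Full"))
  res1 <- analyze_molecules(s1, g, seed = 1)
  expect_identical(res1$full_hemi, Inf)
  expect_gt(res1$fraction, 0.95)  # limited only by sites covered < 3x
})

test_that("drawn duplex states match the preset's conditional distribution within 3 SE", {
  g <- make_genome(seed = 11, chrom_len = 20000, n_genes = 5, apt_density = 100)
  p <- preset_6ma("WT")
  sim <- simulate_molecules(g, p, 2000, mean_len = 800, seed = 12)
  st <- sim$truth$states
  n <- nrow(st)
  expect_gt(n, 2000)
  for (state in names(p$cond_state_probs)) {
    prob <- p$cond_state_probs[[state]]
    se <- sqrt(prob * (1 - prob) / n)
    expect_lt(abs(mean(st$state == state) - prob), 3 * se + 1e-9)
  }
  # ground-truth sigma-P is additive over sites (exact)
  sites <- sim$truth$sites[!is.na(gene_id)]
  by_gene <- sites[, sum(pen_W + pen_C), by = gene_id]
  truth <- merge(by_gene, sim$truth$genes, by = "gene_id")
  expect_equal(truth$V1, truth$true_sigma_p)
})

test_that("per-gene sigma-P overrides hit their configured targets exactly", {
  g <- make_genome(seed = 21, chrom_len = 8000, n_genes = 1,
                   gene_lengths = 3000, apt_density = 100)
  gid <- g$genes$gene_id[1]
  p <- preset_6ma("WT", sigma_p_overrides = setNames(34.47, gid))
  sim <- simulate_molecules(g, p, 10, mean_len = 600, seed = 22)
  expect_equal(sim$truth$genes[gene_id == gid, true_sigma_p], 34.47,
               tolerance = 1e-12)
})

test_that("fragment simulation honours the positioning-degree contract", {
  dyads <- seq(1000, 6000, by = 400)

  # perfectly positioned: every midpoint within +/- 25 bp of a dyad
  f1 <- simulate_fragments(dyads, positioning = 1, n_fragments = 2000, seed = 31)
  mid <- (f1$start + f1$end) %/% 2L
  d_near <- vapply(mid, function(m) min(abs(m - dyads)), numeric(1))
  expect_true(all(d_near <= 25))

  # fully random placement within the wide window measures the floor ~ 51/151
  f0 <- simulate_fragments(dyads, positioning = 0, n_fragments = 20000, seed = 32)
  deg0 <- positioning_degree(dyads, f0)
  expect_equal(mean(deg0$degree), 51 / 151, tolerance = 0.02)

  # intermediate degree is recovered
  f8 <- simulate_fragments(dyads, positioning = 0.8, n_fragments = 10000, seed = 33)
  deg8 <- positioning_degree(dyads, f8)
  expect_equal(mean(deg8$degree), 0.8, tolerance = 0.03)

  expect_error(simulate_fragments(integer(), 0.5, 10), "non-empty")
})

test_that("count simulation recovers size factors and fold changes", {
  # a block of downregulated genes, as in a real knockdown contrast
  lfc <- c(rep(-2, 20), rep(0, 280))
  sim <- simulate_counts(n_genes = 300, n_samples = 6, fold_changes = lfc,
                         spike_true_factors = c(1, 1, 1, 1, 1, 1), seed = 41)
  f <- spike_size_factors(sim$spike_totals)
  expect_equal(unname(f), rep(1, 6), tolerance = 0.01)

  de <- differential_expression(sim$counts, f, sim$group_labels)
  expect_equal(mean(de$log2FoldChange[1:20]), -2, tolerance = 0.3)
  expect_gte(mean(de$p_adj[1:20] < 0.05), 0.9)

  # spike factor ratio recovered from Poisson totals
  sim2 <- simulate_counts(n_genes = 10, n_samples = 2, seed = 42,
                          spike_true_factors = c(1, 2))
  f2 <- spike_size_factors(sim2$spike_totals)
  expect_equal(f2[2] / f2[1], 2, tolerance = 0.02)

  expect_error(simulate_counts(10, 4, dispersion = 0), "dispersion")
  expect_error(simulate_counts(10, 2, spike_true_factors = c(1, -1)),
               "spike_true_factors")
})
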