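# A toy duplex world: ApT sites at chosen positions, molecules covering them
# with chosen strand IPDs.
toy_calls_input <- function(specs, apt_pos = 100L) {
  # specs: list of c(watson_ipd, crick_ipd), one per molecule
  rbindlist(lapply(seq_along(specs), function(i) {
    toy_molecule(i, pos_w = apt_pos, ipd_w = specs[[i]][1],
                 pos_c = apt_pos + 1L, ipd_c = specs[[i]][2],
                 start = apt_pos - 5L, end = apt_pos + 6L)
  }))
}
toy_apt <- function(pos = 100L) data.table(chrom = "chr1", pos = as.integer(pos))

test_that("duplex states follow the two-strand threshold rule, ties methylated", {
  m <- toy_calls_input(list(c(5, 5), c(5, 1), c(1, 5), c(1, 1), c(2.6, 2.59)))
  calls <- call_duplexes(m, toy_apt(), threshold = 2.6)
  expect_equal(calls[order(molecule_id), state],
               c("Full", "Hemi-W", "Hemi-C", "Un", "Hemi-W"))
  # partition conservation: the four states cover every observation
  expect_equal(sum(table(calls$state)), nrow(calls))

  # a duplex with a missing strand is skipped and counted
  m2 <- toy_molecule(9, pos_w = 100L, ipd_w = 5)  # no Crick record
  calls2 <- call_duplexes(rbind(m, m2), toy_apt(), threshold = 2.6)
  expect_equal(nrow(calls2), 5L)
  expect_equal(attr(calls2, "n_skipped"), 1L)

  # molecules overlapping no ApT site contribute nothing
  m3 <- toy_molecule(10, pos_w = 500L, ipd_w = 5, pos_c = 501L, ipd_c = 5)
  expect_equal(nrow(call_duplexes(m3, toy_apt(), 2.6)), 0L)
})

test_that("full/hemi ratio counts duplex-molecule observations", {
  mk <- function(states) data.table(state = states)
  expect_equal(full_hemi_ratio(mk(c(rep("Full", 10), rep("Hemi-W", 3),
                                    rep("Hemi-C", 2)))), 2.0)
  expect_equal(full_hemi_ratio(mk(c(rep("Hemi-W", 4), "Un"))), 0.0)
  expect_identical(full_hemi_ratio(mk(rep("Full", 5))), Inf)
  expect_identical(full_hemi_ratio(mk(rep("Un", 5))), NA_real_)
  expect_identical(full_hemi_ratio(mk(character())), NA_real_)
})

test_that("penetrance table counts methylated strands per site", {
  # 10 molecules: 3 methylate the Watson strand (2 Full + 1 Hemi-W),
  # 2 methylate the Crick strand (2 Full)
  specs <- c(replicate(2, c(5, 5), simplify = FALSE),
             replicate(1, c(5, 1), simplify = FALSE),
             replicate(7, c(1, 1), simplify = FALSE))
  calls <- call_duplexes(toy_calls_input(specs), toy_apt(), 2.8)
  tab <- penetrance_table(calls)

  w <- tab[strand == "W"]
  c_ <- tab[strand == "C"]
  expect_equal(w$methylated_count, 3L)
  expect_equal(w$covered_count, 10L)
  expect_equal(w$penetrance, 0.3)
  expect_true(w$high_confidence)     # >= 3 supporting molecules
  expect_equal(c_$methylated_count, 2L)
  expect_equal(c_$penetrance, 0.2)
  expect_false(c_$high_confidence)   # 2 molecules is below the bound
  expect_equal(c_$position, w$position + 1L)
  expect_equal(unique(tab$duplex_pos), 100L)

  # uncovered sites are absent from the table
  tab2 <- penetrance_table(call_duplexes(toy_calls_input(specs),
                                         toy_apt(c(100L, 400L)), 2.8))
  expect_equal(nrow(tab2), 2L)

  # monotonicity: adding a methylated observation never lowers the numerator
  specs3 <- c(specs, list(c(5, 5)))
  tab3 <- penetrance_table(call_duplexes(toy_calls_input(specs3), toy_apt(), 2.8))
  expect_gte(tab3[strand == "W", methylated_count], w$methylated_count)
  expect_true(all(tab3$penetrance >= 0 & tab3$penetrance <= 1))
})

test_that("genome fraction counts high-confidence sites over covered sites", {
  specs <- replicate(5, c(5, 5), simplify = FALSE)   # fully methylated
  calls <- call_duplexes(toy_calls_input(specs), toy_apt(), 2.8)
  expect_equal(genome_6mApT_fraction(penetrance_table(calls)), 1.0)

  specs_un <- replicate(5, c(1, 1), simplify = FALSE)
  calls_un <- call_duplexes(toy_calls_input(specs_un), toy_apt(), 2.8)
  expect_equal(genome_6mApT_fraction(penetrance_table(calls_un)), 0.0)

  expect_identical(genome_6mApT_fraction(penetrance_table(calls[0])), NA_real_)
})

test_that("gene sigma-P sums site penetrance and is additive over partitions", {
  ptab <- data.table(
    chrom = "chr1",
    position = c(100L, 101L, 300L, 301L, 900L),
    strand = c("W", "C", "W", "C", "W"),
    duplex_pos = c(100L, 100L, 300L, 300L, 900L),
    methylated_count = c(5L, 2L, 3L, 0L, 4L),
    covered_count = c(10L, 8L, 12L, 10L, 10L),
    penetrance = c(0.5, 0.25, 0.25, 0, 0.4),
    high_confidence = c(TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  genes <- data.table(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(0L, 800L), end = c(400L, 1000L),
                      strand = c("+", "-"))
  gm <- gene_methylation(genes, ptab)
  expect_equal(gm[gene_id == "gA", sigma_p], 0.5 + 0.25 + 0.25 + 0)
  expect_equal(gm[gene_id == "gA", n_apt], 4L)
  expect_equal(gm[gene_id == "gA", n_6mApT], 2L)
  expect_equal(gm[gene_id == "gA", ratio_6mApT_per_ApT], 0.5)

  # partitioning gA at 200 conserves sigma-P
  split_genes <- data.table(gene_id = c("gA1", "gA2"), chrom = "chr1",
                            start = c(0L, 200L), end = c(200L, 400L),
                            strand = "+")
  gs <- gene_methylation(split_genes, ptab)
  expect_equal(sum(gs$sigma_p), gm[gene_id == "gA", sigma_p])

  # gene without ApT sites: sigma-P 0, undefined ratio
  genes0 <- rbind(genes, data.table(gene_id = "gC", chrom = "chr1",
                                    start = 2000L, end = 2500L, strand = "+"))
  gm0 <- gene_methylation(genes0, ptab)
  expect_equal(gm0[gene_id == "gC", sigma_p], 0)
  expect_identical(gm0[gene_id == "gC", ratio_6mApT_per_ApT], NA_real_)
})

test_that("metagene profiles are strand-aware and flat under uniform penetrance", {
  n_genes <- 40L
  genes <- data.table(gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                      start = seq(10000L, by = 9000L, length.out = n_genes),
                      end = seq(10000L, by = 9000L, length.out = n_genes) + 3000L,
                      strand = rep(c("+", "-"), n_genes / 2))
  # a site every 10 bp through each gene body, uniform penetrance
  ptab <- genes[, .(position = seq(start, end - 1L, by = 10L)), by = gene_id]
  ptab <- merge(ptab, genes[, .(gene_id, chrom)], by = "gene_id")
  ptab[, `:=`(strand = "W", duplex_pos = position, methylated_count = 5L,
              covered_count = 10L, penetrance = 0.5, high_confidence = TRUE)]
  prof <- metagene_profile(genes, ptab, n_bins = 30L)
  body <- prof[segment == "body", sum_penetrance]
  expect_equal(length(body), 30L)
  expect_lt(sd(body) / mean(body), 0.1)
  expect_equal(prof[segment == "upstream", sum(sum_penetrance)], 0)

  # methylation confined to the 5' quarter lands in the first bins
  q <- copy(ptab)
  q <- merge(q, genes[, .(gene_id, start, end, strand)], by = "gene_id",
             suffixes = c("", ".g"))
  rel <- ifelse(q$strand.g == "+", (q$position - q$start) / (q$end - q$start),
                (q$end - 1L - q$position) / (q$end - q$start))
  q <- q[rel < 0.25][, c("start", "end", "strand.g") := NULL]
  q[, strand := "W"]
  prof5 <- metagene_profile(genes, q, n_bins = 30L)
  body5 <- prof5[segment == "body"]
  expect_gte(sum(body5[bin <= 7, sum_penetrance]) / sum(body5$sum_penetrance),
             0.8)

  # a minus-strand gene mirrors the plus-strand construction
  gp <- data.table(gene_id = "p", chrom = "chr1", start = 1000L, end = 2000L,
                   strand = "+")
  gm <- data.table(gene_id = "m", chrom = "chr1", start = 1000L, end = 2000L,
                   strand = "-")
  site_p <- data.table(chrom = "chr1", position = 1100L, strand = "W",
                       duplex_pos = 1100L, methylated_count = 3L,
                       covered_count = 10L, penetrance = 0.3,
                       high_confidence = TRUE)
  site_m <- copy(site_p)[, `:=`(position = 1899L, duplex_pos = 1899L)]
  bp <- metagene_profile(gp, site_p)[sum_penetrance > 0, bin]
  bm <- metagene_profile(gm, site_m)[sum_penetrance > 0, bin]
  expect_equal(bp, bm)
  expect_equal(bp, 3L)  # 100/1000 of the way in -> bin 3
})
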