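#' Call per-molecule ApT duplex methylation states
#'
#' For every molecule x ApT duplex covered on both strands, compares the
#' Watson-strand adenine IPD (at the duplex position) and the Crick-strand
#' adenine IPD (at position + 1) to the threshold and assigns one of the four
#' duplex states: `Full` (both strands >= cutoff), `Hemi-W` (Watson only),
#' `Hemi-C` (Crick only), `Un` (neither). Ties at the cutoff are called
#' methylated. Duplexes with a missing strand record are skipped and counted
#' in the `n_skipped` attribute.
#'
#' @param molecules long molecule table (QC already applied) or
#'   `sim_molecules`.
#' @param apt ApT site list: a `sim_genome` or a table with `chrom`, `pos`
#'   (Watson-strand adenine positions, 0-based).
#' @param threshold an [fit_ipd_threshold()] object or a bare numeric cutoff.
#' @return data.table of duplex calls: `molecule_id`, `chrom`, `watson_pos`,
#'   `state`, `watson_ipd`, `crick_ipd`; attribute `n_skipped`.
#' @export
call_duplexes <- function(molecules, apt, threshold) {
  if (inherits(molecules, "sim_molecules")) molecules <- molecules$molecules
  assert_molecule_table(molecules)
  apt <- resolve_apt(apt)
  cutoff <- if (inherits(threshold, "ipd_threshold")) threshold$cutoff
            else as.numeric(threshold)
  if (!is.finite(cutoff) || cutoff <= 0) stopf("threshold cutoff must be > 0")

  sides <- duplex_strand_ipds(molecules, apt)
  merged <- merge(sides$w, sides$c, by = c("molecule_id", "chrom", "watson_pos"))
  n_skipped <- nrow(sides$w) + nrow(sides$c) - 2L * nrow(merged)

  wm <- merged$watson_ipd >= cutoff
  cm <- merged$crick_ipd >= cutoff
  merged[, state := data.table::fcase(
    wm & cm, "Full",
    wm & !cm, "Hemi-W",
    !wm & cm, "Hemi-C",
    default = "Un"
  )]
  data.table::setorder(merged, chrom, watson_pos, molecule_id)
  data.table::setattr(merged, "n_skipped", n_skipped)
  merged[]
}

# Per-strand adenine IPDs at ApT duplexes: Watson A at pos, Crick A at pos+1.
duplex_strand_ipds <- function(molecules, apt) {
  w <- molecules[strand == "W" & base == "A"][
    apt, on = .(chrom, position = pos), nomatch = NULL,
    .(molecule_id, chrom, watson_pos = position, watson_ipd = ipd_ratio)]
  c_ <- molecules[strand == "C" & base == "A"][
    apt[, .(chrom, pos = pos + 1L)], on = .(chrom, position = pos),
    nomatch = NULL,
    .(molecule_id, chrom, watson_pos = position - 1L, crick_ipd = ipd_ratio)]
  list(w = w, c = c_)
}

#' Pooled ApT-context adenine IPD ratios
#'
#' Collects the adenine IPD ratios of every covered ApT duplex strand (Watson
#' adenine at the duplex position, Crick adenine at position + 1) across
#' molecules — the input pool for [fit_ipd_threshold()].
#'
#' @param molecules long molecule table (usually after QC).
#' @param apt ApT site list (`sim_genome` or table with `chrom`, `pos`).
#' @return numeric vector of IPD ratios.
#' @export
apt_adenine_ipds <- function(molecules, apt) {
  sides <- duplex_strand_ipds(molecules, resolve_apt(apt))
  c(sides$w$watson_ipd, sides$c$crick_ipd)
}

#' Full/hemi ratio of duplex observations
#'
#' Ratio between fully methylated and hemi-methylated ApT duplex
#' observations, counted per molecule x duplex (each molecule's view of each
#' duplex counts once). `Inf` when hemi observations are absent but full ones
#' exist; `NA` when both are absent.
#'
#' @param calls duplex calls from [call_duplexes()].
#' @return a single number.
#' @export
full_hemi_ratio <- function(calls) {
  n_full <- sum(calls$state == "Full")
  n_hemi <- sum(calls$state %in% c("Hemi-W", "Hemi-C"))
  if (n_hemi == 0L) {
    if (n_full == 0L) return(NA_real_)
    return(Inf)
  }
  n_full / n_hemi
}

#' Per-site methylation penetrance table
#'
#' Each strand's adenine of each covered ApT duplex is a site. Penetrance is
#' the fraction of covering molecules whose duplex call methylates that
#' strand (`Full` counts for both strands, `Hemi-W` for Watson only,
#' `Hemi-C` for Crick only). Sites supported by at least `min_molecules`
#' methylated molecules are flagged high-confidence.
#'
#' @param calls duplex calls from [call_duplexes()].
#' @param min_molecules minimum methylated-molecule support for a
#'   high-confidence 6mA site (default 3).
#' @return data.table, one row per covered site: `chrom`, `position`,
#'   `strand`, `duplex_pos` (Watson-anchor of the duplex), `methylated_count`,
#'   `covered_count`, `penetrance`, `high_confidence`.
#' @export
penetrance_table <- function(calls, min_molecules = 3L) {
  w <- calls[, .(methylated_count = sum(state %chin% c("Full", "Hemi-W")),
                 covered_count = .N),
             by = .(chrom, duplex_pos = watson_pos)]
  w[, `:=`(position = duplex_pos, strand = "W")]
  c_ <- calls[, .(methylated_count = sum(state %chin% c("Full", "Hemi-C")),
                  covered_count = .N),
              by = .(chrom, duplex_pos = watson_pos)]
  c_[, `:=`(position = duplex_pos + 1L, strand = "C")]
  tab <- data.table::rbindlist(list(w, c_), use.names = TRUE)
  tab[, penetrance := methylated_count / covered_count]
  tab[, high_confidence := methylated_count >= min_molecules]
  data.table::setorder(tab, chrom, position, strand)
  data.table::setcolorder(tab, c("chrom", "position", "strand", "duplex_pos",
                                 "methylated_count", "covered_count",
                                 "penetrance", "high_confidence"))
  tab[]
}

#' Genome-wide 6mApT/ApT fraction
#'
#' High-confidence methylated adenine sites in ApT context divided by all
#' covered ApT adenine sites. `NA` when no sites are covered.
#'
#' @param ptable penetrance table from [penetrance_table()].
#' @return fraction in `[0, 1]` (multiply by 100 for the conventional
#'   percentage).
#' @export
genome_6mApT_fraction <- function(ptable) {
  if (!nrow(ptable)) return(NA_real_)
  sum(ptable$high_confidence) / nrow(ptable)
}

#' Gene-level methylation statistics (sigma-P and 6mApT/ApT)
#'
#' Assigns every covered ApT adenine site to a gene by the Watson-anchor
#' position of its duplex (`duplex_pos` in `[start, end)`, strand-agnostic:
#' both adenines of a duplex count as separate sites). Sigma-P is the sum of
#' penetrance over those sites; `n_6mApT` counts the high-confidence
#' methylated sites and `ratio_6mApT_per_ApT` divides it by the covered
#' sites. Genes without covered ApT sites get sigma-P 0 and an undefined
#' ratio.
#'
#' @param genes gene models (`sim_genome` or BED6-like table; must be
#'   non-overlapping).
#' @param ptable penetrance table from [penetrance_table()].
#' @return data.table per gene: `gene_id`, `sigma_p`, `n_apt`, `n_6mApT`,
#'   `ratio_6mApT_per_ApT`.
#' @export
gene_methylation <- function(genes, ptable) {
  genes <- resolve_genes(genes)
  tab <- data.table::copy(ptable)
  tab[, gene_id := assign_to_genes(chrom, duplex_pos, genes)]
  per <- tab[!is.na(gene_id),
             .(sigma_p = sum(penetrance), n_apt = .N,
               n_6mApT = sum(high_confidence)),
             by = gene_id]
  out <- merge(genes[, .(gene_id)], per, by = "gene_id", all.x = TRUE)
  out[is.na(sigma_p), `:=`(sigma_p = 0, n_apt = 0L, n_6mApT = 0L)]
  out[, ratio_6mApT_per_ApT := data.table::fifelse(n_apt > 0L,
                                                   n_6mApT / n_apt, NA_real_)]
  out[]
}

#' Metagene profile of summed penetrance around gene bodies
#'
#' Genes are scaled to unit length and extended by one unit length on each
#' side; each unit is divided into `n_bins` bins, oriented by gene strand
#' (bin 0 starts at the TSS). The profile is the sum of site penetrance per
#' bin across genes. Bins are indexed `-n_bins .. -1` (upstream),
#' `0 .. n_bins-1` (gene body), `n_bins .. 2*n_bins-1` (downstream).
#'
#' @param genes gene models.
#' @param ptable penetrance table from [penetrance_table()].
#' @param n_bins bins per unit length (default 30).
#' @return data.table: `bin`, `segment`, `sum_penetrance` (complete grid,
#'   zeros where no site falls).
#' @export
metagene_profile <- function(genes, ptable, n_bins = 30L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stopf("n_bins must be >= 1")
  genes <- resolve_genes(genes)

  pieces <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    sites <- ptable[chrom == g$chrom &
                      position >= g$start - (g$end - g$start) &
                      position < g$end + (g$end - g$start)]
    if (!nrow(sites)) next
    len <- g$end - g$start
    x <- if (g$strand == "+") sites$position - g$start
         else (g$end - 1L) - sites$position
    u <- x / len
    keep_u <- u >= -1 & u < 2
    if (!any(keep_u)) next
    pieces[[i]] <- data.table::data.table(
      bin = as.integer(floor(u[keep_u] * n_bins)),
      penetrance = sites$penetrance[keep_u]
    )
  }
  pieces <- data.table::rbindlist(pieces)
  grid <- data.table::data.table(bin = seq.int(-n_bins, 2L * n_bins - 1L))
  grid[, segment := data.table::fcase(bin < 0L, "upstream",
                                      bin < n_bins, "body",
                                      default = "downstream")]
  if (nrow(pieces)) {
    sums <- pieces[, .(sum_penetrance = sum(penetrance)), by = bin]
    grid <- merge(grid, sums, by = "bin", all.x = TRUE)
  } else {
    grid[, sum_penetrance := NA_real_]
  }
  grid[is.na(sum_penetrance), sum_penetrance := 0]
  data.table::setorder(grid, bin)
  grid[]
}

#' Run the full single-molecule 6mA calling pipeline
#'
#' Composes molecule QC, threshold deconvolution (on pooled ApT-context
#' adenine IPDs of the retained molecules), duplex-state calling and the
#' penetrance table, and reports the headline statistics.
#'
#' @param molecules long molecule table or `sim_molecules`.
#' @param genome `sim_genome` (or list of `apt` + `genes` tables).
#' @param seed seed for the threshold fit subsample.
#' @param min_passes,sd_cutoff,unmeth_cutoff QC parameters.
#' @param min_molecules high-confidence support threshold.
#' @param genes optional gene table overriding `genome$genes`.
#' @return list: `qc` (report), `threshold`, `calls`, `penetrance`,
#'   `fraction` (genome-wide 6mApT/ApT), `full_hemi`, `gene_stats`.
#' @export
analyze_molecules <- function(molecules, genome, seed = 1L, min_passes = 20L,
                              sd_cutoff = 0.35, unmeth_cutoff = 2.8,
                              min_molecules = 3L, genes = NULL) {
  qc <- run_qc(molecules, min_passes = min_passes, unmeth_cutoff = unmeth_cutoff,
               sd_cutoff = sd_cutoff)
  apt <- resolve_apt(genome)
  pool <- apt_adenine_ipds(qc$molecules, apt)
  thr <- if (length(pool) >= 100L) {
    fit_ipd_threshold(pool, seed = seed, fallback_cutoff = unmeth_cutoff)
  } else {
    # too few ApT adenine observations to deconvolve: fixed working cutoff
    structure(list(cutoff = unmeth_cutoff, components = NULL,
                   loglik = NA_real_, bimodal = FALSE, n_used = length(pool)),
              class = "ipd_threshold")
  }
  calls <- call_duplexes(qc$molecules, apt, thr)
  ptab <- penetrance_table(calls, min_molecules = min_molecules)
  gene_tab <- if (!is.null(genes)) resolve_genes(genes)
              else if (inherits(genome, "sim_genome")) genome$genes
              else NULL
  list(
    qc = qc$report,
    threshold = thr,
    calls = calls,
    penetrance = ptab,
    fraction = genome_6mApT_fraction(ptab),
    full_hemi = full_hemi_ratio(calls),
    gene_stats = if (!is.null(gene_tab) && nrow(gene_tab))
      gene_methylation(gene_tab, ptab) else NULL
  )
}
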