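#' Filter aligned fragments on length
#'
#' Retains nucleosome-scale fragments with `min_len <= length <= max_len`
#' (both boundaries inclusive); length is `end - start` on 0-based half-open
#' intervals.
#'
#' @param fragments table with `chrom`, `start`, `end`.
#' @param min_len,max_len inclusive length bounds in bp (defaults 120, 260).
#' @return the retained fragments.
#' @export
filter_fragment_lengths <- function(fragments, min_len = 120L, max_len = 260L) {
  f <- data.table::as.data.table(fragments)
  f[(end - start) >= min_len & (end - start) <= max_len]
}

fragment_midpoints <- function(fragments) {
  (fragments$start + fragments$end) %/% 2L
}

#' Per-gene ChIP enrichment ratio
#'
#' For each gene, the normalized fragment count in the ChIP sample divided
#' by the normalized count in the input sample; normalization is per total
#' fragments (counts-per-million equivalent, so the totals cancel up to a
#' constant). A fragment maps to a gene when its midpoint lies in
#' `[start, end)`. Genes with zero input midpoints get an undefined ratio.
#'
#' @param genes gene models (`sim_genome` or BED6-like table,
#'   non-overlapping).
#' @param chip_fragments,input_fragments fragment tables (already
#'   length-filtered).
#' @return data.table per gene: `gene_id`, `chip_count`, `input_count`,
#'   `enrichment`.
#' @export
chip_enrichment <- function(genes, chip_fragments, input_fragments) {
  genes <- resolve_genes(genes)
  chip <- data.table::as.data.table(chip_fragments)
  inp <- data.table::as.data.table(input_fragments)
  if (!nrow(chip) || !nrow(inp)) stopf("both samples must be non-empty")

  count_by_gene <- function(f) {
    gid <- assign_to_genes(f$chrom, fragment_midpoints(f), genes)
    tab <- table(factor(gid, levels = genes$gene_id))
    as.integer(tab)
  }
  out <- data.table::data.table(
    gene_id = genes$gene_id,
    chip_count = count_by_gene(chip),
    input_count = count_by_gene(inp)
  )
  out[, enrichment := data.table::fifelse(
    input_count > 0L,
    (chip_count / nrow(chip)) / (input_count / nrow(inp)),
    NA_real_)]
  out[]
}

#' Nucleosome positioning degree at dyads
#'
#' For each dyad, the number of fragment midpoints within 25 bp upstream and
#' downstream of the dyad divided by the number within 75 bp upstream and
#' downstream (closed windows on integer positions). Undefined when no
#' midpoint falls in the wide window.
#'
#' @param dyads table with `chrom`, `pos` (dyad positions) or a numeric
#'   vector of positions (single chromosome matching the fragments).
#' @param fragments length-filtered fragment table.
#' @param near,far window half-widths in bp (defaults 25, 75).
#' @return data.table per dyad: `chrom`, `pos`, `n_near`, `n_far`, `degree`.
#' @export
positioning_degree <- function(dyads, fragments, near = 25L, far = 75L) {
  f <- data.table::as.data.table(fragments)
  if (is.numeric(dyads)) {
    dyads <- data.table::data.table(chrom = unique(f$chrom)[1L],
                                    pos = as.integer(dyads))
  } else {
    dyads <- data.table::as.data.table(dyads)[, .(chrom = as.character(chrom),
                                                  pos = as.integer(pos))]
  }
  f[, midpoint := fragment_midpoints(f)]

  out <- data.table::copy(dyads)
  out[, `:=`(n_near = 0L, n_far = 0L)]
  for (ch in unique(dyads$chrom)) {
    mids <- sort(f[chrom == ch, midpoint])
    sel <- which(out$chrom == ch)
    if (!length(mids) || !length(sel)) next
    cnt <- function(lo, hi) findInterval(hi, mids) - findInterval(lo - 1L, mids)
    data.table::set(out, sel, "n_near",
                    cnt(out$pos[sel] - near, out$pos[sel] + near))
    data.table::set(out, sel, "n_far",
                    cnt(out$pos[sel] - far, out$pos[sel] + far))
  }
  out[, degree := data.table::fifelse(n_far > 0L, n_near / n_far, NA_real_)]
  out[]
}

#' Gene-level nucleosome positioning degree
#'
#' Averages the positioning degree of the two or three nucleosomes
#' immediately adjacent to the TSS on the gene-body side (the +1/+2/+3
#' nucleosomes: dyads within `[start, end)`, ordered by distance from the
#' TSS in the gene's orientation). Genes with fewer than two such dyads with
#' a defined degree get an undefined value.
#'
#' @param genes gene models.
#' @param dyads data.table with `chrom`, `pos`, `degree` (e.g. from
#'   [positioning_degree()]).
#' @param max_nucleosomes how many TSS-adjacent nucleosomes to average
#'   (default 3).
#' @return data.table per gene: `gene_id`, `n_dyads_used`,
#'   `positioning_degree`.
#' @export
gene_positioning_degree <- function(genes, dyads, max_nucleosomes = 3L) {
  genes <- resolve_genes(genes)
  d <- data.table::as.data.table(dyads)
  res <- data.table::data.table(gene_id = genes$gene_id, n_dyads_used = 0L,
                                positioning_degree = NA_real_)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    dd <- d[chrom == g$chrom & pos >= g$start & pos < g$end & !is.na(degree)]
    if (!nrow(dd)) next
    dd[, dist_tss := if (g$strand == "+") pos - g$start else g$end - pos]
    data.table::setorder(dd, dist_tss)
    use <- head(dd, max_nucleosomes)
    if (nrow(use) < 2L) next
    data.table::set(res, i, "n_dyads_used", nrow(use))
    data.table::set(res, i, "positioning_degree", mean(use$degree))
  }
  res[]
}

#' Simulate MNase fragments around positioned nucleosome dyads
#'
#' Fragment midpoints are drawn from a two-component mixture around randomly
#' chosen dyads: a tight window (+/- `near` bp) with probability `a` and a
#' loose window (+/- `far` bp) otherwise, where `a` is chosen so the
#' *expected* measured positioning degree (closed integer windows, see
#' [positioning_degree()]) equals `positioning`. The statistic has a floor
#' of (2*near+1)/(2*far+1) ~ 1/3 — the value measured for fully random
#' placement within the wide window — so requested degrees below the floor
#' saturate at it. Fragment lengths are uniform in `frag_len_range`.
#'
#' @param dyads numeric vector of dyad positions or table with `chrom`,
#'   `pos`; must be non-empty.
#' @param positioning target positioning degree in `[0, 1]`.
#' @param n_fragments number of fragments.
#' @param frag_len_range inclusive fragment length range (default 120-260).
#' @param seed integer seed.
#' @param chrom chromosome label used when `dyads` is a bare vector.
#' @param near,far tight/loose half-widths (defaults 25, 75).
#' @return data.table of fragments: `chrom`, `start`, `end`.
#' @export
simulate_fragments <- function(dyads, positioning, n_fragments,
                               frag_len_range = c(120L, 260L), seed = 1L,
                               chrom = "chr1", near = 25L, far = 75L) {
  if (is.numeric(dyads)) {
    dyads <- data.table::data.table(chrom = chrom, pos = as.integer(dyads))
  } else {
    dyads <- data.table::as.data.table(dyads)
  }
  if (!nrow(dyads)) stopf("`dyads` must be non-empty")
  if (positioning < 0 || positioning > 1) stopf("positioning must be in [0,1]")

  floor_deg <- (2 * near + 1) / (2 * far + 1)
  a <- (positioning - floor_deg) / (1 - floor_deg)
  a <- min(max(a, 0), 1)

  with_seed(seed, {
    di <- sample.int(nrow(dyads), n_fragments, replace = TRUE)
    tight <- runif(n_fragments) < a
    off <- integer(n_fragments)
    off[tight] <- sample.int(2L * near + 1L, sum(tight), replace = TRUE) - near - 1L
    off[!tight] <- sample.int(2L * far + 1L, sum(!tight), replace = TRUE) - far - 1L
    mid <- dyads$pos[di] + off
    len <- sample.int(frag_len_range[2] - frag_len_range[1] + 1L, n_fragments,
                      replace = TRUE) + frag_len_range[1] - 1L
    start <- mid - len %/% 2L
    data.table::data.table(chrom = dyads$chrom[di], start = start,
                           end = start + len)
  })
}
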