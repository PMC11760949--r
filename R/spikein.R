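#' Spike-in size factors from exogenous-genome read totals
#'
#' For each sample, the reads mapped to the spike-in (zebrafish) genome are
#' divided by the exponential of the mean natural logarithm over samples:
#' \deqn{f_i = z_i / \exp\left(\tfrac{1}{n}\sum_j \ln z_j\right).}
#' This centres the factors on the geometric mean, so their product is
#' exactly 1.
#'
#' @param spike_totals positive per-sample spike-in read counts (optionally
#'   named).
#' @return numeric vector of size factors in sample order.
#' @export
spike_size_factors <- function(spike_totals) {
  z <- spike_totals
  bad <- which(!is.finite(z) | z <= 0)
  if (length(bad)) {
    lab <- if (!is.null(names(z))) names(z)[bad[1]] else as.character(bad[1])
    stopf("spike totals must be > 0; offending sample: %s", lab)
  }
  z / exp(mean(log(z)))
}

#' Normalize a count matrix by per-sample size factors
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param factors per-sample size factors (length = ncol(counts)).
#' @return matrix of `counts[, j] / factors[j]`.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) {
    stopf("length(factors) (%d) must equal ncol(counts) (%d)",
          length(factors), ncol(counts))
  }
  sweep(counts, 2L, factors, `/`)
}

#' Differential expression on spike-in-normalized counts
#'
#' A deliberately simple, documented test adapter around the spike-in size
#' factors: counts are normalized by the factors, fold changes are computed
#' on group means with a pseudocount, and per-gene p-values come from a
#' Welch two-sample t-test on `log2(normalized + pseudocount)`, adjusted by
#' Benjamini-Hochberg. Shrinkage-based NB machinery is intentionally out of
#' scope; the spike-in factor computation is the quantity of interest here
#' and the test is a replaceable adapter.
#'
#' @param counts gene x sample count matrix (rownames = gene ids).
#' @param factors per-sample size factors (e.g. [spike_size_factors()]).
#' @param group_labels per-sample labels with exactly two levels.
#' @param control,treatment which label is the reference / the condition;
#'   default: first and second unique label.
#' @param pseudocount added before log/ratio (default 0.5).
#' @return data.table per gene: `gene_id`, `baseMean`, `log2FoldChange`
#'   (treatment vs control), `p_value`, `p_adj`.
#' @export
differential_expression <- function(counts, factors, group_labels,
                                    control = NULL, treatment = NULL,
                                    pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (length(group_labels) != ncol(counts)) {
    stopf("group_labels must have one label per sample")
  }
  lev <- unique(group_labels)
  if (length(lev) != 2L) stopf("exactly two groups are required")
  control <- control %||% lev[1]
  treatment <- treatment %||% setdiff(lev, control)[1]
  i1 <- which(group_labels == control)
  i2 <- which(group_labels == treatment)
  if (length(i1) < 2L || length(i2) < 2L) {
    stopf("each group needs >= 2 samples (control %d, treatment %d)",
          length(i1), length(i2))
  }

  norm <- normalize_counts(counts, factors)
  l <- log2(norm + pseudocount)

  m1 <- rowMeans(l[, i1, drop = FALSE]); m2 <- rowMeans(l[, i2, drop = FALSE])
  v1 <- apply(l[, i1, drop = FALSE], 1L, var)
  v2 <- apply(l[, i2, drop = FALSE], 1L, var)
  n1 <- length(i1); n2 <- length(i2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate genes (zero variance in both groups)
  flat <- se2 == 0 | !is.finite(tstat)
  p[flat] <- ifelse(abs(m2 - m1)[flat] < 1e-12, 1, 0)

  lfc <- log2((rowMeans(norm[, i2, drop = FALSE]) + pseudocount) /
                (rowMeans(norm[, i1, drop = FALSE]) + pseudocount))

  data.table::data.table(
    gene_id = rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts))),
    baseMean = rowMeans(norm),
    log2FoldChange = lfc,
    p_value = p,
    p_adj = p.adjust(p, method = "BH")
  )
}

#' Co-downregulated gene sets and their intersections
#'
#' Per condition, the set of genes with `log2FoldChange <= lfc_cutoff`
#' (boundary inclusive), `p_adj < padj_cutoff`, and reduced 6mA
#' (delta 6mA < 0). Returns the per-condition sets together with all
#' pairwise intersections and the intersection across all conditions.
#'
#' @param de_results named list of [differential_expression()] tables.
#' @param meth_deltas named list (same names) of per-gene 6mA changes:
#'   either a named numeric vector (gene -> delta) or a table with
#'   `gene_id`, `delta`.
#' @param lfc_cutoff,padj_cutoff thresholds (defaults -1 and 0.05).
#' @return list: `sets` (named list of gene-id vectors), `intersections`
#'   (named list: every pair `"A.B"` and the full `"all"`).
#' @export
co_downregulated <- function(de_results, meth_deltas, lfc_cutoff = -1,
                             padj_cutoff = 0.05) {
  stopifnot(is.list(de_results), is.list(meth_deltas))
  conds <- names(de_results)
  if (is.null(conds) || !all(conds %in% names(meth_deltas))) {
    stopf("de_results and meth_deltas must be named consistently")
  }
  get_delta <- function(md) {
    if (is.data.frame(md)) setNames(md$delta, md$gene_id) else md
  }
  sets <- lapply(conds, function(cn) {
    de <- de_results[[cn]]
    delta <- get_delta(meth_deltas[[cn]])
    down <- de$gene_id[de$log2FoldChange <= lfc_cutoff & de$p_adj < padj_cutoff]
    down[down %in% names(delta)[!is.na(delta) & delta < 0]]
  })
  names(sets) <- conds

  inter <- list()
  if (length(conds) >= 2L) {
    prs <- utils::combn(conds, 2L, simplify = FALSE)
    for (p in prs) {
      inter[[paste(p, collapse = ".")]] <- intersect(sets[[p[1]]], sets[[p[2]]])
    }
  }
  inter[["all"]] <- Reduce(intersect, sets)
  list(sets = sets, intersections = inter)
}

#' Simulate a gene x sample count matrix with spike-in totals
#'
#' Gene counts are negative binomial with mean
#' `baseline * 2^(log2FC * treated) * factor_j`; spike-in totals are Poisson
#' around `spike_mean * factor_j`. Ground truth (geometric-mean-centred true
#' factors and the fold changes) is returned alongside.
#'
#' @param n_genes,n_samples dimensions.
#' @param fold_changes per-gene log2 fold change applied in the treatment
#'   group (length `n_genes`, default all 0).
#' @param spike_true_factors per-sample true depth factors (> 0).
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2; > 0).
#' @param baseline_mean per-gene baseline mean (scalar or length `n_genes`).
#' @param group_labels per-sample labels; default first half `"control"`,
#'   second half `"treatment"`.
#' @param spike_mean expected spike-in total at factor 1.
#' @param seed integer seed.
#' @return list: `counts` (matrix), `spike_totals`, `group_labels`,
#'   `truth` (`$size_factors` centred on geometric mean, `$log2fc`).
#' @export
simulate_counts <- function(n_genes, n_samples, fold_changes = NULL,
                            spike_true_factors = NULL, dispersion = 0.01,
                            baseline_mean = 500, group_labels = NULL,
                            spike_mean = 5e5, seed = 1L) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  fold_changes <- fold_changes %||% rep(0, n_genes)
  spike_true_factors <- spike_true_factors %||% rep(1, n_samples)
  if (any(spike_true_factors <= 0)) stopf("spike_true_factors must be > 0")
  group_labels <- group_labels %||%
    rep(c("control", "treatment"), c(ceiling(n_samples / 2), floor(n_samples / 2)))
  base <- rep_len(baseline_mean, n_genes)

  with_seed(seed, {
    treated <- group_labels == unique(group_labels)[2]
    mu <- outer(base, spike_true_factors) *
      2^(outer(fold_changes, as.numeric(treated)))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_genes,
                     dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                     sprintf("s%02d", seq_len(n_samples))))
    spikes <- rpois(n_samples, spike_mean * spike_true_factors)
    list(counts = counts, spike_totals = spikes, group_labels = group_labels,
         truth = list(
           size_factors = spike_true_factors / exp(mean(log(spike_true_factors))),
           log2fc = fold_changes))
  })
}
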