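# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately written in the most literal way possible (loops,
# direct formulas) and share no code with the package implementation.

library(data.table)

# Build a long molecule table from per-strand position/base/ipd vectors.
toy_molecule <- function(id, pos_w = integer(), ipd_w = numeric(),
                         base_w = rep("A", length(pos_w)),
                         pos_c = integer(), ipd_c = numeric(),
                         base_c = rep("A", length(pos_c)),
                         passes = 30L, chrom = "chr1",
                         start = NULL, end = NULL) {
  all_pos <- c(pos_w, pos_c)
  start <- start %||% if (length(all_pos)) min(all_pos) else 0L
  end <- end %||% if (length(all_pos)) max(all_pos) + 1L else 1L
  rbindlist(list(
    data.table(molecule_id = id, chrom = chrom, start = start, end = end,
               passes = passes, strand = "W", position = as.integer(pos_w),
               base = base_w, ipd_ratio = ipd_w),
    data.table(molecule_id = id, chrom = chrom, start = start, end = end,
               passes = passes, strand = "C", position = as.integer(pos_c),
               base = base_c, ipd_ratio = ipd_c)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random molecule tables (<= max_pos positions) for oracle-equivalence tests.
random_molecules <- function(n_mol, max_pos = 200L, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    np <- sample(5:max_pos, 1L)
    start <- sample(0:5000, 1L)
    pos <- sort(sample(start:(start + 2L * np), np))
    pass_i <- sample(10:40, 1L)
    mk_strand <- function(str) {
      data.table(molecule_id = i, chrom = "chr1", start = start,
                 end = max(pos) + 1L, passes = pass_i, strand = str,
                 position = pos,
                 base = sample(c("A", "C", "G", "T"), np, replace = TRUE),
                 # heavy right tail so some values cross the 2.8 bound
                 ipd_ratio = exp(rnorm(np, 0, 0.6)))
    }
    out[[i]] <- rbindlist(list(mk_strand("W"), mk_strand("C")))
  }
  rbindlist(out)
}

# --- brute-force oracles -------------------------------------------------

# Sample SD by the direct textbook formula.
oracle_sample_sd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# Global-dispersion decision for one molecule table, literal reading:
# per strand, unmethylated adenines are A with ipd < 2.8; remove if any
# strand with >= 2 such adenines has sample SD >= 0.35.
oracle_global_remove <- function(mol, unmeth_cutoff = 2.8, sd_cutoff = 0.35) {
  for (str in c("W", "C")) {
    v <- mol[mol$strand == str & mol$base == "A" &
               mol$ipd_ratio < unmeth_cutoff, ][["ipd_ratio"]]
    if (length(v) >= 2L) {
      if (oracle_sample_sd(v) >= sd_cutoff) return(TRUE)
    }
  }
  FALSE
}

# N*-chain decision by explicit enumeration: walk sorted qualifying
# positions per strand and count the longest run of successive gaps <= 25.
oracle_nstar_remove <- function(mol, nstar_ipd = 2.8, max_gap = 25L,
                                min_count = 4L) {
  for (str in c("W", "C")) {
    p <- sort(mol[mol$strand == str & mol$base != "A" &
                    mol$ipd_ratio >= nstar_ipd, ][["position"]])
    if (length(p) < min_count) next
    run <- 1L
    for (i in seq_along(p)[-1]) {
      run <- if (p[i] - p[i - 1L] <= max_gap) run + 1L else 1L
      if (run >= min_count) return(TRUE)
    }
  }
  FALSE
}

# Equal-posterior crossing of a 2-component Gaussian mixture by dense grid
# search on the log scale (independent of the closed-form solver).
oracle_grid_cutoff <- function(w, mu, sigma, n_grid = 200000L) {
  x <- seq(mu[1], mu[2], length.out = n_grid)
  d1 <- w[1] * dnorm(x, mu[1], sigma[1])
  d2 <- w[2] * dnorm(x, mu[2], sigma[2])
  i <- which(d2 >= d1)[1]
  exp(x[i])
}

# Misclassification rate of labelled log-normal draws at a cutoff.
misclass_rate <- function(ipds, is_meth, cutoff) {
  mean((ipds >= cutoff) != is_meth)
}
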