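#' Simulate SMRT-CCS single molecules with per-position IPD ratios
#'
#' Draws mapped single molecules over a synthetic genome and emits an IPD
#' ratio for every covered position on both strands (Watson = reference
#' forward strand; Crick records share the same coordinate axis). Duplex
#' methylation states at ApT methylation sites are drawn i.i.d. per molecule
#' from the preset's conditional state distribution; methylated adenines emit
#' from the elevated log-normal component. A configurable fraction of
#' molecules are globally dispersed (inflated per-molecule noise) or carry an
#' injected N* cluster (a run of non-A positions with elevated IPD ratios),
#' emulating the sequencing-instability artifacts the QC filters remove.
#'
#' @param genome a [make_genome()] `sim_genome`.
#' @param preset a [methylation_preset()].
#' @param n_molecules number of molecules to draw (0 gives an empty table).
#' @param mean_len mean molecule length in bp (>= 500); lengths are normal
#'   around this with 10% CV, truncated to `[500, chrom_len]`.
#' @param seed integer seed; the generator is a pure function of
#'   `(genome, preset, n_molecules, mean_len, seed, site_seed)`.
#' @param site_seed optional separate seed for the methylation-site model.
#'   By default sites are drawn from the same stream as the molecules; give
#'   the same `site_seed` to several calls to simulate independent molecule
#'   batches over one shared set of methylation sites.
#'
#' @return A list of class `sim_molecules`:
#' \describe{
#'   \item{molecules}{long data.table, one row per (molecule, strand,
#'     position): molecule_id, chrom, start, end, passes, strand (W/C),
#'     position, base, ipd_ratio.}
#'   \item{truth}{ground truth: `$sites` (per ApT duplex: chrom, pos,
#'     gene_id, meth, intensity, pen_W, pen_C — expected per-strand
#'     penetrance), `$genes` (per gene true sigma-P and site counts),
#'     `$molecules` (per molecule: dispersed/nstar flags, extra noise SD),
#'     `$states` (per molecule x methylation-site duplex: drawn state),
#'     `$genome_fraction` (true genome-wide 6mApT/ApT over full-intensity
#'     sites).}
#' }
#' @export
simulate_molecules <- function(genome, preset, n_molecules, mean_len = 1000L,
                               seed = 1L, site_seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(preset, "methylation_preset"))
  if (mean_len < 500) stopf("mean_len must be >= 500 bp")
  n_molecules <- as.integer(n_molecules)

  em <- preset$emission
  disp <- preset$dispersion
  cond <- preset$cond_state_probs

  with_seed(seed, {
    site_model <- if (is.null(site_seed)) build_site_model(genome, preset)
                  else with_seed(site_seed, build_site_model(genome, preset))

    if (n_molecules == 0L) {
      return(structure(list(
        molecules = empty_molecule_table(),
        truth = list(sites = site_model, genes = site_model_gene_truth(site_model, genome),
                     molecules = data.table::data.table(
                       molecule_id = integer(), dispersed = logical(),
                       nstar = logical(), sd_mol = numeric(), passes = integer()),
                     states = data.table::data.table(
                       molecule_id = integer(), chrom = character(), pos = integer(),
                       state = character()),
                     genome_fraction = site_model_fraction(site_model))
      ), class = "sim_molecules"))
    }

    chrom_names <- names(genome$chroms)
    chrom_lens <- vapply(genome$chroms, length, integer(1))
    chrom_idx <- sample.int(length(chrom_names), n_molecules, replace = TRUE,
                            prob = chrom_lens)

    lens <- as.integer(round(rnorm(n_molecules, mean_len, 0.1 * mean_len)))
    lens <- pmin(pmax(lens, 500L), chrom_lens[chrom_idx])
    starts <- as.integer(floor(runif(n_molecules) * (chrom_lens[chrom_idx] - lens + 1L)))
    passes <- sample(seq.int(preset$passes_range[1], preset$passes_range[2]),
                     n_molecules, replace = TRUE)

    dispersed <- runif(n_molecules) < disp$rate
    sd_mol <- ifelse(dispersed,
                     runif(n_molecules, disp$sd_dispersed[1], disp$sd_dispersed[2]),
                     runif(n_molecules, disp$sd_normal[1], disp$sd_normal[2]))
    nstar <- runif(n_molecules) < preset$nstar_rate

    mol_info <- data.table::data.table(
      molecule_id = seq_len(n_molecules), chrom = chrom_names[chrom_idx],
      start = starts, end = starts + lens, passes = passes,
      dispersed = dispersed, nstar = nstar, sd_mol = sd_mol
    )

    # -- duplex states at methylation-capable sites ------------------------
    meth_sites <- site_model[intensity > 0]
    states <- draw_duplex_states(mol_info, meth_sites, cond)

    # -- long per-position table ------------------------------------------
    molecules <- build_position_table(mol_info, genome, em, states)

    # -- N* cluster injection ---------------------------------------------
    inject_nstar_clusters(molecules, mol_info[nstar == TRUE], em)

    truth <- list(
      sites = site_model,
      genes = site_model_gene_truth(site_model, genome),
      molecules = mol_info[, .(molecule_id, dispersed, nstar, sd_mol, passes)],
      states = states[, .(molecule_id, chrom, pos, state)],
      genome_fraction = site_model_fraction(site_model)
    )
    structure(list(molecules = molecules, truth = truth),
              class = "sim_molecules")
  })
}

# Decide which ApT duplexes are methylation sites and at what intensity.
# Intensity m in (0,1] scales the conditional state distribution: a molecule
# at that duplex uses the methylation-site distribution with probability m
# and is unmethylated otherwise. Global selection uses an exact count
# round(site_fraction * n_eligible); per-gene overrides are applied first.
build_site_model <- function(genome, preset) {
  apt <- data.table::copy(genome$apt)
  if (!nrow(apt)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  gene_id = character(), meth = logical(),
                                  intensity = numeric(), pen_W = numeric(),
                                  pen_C = numeric()))
  }
  apt[, gene_id := assign_to_genes(chrom, pos, genome$genes)]
  apt[, `:=`(meth = FALSE, intensity = 0)]

  pen <- preset$site_penetrance
  pi2 <- sum(pen)  # expected duplex penetrance sum at intensity 1

  override_genes <- character()

  sfo <- preset$site_fraction_overrides
  if (!is.null(sfo)) {
    for (gid in names(sfo)) {
      rows <- which(apt$gene_id %in% gid)
      if (!length(rows)) stopf("site_fraction_overrides: gene '%s' has no ApT sites", gid)
      k <- round(sfo[[gid]] * length(rows))
      pick <- if (k > 0) rows[sample.int(length(rows), k)] else integer()
      apt[pick, `:=`(meth = TRUE, intensity = 1)]
      override_genes <- c(override_genes, gid)
    }
  }

  spo <- preset$sigma_p_overrides
  if (!is.null(spo)) {
    for (gid in names(spo)) {
      rows <- which(apt$gene_id %in% gid)
      target <- spo[[gid]]
      k <- floor(target / pi2)
      frac <- (target - k * pi2) / pi2
      need <- k + (frac > 1e-9)
      if (length(rows) < need) {
        stopf("sigma_p override %.2f for gene '%s' needs %d ApT duplexes, only %d present",
              target, gid, need, length(rows))
      }
      pick <- rows[sample.int(length(rows), need)]
      if (k > 0) apt[pick[seq_len(k)], `:=`(meth = TRUE, intensity = 1)]
      if (frac > 1e-9) apt[pick[need], `:=`(meth = TRUE, intensity = frac)]
      override_genes <- c(override_genes, gid)
    }
  }

  eligible <- which(!(apt$gene_id %in% override_genes))
  k <- round(preset$site_fraction * length(eligible))
  if (k > 0) {
    pick <- eligible[sample.int(length(eligible), k)]
    apt[pick, `:=`(meth = TRUE, intensity = 1)]
  }

  apt[, `:=`(pen_W = intensity * pen[["W"]], pen_C = intensity * pen[["C"]])]
  apt[]
}

site_model_gene_truth <- function(site_model, genome) {
  gt <- site_model[!is.na(gene_id),
                   .(true_sigma_p = sum(pen_W + pen_C),
                     n_apt_duplex = .N, n_meth_duplex = sum(meth)),
                   by = gene_id]
  out <- merge(genome$genes[, .(gene_id)], gt, by = "gene_id", all.x = TRUE)
  for (cl in c("true_sigma_p", "n_apt_duplex", "n_meth_duplex")) {
    data.table::set(out, which(is.na(out[[cl]])), cl, 0)
  }
  out
}

# True genome-wide 6mApT/ApT: fraction of ApT adenine sites belonging to a
# full-intensity methylation site (fractional-intensity override duplexes are
# excluded from the numerator; they exist only to hit exact sigma-P targets).
site_model_fraction <- function(site_model) {
  if (!nrow(site_model)) return(NA_real_)
  sum(site_model$intensity >= 1) / nrow(site_model)
}

# Draw per-molecule duplex states at methylation-capable sites.
draw_duplex_states <- function(mol_info, meth_sites, cond) {
  empty <- data.table::data.table(molecule_id = integer(), chrom = character(),
                                  pos = integer(), intensity = numeric(),
                                  state = character(), meth_W = logical(),
                                  meth_C = logical())
  if (!nrow(meth_sites) || !nrow(mol_info)) return(empty)

  dup <- meth_sites[, .(chrom, mstart = pos, mend = pos + 1L, dstart = pos,
                        intensity)]
  mols <- mol_info[, .(molecule_id, chrom, mstart = start, mend = end - 1L)]
  data.table::setkey(mols, chrom, mstart, mend)
  ov <- data.table::foverlaps(dup, mols, by.x = c("chrom", "mstart", "mend"),
                              type = "within", nomatch = NULL)
  if (!nrow(ov)) return(empty)
  pairs <- ov[, .(molecule_id, chrom, pos = dstart, intensity)]

  n <- nrow(pairs)
  active <- runif(n) < pairs$intensity
  cum <- cumsum(cond[c("Full", "Hemi-W", "Hemi-C")])
  r <- runif(n)
  st <- c("Full", "Hemi-W", "Hemi-C", "Un")[findInterval(r, cum) + 1L]
  st[!active] <- "Un"
  pairs[, state := st]
  pairs[, `:=`(meth_W = state %chin% c("Full", "Hemi-W"),
               meth_C = state %chin% c("Full", "Hemi-C"))]
  pairs[]
}

# Expand molecules into the long per-position table and emit IPD ratios.
build_position_table <- function(mol_info, genome, em, states) {
  lens <- mol_info$end - mol_info$start
  idx <- rep.int(mol_info$molecule_id, lens)
  position <- sequence(lens, from = mol_info$start)
  chrom <- rep.int(mol_info$chrom, lens)

  base_w <- character(length(position))
  for (ch in names(genome$chroms)) {
    sel <- chrom == ch
    base_w[sel] <- genome$chroms[[ch]][position[sel] + 1L]
  }

  half <- data.table::data.table(
    molecule_id = idx, chrom = chrom,
    start = rep.int(mol_info$start, lens), end = rep.int(mol_info$end, lens),
    passes = rep.int(mol_info$passes, lens), position = position
  )
  w <- data.table::copy(half)[, `:=`(strand = "W", base = base_w)]
  c_ <- half[, `:=`(strand = "C", base = unname(DNA_COMPLEMENT[base_w]))]
  molecules <- data.table::rbindlist(list(w, c_), use.names = TRUE)

  sdv <- sqrt(em$sdlog^2 + mol_info$sd_mol[molecules$molecule_id]^2)
  molecules[, ipd_ratio := exp(rnorm(.N, em$meanlog_unmeth, sdv))]

  if (nrow(states)) {
    meth_keys <- data.table::rbindlist(list(
      states[meth_W == TRUE, .(molecule_id, chrom, position = pos, strand = "W")],
      states[meth_C == TRUE, .(molecule_id, chrom, position = pos + 1L, strand = "C")]
    ))
    if (nrow(meth_keys)) {
      rows <- molecules[meth_keys, on = .(molecule_id, chrom, position, strand),
                        which = TRUE, nomatch = NULL]
      sdm <- sqrt(em$sdlog^2 + mol_info$sd_mol[molecules$molecule_id[rows]]^2)
      data.table::set(molecules, rows, "ipd_ratio",
                      exp(rnorm(length(rows), em$meanlog_meth, sdm)))
    }
  }

  data.table::setcolorder(molecules, MOLECULE_COLS)
  molecules[]
}

# Overwrite a short run of non-A positions with elevated IPD ratios on one
# strand of each flagged molecule (5 positions, so the >=4 N* chain rule
# fires even if one draw falls below the 2.8 bound).
inject_nstar_clusters <- function(molecules, flagged, em, n_sites = 5L) {
  if (!nrow(flagged)) return(invisible(molecules))
  idx_all <- molecules[molecule_id %in% flagged$molecule_id & base != "A",
                       which = TRUE]
  cand <- molecules[idx_all, .(molecule_id, strand, position)]
  cand[, mol_row := idx_all]
  data.table::setorder(cand, molecule_id, strand, position)
  rows_sel <- integer()
  for (i in seq_len(nrow(flagged))) {
    mid <- flagged$molecule_id[i]
    str <- sample(c("W", "C"), 1L)
    span <- flagged$end[i] - flagged$start[i]
    anchor <- flagged$start[i] + sample.int(max(span - 60L, 1L), 1L) - 1L
    cm <- cand[molecule_id == mid & strand == str]
    sel <- cm[position >= anchor]
    if (nrow(sel) < n_sites) sel <- cm
    if (nrow(sel) < 4L) next
    rows_sel <- c(rows_sel, head(sel$mol_row, n_sites))
  }
  if (length(rows_sel)) {
    data.table::set(molecules, rows_sel, "ipd_ratio",
                    exp(rnorm(length(rows_sel), em$meanlog_meth, em$sdlog)))
  }
  invisible(molecules)
}

#' @export
print.sim_molecules <- function(x, ...) {
  n <- if (nrow(x$molecules)) length(unique(x$molecules$molecule_id)) else 0L
  cat(sprintf("sim_molecules: %d molecules, %d position records, true 6mApT/ApT %s\n",
              n, nrow(x$molecules),
              ifelse(is.na(x$truth$genome_fraction), "undefined",
                     sprintf("%.3f%%", 100 * x$truth$genome_fraction))))
  invisible(x)
}

#' Write/read the long molecule table as TSV
#'
#' One row per (molecule, strand, position) with columns `molecule_id,
#' chrom, start, end, passes, strand, position, base, ipd_ratio`.
#'
#' @param molecules a long molecule table (or `sim_molecules`).
#' @param file path to a tab-separated file.
#' @return `read_molecules_tsv` returns a data.table in the same long form.
#' @export
write_molecules_tsv <- function(molecules, file) {
  if (inherits(molecules, "sim_molecules")) molecules <- molecules$molecules
  assert_molecule_table(molecules)
  data.table::fwrite(molecules, file, sep = "\t")
  invisible(file)
}

#' @rdname write_molecules_tsv
#' @export
read_molecules_tsv <- function(file) {
  m <- data.table::fread(file, sep = "\t")
  assert_molecule_table(m)
  m
}
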