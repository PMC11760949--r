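#' Filter molecules on CCS passes
#'
#' Retains high-confidence single molecules with `passes >= min_passes`
#' (boundary inclusive). Operates on the long per-position table and keeps
#' molecule order.
#'
#' @param molecules long molecule table (see [simulate_molecules()]).
#' @param min_passes minimum number of CCS passes (default 20).
#' @return The retained rows of `molecules`.
#' @export
filter_passes <- function(molecules, min_passes = 20L) {
  if (inherits(molecules, "sim_molecules")) molecules <- molecules$molecules
  assert_molecule_table(molecules)
  if (min_passes < 1L) stopf("min_passes must be >= 1")
  molecules[passes >= min_passes]
}

#' Global dispersion filter on unmethylated-adenine IPD ratios
#'
#' A molecule is globally dispersed when the sample standard deviation of
#' IPD ratios over its unmethylated adenine positions (adenines with
#' `ipd_ratio < unmeth_cutoff`) reaches `sd_cutoff` on the Watson and/or
#' Crick strand. Strands with fewer than two qualifying adenines contribute
#' no SD and never trigger removal; molecules with no adenine records at all
#' are kept and flagged `"no-adenine"`.
#'
#' @param molecules long molecule table.
#' @param unmeth_cutoff IPD ratio below which an adenine is treated as
#'   unmethylated (default 2.8).
#' @param sd_cutoff sample-SD threshold (default 0.35, boundary inclusive).
#' @return data.table, one row per molecule: `molecule_id`, `sd_W`, `sd_C`
#'   (NA when fewer than 2 qualifying adenines), `remove_molecule`, `flag`.
#' @export
global_dispersion_filter <- function(molecules, unmeth_cutoff = 2.8,
                                     sd_cutoff = 0.35) {
  if (inherits(molecules, "sim_molecules")) molecules <- molecules$molecules
  assert_molecule_table(molecules)
  ids <- unique(molecules$molecule_id)

  st <- molecules[base == "A" & ipd_ratio < unmeth_cutoff,
                  .(n = .N, s = sd(ipd_ratio)), by = .(molecule_id, strand)]
  st[n < 2L, s := NA_real_]
  wide <- data.table::dcast(st, molecule_id ~ strand, value.var = "s")
  for (cl in c("W", "C")) if (!cl %in% names(wide)) wide[, (cl) := NA_real_]
  data.table::setnames(wide, c("W", "C"), c("sd_W", "sd_C"))

  has_a <- molecules[base == "A", unique(molecule_id)]
  out <- data.table::data.table(molecule_id = ids)
  out <- merge(out, wide, by = "molecule_id", all.x = TRUE, sort = FALSE)
  out[, remove_molecule :=
        (!is.na(sd_W) & sd_W >= sd_cutoff) | (!is.na(sd_C) & sd_C >= sd_cutoff)]
  out[, flag := data.table::fifelse(molecule_id %in% has_a, "", "no-adenine")]
  out[]
}

#' Local N*-cluster artifact filter
#'
#' High-density N* sites are non-A bases with IPD ratio >= `nstar_ipd`. Per
#' strand, qualifying positions are chained while each successive gap is
#' <= `max_gap` bp; a molecule is removed when any chain on a single strand
#' holds >= `min_count` members (strands are never pooled).
#'
#' @param molecules long molecule table.
#' @param nstar_ipd IPD-ratio bound defining an N* site (default 2.8,
#'   inclusive).
#' @param max_gap maximum distance between successive N* sites in a chain
#'   (default 25 bp, inclusive).
#' @param min_count minimum chain size triggering removal (default 4).
#' @return data.table, one row per molecule: `molecule_id`,
#'   `max_chain` (largest N* chain on any single strand),
#'   `n_nstar` (qualifying positions), `remove_molecule`.
#' @export
local_artifact_filter <- function(molecules, nstar_ipd = 2.8, max_gap = 25L,
                                  min_count = 4L) {
  if (inherits(molecules, "sim_molecules")) molecules <- molecules$molecules
  assert_molecule_table(molecules)
  ids <- unique(molecules$molecule_id)

  cand <- molecules[base != "A" & ipd_ratio >= nstar_ipd,
                    .(molecule_id, strand, position)]
  if (nrow(cand)) {
    data.table::setorder(cand, molecule_id, strand, position)
    cand[, gap := c(0L, diff(position)), by = .(molecule_id, strand)]
    cand[, chain := cumsum(gap > max_gap), by = .(molecule_id, strand)]
    chains <- cand[, .N, by = .(molecule_id, strand, chain)]
    per_mol <- chains[, .(max_chain = max(N), n_nstar = sum(N)),
                      by = molecule_id]
  } else {
    per_mol <- data.table::data.table(molecule_id = integer(),
                                      max_chain = integer(), n_nstar = integer())
  }
  out <- data.table::data.table(molecule_id = ids)
  out <- merge(out, per_mol, by = "molecule_id", all.x = TRUE, sort = FALSE)
  out[is.na(max_chain), `:=`(max_chain = 0L, n_nstar = 0L)]
  out[, remove_molecule := max_chain >= min_count]
  out[]
}

#' Run the full molecule QC (passes, global dispersion, N* clusters)
#'
#' Applies the three filters in sequence and tallies a QC report. The
#' retained set equals the intersection of the per-filter keeps: each filter
#' is per-molecule, so the outcome is order-independent; the report
#' attributes each removed molecule to the first filter it fails.
#'
#' @param molecules long molecule table or `sim_molecules`.
#' @param min_passes,unmeth_cutoff,sd_cutoff,nstar_ipd,max_gap,min_count
#'   filter parameters; see [filter_passes()],
#'   [global_dispersion_filter()], [local_artifact_filter()].
#' @return list: `molecules` (retained long table), `report` (counts:
#'   n_input, n_fail_passes, n_removed_global, n_removed_local, n_retained),
#'   `per_molecule` (molecule_id, reason: retained / passes / global / local).
#' @export
run_qc <- function(molecules, min_passes = 20L, unmeth_cutoff = 2.8,
                   sd_cutoff = 0.35, nstar_ipd = 2.8, max_gap = 25L,
                   min_count = 4L) {
  if (inherits(molecules, "sim_molecules")) molecules <- molecules$molecules
  assert_molecule_table(molecules)

  mol_passes <- unique(molecules[, .(molecule_id, passes)])
  n_input <- nrow(mol_passes)
  fail_passes <- mol_passes[passes < min_passes, molecule_id]

  stage1 <- molecules[!molecule_id %in% fail_passes]
  glob <- global_dispersion_filter(stage1, unmeth_cutoff, sd_cutoff)
  fail_global <- glob[remove_molecule == TRUE, molecule_id]

  stage2 <- stage1[!molecule_id %in% fail_global]
  loc <- local_artifact_filter(stage2, nstar_ipd, max_gap, min_count)
  fail_local <- loc[remove_molecule == TRUE, molecule_id]

  retained <- stage2[!molecule_id %in% fail_local]

  per_molecule <- data.table::data.table(molecule_id = mol_passes$molecule_id,
                                         reason = "retained")
  per_molecule[molecule_id %in% fail_passes, reason := "passes"]
  per_molecule[molecule_id %in% fail_global, reason := "global_dispersion"]
  per_molecule[molecule_id %in% fail_local, reason := "local_nstar"]

  report <- data.table::data.table(
    n_input = n_input,
    n_fail_passes = length(fail_passes),
    n_removed_global = length(fail_global),
    n_removed_local = length(fail_local),
    n_retained = n_input - length(fail_passes) - length(fail_global) -
      length(fail_local)
  )
  stopifnot(report$n_retained == length(unique(retained$molecule_id)) ||
              report$n_retained == 0L)
  list(molecules = retained, report = report, per_molecule = per_molecule)
}
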