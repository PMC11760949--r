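#' Construct a methylation preset for the molecule simulator
#'
#' A preset bundles everything the single-molecule simulator needs: how many
#' ApT duplex sites are methylation sites, the duplex-state mix at those
#' sites, the IPD-ratio emission model, the molecule-level dispersion model,
#' artifact injection rates, and the CCS passes distribution.
#'
#' The site model reflects how 6mA occurs in *Tetrahymena*: methylation is
#' concentrated at a minority of discrete ApT sites with high penetrance,
#' rather than smeared thinly over all sites. A fraction `site_fraction` of
#' ApT duplexes are designated methylation sites (as an exact count, so the
#' simulated ground-truth 6mApT/ApT equals the configured value up to
#' rounding); at a methylation site, each sequenced molecule draws its duplex
#' state i.i.d. from the conditional distribution implied by
#' `full_hemi_ratio` and `p_un_site`:
#' \deqn{P(Full) : P(Hemi) = r : 1, \quad P(Un) = p\_un\_site,}
#' with Hemi split evenly between Hemi-W and Hemi-C. At all other sites every
#' molecule is unmethylated. The genome-wide marginal duplex-state
#' probabilities (`$state_probs`) are derived from these and sum to 1.
#'
#' IPD ratios are emitted log-normally: unmethylated adenines and all non-A
#' bases around meanlog `emission$meanlog_unmeth` (ratio 1), methylated
#' adenines around `emission$meanlog_meth`. The default separation
#' (ratio 6 vs 1, sdlog 0.25) gives a clearly bimodal pooled adenine
#' distribution whose crossing point is consistent with the 2.8 working bound
#' for unmethylated adenines.
#'
#' @param name preset label.
#' @param site_fraction fraction of ApT duplex sites that are methylation
#'   sites (the configured genome-wide 6mApT/ApT, as a fraction).
#' @param full_hemi_ratio ratio of Full to Hemi (Hemi-W + Hemi-C) duplex
#'   observations at methylation sites.
#' @param p_un_site probability that a molecule shows no methylation at a
#'   methylation site (1 - site penetrance at the duplex level).
#' @param emission list: `meanlog_unmeth`, `meanlog_meth`, `sdlog` of the
#'   log-normal IPD-ratio emissions.
#' @param dispersion list: `rate` (fraction of molecules that are globally
#'   dispersed), `sd_normal`, `sd_dispersed` (ranges of the per-molecule
#'   extra log-scale noise SD for normal and dispersed molecules).
#' @param nstar_rate fraction of molecules receiving an injected N* cluster
#'   (a run of non-A positions with elevated IPD ratios).
#' @param passes_range inclusive integer range of the CCS passes
#'   distribution (discrete uniform), chosen to exercise both sides of the
#'   passes >= 20 filter.
#' @param sigma_p_overrides optional named numeric vector: per-gene target
#'   sigma-P (sum of per-site penetrance over the gene body). Inside these
#'   genes the global site model is replaced by whole duplexes at intensity 1
#'   plus one fractional duplex so the true sigma-P matches exactly.
#' @param site_fraction_overrides optional named numeric vector: per-gene
#'   6mApT/ApT fraction applied as an exact site count within the gene.
#'
#' @return An object of class `methylation_preset`.
#' @export
methylation_preset <- function(name, site_fraction, full_hemi_ratio,
                               p_un_site = 0.05,
                               emission = list(meanlog_unmeth = 0,
                                               meanlog_meth = log(6),
                                               sdlog = 0.25),
                               dispersion = list(rate = 0.05,
                                                 sd_normal = c(0.02, 0.10),
                                                 sd_dispersed = c(0.40, 0.55)),
                               nstar_rate = 0.02,
                               passes_range = c(10L, 40L),
                               sigma_p_overrides = NULL,
                               site_fraction_overrides = NULL) {
  if (site_fraction < 0 || site_fraction > 1) stopf("site_fraction must be in [0,1]")
  if (p_un_site < 0 || p_un_site >= 1) stopf("p_un_site must be in [0,1)")
  if (full_hemi_ratio < 0) stopf("full_hemi_ratio must be >= 0")

  p_meth <- 1 - p_un_site
  if (is.finite(full_hemi_ratio)) {
    c_full <- p_meth * full_hemi_ratio / (1 + full_hemi_ratio)
    c_hemi <- p_meth / (1 + full_hemi_ratio)
  } else {
    c_full <- p_meth
    c_hemi <- 0
  }
  cond <- c(Full = c_full, `Hemi-W` = c_hemi / 2, `Hemi-C` = c_hemi / 2,
            Un = p_un_site)
  stopifnot(abs(sum(cond) - 1) < 1e-12)

  s <- site_fraction
  marg <- c(Full = s * cond[["Full"]], `Hemi-W` = s * cond[["Hemi-W"]],
            `Hemi-C` = s * cond[["Hemi-C"]],
            Un = 1 - s * (1 - cond[["Un"]]))
  stopifnot(abs(sum(marg) - 1) < 1e-12)

  structure(
    list(name = name, site_fraction = site_fraction,
         full_hemi_ratio = full_hemi_ratio,
         cond_state_probs = cond, state_probs = marg,
         # expected per-strand penetrance at a full-intensity methylation site
         site_penetrance = c(W = cond[["Full"]] + cond[["Hemi-W"]],
                             C = cond[["Full"]] + cond[["Hemi-C"]]),
         emission = emission, dispersion = dispersion,
         nstar_rate = nstar_rate, passes_range = as.integer(passes_range),
         sigma_p_overrides = sigma_p_overrides,
         site_fraction_overrides = site_fraction_overrides),
    class = "methylation_preset"
  )
}

#' Named methylation presets calibrated to the four strain conditions
#'
#' Returns a preset whose genome-wide 6mApT/ApT and full/hemi ratio are set
#' to the values estimated for the corresponding strain: wild type
#' (6mApT/ApT 2.03%, full/hemi 7.58), the catalytically dead AMT1-APPA point
#' mutant (0.50%, 0.02), the AMT1 knockout (0.53%, 0.02) and inducible
#' AMT1-RNAi knockdown (1.02%). No full/hemi value is reported for the
#' knockdown beyond "lower than wild type"; 3.8 is used as a plausible
#' intermediate between the wild-type and null regimes.
#'
#' @param name one of `"WT"`, `"APPA"`, `"dAMT1"`, `"RNAi"`.
#' @param ... further arguments passed to [methylation_preset()] (e.g.
#'   per-gene overrides).
#' @return A `methylation_preset`.
#' @export
preset_6ma <- function(name = c("WT", "APPA", "dAMT1", "RNAi"), ...) {
  name <- match.arg(name)
  pars <- switch(name,
    WT    = list(site_fraction = 0.0203, full_hemi_ratio = 7.58),
    APPA  = list(site_fraction = 0.0050, full_hemi_ratio = 0.02),
    dAMT1 = list(site_fraction = 0.0053, full_hemi_ratio = 0.02),
    RNAi  = list(site_fraction = 0.0102, full_hemi_ratio = 3.8)
  )
  methylation_preset(name = name, site_fraction = pars$site_fraction,
                     full_hemi_ratio = pars$full_hemi_ratio, ...)
}

#' @export
print.methylation_preset <- function(x, ...) {
  cat(sprintf("methylation_preset '%s': 6mApT/ApT %.2f%%, full/hemi %s\n",
              x$name, 100 * x$site_fraction, format(x$full_hemi_ratio)))
  cat("  duplex-state probabilities (marginal):\n")
  print(round(x$state_probs, 6))
  invisible(x)
}
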