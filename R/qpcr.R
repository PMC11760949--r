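#' 6mA-IP qPCR fold enrichment (delta-delta-Ct)
#'
#' Implements the Livak comparison of a methylated target against the
#' unmethylated rDNA reference:
#' \deqn{\Delta Ct = Ct(IP) - Ct(Input), \qquad
#'       \Delta\Delta Ct = \Delta Ct(\mathrm{target}) -
#'                         \Delta Ct(\mathrm{rDNA}),}
#' with fold enrichment \eqn{2^{-\Delta\Delta Ct}}. Replicate Ct values
#' (typically three technical replicates) are averaged before the
#' subtraction.
#'
#' @param ip_target,input_target Ct replicates (numeric vectors) of the
#'   target locus in the IP and input samples.
#' @param ip_reference,input_reference Ct replicates of the unmethylated
#'   reference locus (rDNA) in IP and input.
#' @return list: `delta_ct_target`, `delta_ct_reference`, `ddct`, `fold`.
#' @export
ip_qpcr_enrichment <- function(ip_target, input_target,
                               ip_reference, input_reference) {
  ms <- lapply(list(ip_target = ip_target, input_target = input_target,
                    ip_reference = ip_reference,
                    input_reference = input_reference), ct_mean)
  d_t <- ms$ip_target - ms$input_target
  d_r <- ms$ip_reference - ms$input_reference
  ddct <- d_t - d_r
  list(delta_ct_target = d_t, delta_ct_reference = d_r, ddct = ddct,
       fold = 2^(-ddct))
}

#' RT-qPCR relative expression (delta-delta-Ct)
#'
#' \deqn{\Delta Ct = Ct(\mathrm{gene}) - Ct(\mathrm{internal\ control}),
#'       \qquad
#'       \Delta\Delta Ct = \Delta Ct(\mathrm{target\ strain}) -
#'                         \Delta Ct(\mathrm{control\ strain}),}
#' relative expression \eqn{2^{-\Delta\Delta Ct}}. Swapping the strains
#' inverts the result exactly, and adding a constant to every Ct leaves it
#' unchanged.
#'
#' @param gene_target,control_target Ct replicates of the gene of interest
#'   and the internal-control gene in the target strain.
#' @param gene_reference,control_reference the same in the reference
#'   (control) strain.
#' @return list: `delta_ct_target`, `delta_ct_reference`, `ddct`,
#'   `relative_expression`.
#' @export
rt_qpcr_relative_expression <- function(gene_target, control_target,
                                        gene_reference, control_reference) {
  ms <- lapply(list(gene_target = gene_target, control_target = control_target,
                    gene_reference = gene_reference,
                    control_reference = control_reference), ct_mean)
  d_t <- ms$gene_target - ms$control_target
  d_r <- ms$gene_reference - ms$control_reference
  ddct <- d_t - d_r
  list(delta_ct_target = d_t, delta_ct_reference = d_r, ddct = ddct,
       relative_expression = 2^(-ddct))
}

# Mean Ct over technical replicates, with validation.
ct_mean <- function(ct) {
  if (length(ct) == 0L || any(!is.finite(ct))) {
    stopf("missing or non-finite Ct values")
  }
  if (any(ct <= 0)) stopf("Ct values must be > 0")
  mean(ct)
}
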