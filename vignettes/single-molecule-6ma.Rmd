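---
title: "Single-molecule 6mA analysis: models, parameters and design choices"
author: "sixma package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule 6mA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixma)
library(data.table)
```

# The problem

DNA N6-methyladenine (6mA) in the *Tetrahymena* macronucleus occurs almost
exclusively at ApT dinucleotides. Because the motif is symmetric in duplex
DNA — an adenine on each strand, offset by 1 bp — every ApT duplex on every
sequenced molecule is in one of four states: fully methylated (**Full**),
methylated on the Watson strand only (**Hemi-W**), on the Crick strand only
(**Hemi-C**), or unmethylated (**Un**). SMRT circular-consensus sequencing
(CCS) reads this out molecule by molecule: the polymerase pauses at a
methylated adenine, and the inter-pulse-duration (IPD) ratio — observed
pause over the expected unmodified pause — is elevated on the methylated
strand.

`sixma` implements the full analysis around this readout: per-molecule
quality control, determination of the 6mA IPD threshold by deconvolution of
the bimodal adenine IPD distribution, duplex-state calling, and the summary
statistics used to compare strains (site penetrance, gene-level
$\Sigma P$, genome-wide 6mApT/ApT, full/hemi ratio, metagene profiles),
together with the satellite analyses of the same study: nucleosome
positioning degree and ChIP enrichment, spike-in size-factor normalization
with a simple differential-expression adapter, and
$\Delta\Delta C_t$ qPCR arithmetic. A synthetic-data module generates every
input with exported ground truth, so each statistic can be validated by
parameter recovery.

# The synthetic-data model

## Genome and ApT sites

`make_genome()` builds an AT-rich random genome (A 35%, C 12.5%, G 12.5%,
T 40%, matching a strongly AT-biased ciliate genome) in which ApT
dinucleotides are *only* created deliberately: the background is scrubbed of
accidental A→T adjacencies and ApT sites are then placed on a stride-3 grid
at a configurable density (default 100 sites/kb, near the density expected
from the base composition). The full set of ApT duplex positions is
therefore known exactly, which makes the denominator of every 6mApT/ApT
statistic exact. Coordinates are 0-based and half-open throughout; an ApT
duplex is addressed by its Watson-strand adenine position $p$, with the
Crick adenine at $p+1$. Non-overlapping gene models are packed with random
gaps and strands.

## Where methylation lives: the site model

Genome-wide 6mApT/ApT in this system is a fraction of *sites* — methylated
adenine sites (supported by at least three molecules) over all covered ApT
adenine sites — not a per-molecule event rate. Real 6mA is concentrated at
discrete, high-penetrance sites rather than smeared uniformly. The
generator therefore works site-first:

* a preset designates an exact count $\mathrm{round}(s \cdot N)$ of the $N$
  ApT duplexes as **methylation sites** (so the simulated ground truth
  equals the configured fraction $s$ up to rounding);
* at a methylation site, each covering molecule draws its duplex state
  i.i.d. from a conditional distribution with $P(\mathrm{Un}) = 0.05$ and
  the Full:Hemi odds set by the configured full/hemi ratio $r$
  (Hemi split evenly between strands):
  $P(\mathrm{Full}) = 0.95\,r/(1+r)$, $P(\mathrm{Hemi}) = 0.95/(1+r)$;
* all other sites are unmethylated on every molecule.

The marginal per-duplex state probabilities (what a naive genome-wide
summary would see) are exposed on the preset object and sum to 1. Had the
generator instead drawn states i.i.d. at *every* duplex with a 2% marginal
methylation probability, the high-confidence site-counting estimator could
not recover 2% — $P(\mathrm{Binom}(20, 0.02) \ge 3) \approx 0.7\%$ — which
is exactly why the site-first parameterisation is the right emulation of
the data the estimator was designed for.

Four named presets carry the strain calibrations: wild type (6mApT/ApT
2.03%, full/hemi 7.58), the catalytically dead AMT1-APPA mutant (0.50%,
0.02), the AMT1 knockout (0.53%, 0.02) and AMT1-RNAi knockdown (1.02%). No
full/hemi value is reported for the knockdown beyond "lower than wild
type"; the preset uses 3.8, an intermediate value consistent with partial
loss of maintenance methylation. It is a package choice, not a reported
number.

Two per-gene override mechanisms support gene-focused experiments:
`site_fraction_overrides` pins a gene's 6mApT/ApT as an exact site count
(used for the AMT1-like 11.71%-over-3.07%-background recovery), and
`sigma_p_overrides` fills whole duplexes at intensity 1 plus a single
fractional-intensity duplex so the gene's true $\Sigma P$ equals its target
*exactly*. The concentrated allocation (few high-penetrance sites rather
than many weak ones) mimics real 6mA architecture and happens to minimise
the variance of the $\Sigma P$ estimator at fixed coverage — with per-site
penetrance $p$ and coverage $n$, $\mathrm{Var}(\widehat{\Sigma P}) \approx
\Sigma P\,(1-p)/n$, decreasing in $p$.

## IPD emissions, dispersion and artifacts

IPD ratios are emitted log-normally: unmethylated adenines and all non-A
bases at $\ln(\mathrm{IPD}) \sim \mathcal N(\ln 1.0,\ 0.25^2)$, methylated
adenines at $\mathcal N(\ln 6.0,\ 0.25^2)$. The separation was chosen so
the pooled adenine distribution is clearly bimodal with a crossing point
consistent with the 2.8 working bound below which adenines are treated as
unmethylated (equal-weight crossing $\approx 2.45$; at realistic
methylated-class weights the crossing sits at $\approx 2.8$). A smaller
separation (e.g. mode at ratio 5 with scale 0.3) leaves $\sim$1%
of methylated adenines below any sensible cutoff; because hemi duplexes
are $\sim$8-fold rarer than full ones in wild type, even a 1%
per-strand miss rate converts enough Full observations into spurious Hemi
calls to bias the full/hemi ratio 15–25% low. At the chosen separation the
residual bias is $\approx 2\%$. The emission law is a stand-in for
unpublished instrument kinetics and is isolated in the preset so it can be
swapped.

Each molecule also carries a multiplicative log-scale noise term
$\sigma_{\mathrm{mol}}$ from a two-component distribution: normal molecules
draw $\sigma_{\mathrm{mol}} \sim U(0.02, 0.10)$ (total unmethylated-adenine
IPD SD $\approx 0.27$, safely below the 0.35 exclusion rule), and a
configurable fraction (default 5%) draw $U(0.40, 0.55)$, which reliably
trips the rule. A further 2% of molecules receive an injected **N\***
cluster — five consecutive non-A positions on one strand rewritten with
methylated-level IPDs — so the local-artifact filter has true positives to
find (five are injected so the $\ge 4$ chain rule still fires if one draw
lands below 2.8). CCS passes are discrete-uniform on 10–40, exercising both
sides of the $\ge 20$ filter; with artifacts at their default rates,
$\approx 63\%$ of simulated molecules survive the full QC.

## What the generator does not emulate

No base-calling or alignment error, no sequence-context kinetic variation
beyond A vs non-A, no correlation of methylation state between neighbouring
sites or along lineages of molecules, no strand-specific coverage bias, and
no partial duplex coverage (both strands of a covered position are always
observed — single-strand sites arise only at molecule boundaries). Passing
recovery tests on these synthetics therefore validates the *estimators and
their wiring*, not robustness to every artifact of real SMRT data.

# Molecule QC

Three per-molecule filters, applied in sequence but independent in outcome
(a molecule is removed iff it fails at least one):

* **passes**: retain `passes >= 20` (boundary inclusive);
* **global dispersion**: per strand, the *sample* SD (n−1 denominator;
  conventional for small per-molecule site counts) of IPD ratios over
  unmethylated adenines (adenine positions with IPD < 2.8); remove when
  either strand reaches SD $\ge$ 0.35. Strands with fewer than two
  qualifying adenines contribute no SD — removal on undefined evidence
  would bias against short molecules — and molecules without adenines are
  kept and flagged;
* **local N\* clusters**: per strand, non-A positions with IPD $\ge 2.8$
  are chained while successive gaps are $\le 25$ bp; remove when any chain
  reaches 4 members. "Within a distance of 25 bp" is read as
  adjacent-gap chaining (not whole-cluster diameter); the alternative
  reading would only make clusters rarer and is switchable via the gap
  parameter. Strands are never pooled.

The 2.8 used inside QC is the fixed working bound, not the per-sample
deconvolved cutoff; both are parameters.

# Threshold deconvolution

`fit_ipd_threshold()` fits a two-component Gaussian mixture to
$\ln(\mathrm{IPD})$ by EM, initialised from k-means with fixed quantile
centres so the fit is deterministic given the data (the seed only governs
subsampling of very large pools, capped at $5\times10^5$ points). The
calling cutoff is the closed-form equal-posterior point between the two
component means — where $w_1\phi_1(x) = w_2\phi_2(x)$ — which minimises
misclassification under the fitted model.

The pool is the ApT-context adenine IPDs of QC-retained molecules (both
strands of each covered duplex), matching the duplex-centric scatter the
cutoff will be applied to. Restricting to ApT context keeps the
methylated-class weight near 2% in wild type; pooling all genomic adenines
would dilute it $\sim$4-fold and starve the minor component.

A fit only counts as bimodal if (i) the two-component model beats a single
Gaussian by more than 10 BIC units — EM happily splits a unimodal
distribution into two overlapping halves, and mean-separation checks alone
do not catch that — (ii) the component means are at least one pooled scale
apart, and (iii) the minor weight is at least 1%. Otherwise the fixed
working cutoff 2.8 is returned with `bimodal = FALSE`. In practice the
wild-type preset deconvolves (cutoff $\approx 2.84$) while the heavily
demethylated presets fall back — their methylated fraction sits below the
1% weight floor — and both paths classify essentially identically because
the components are far apart. One global cutoff is fitted per sample, not
per strand.

# Calling and summary statistics

`call_duplexes()` emits one observation per molecule × ApT duplex covered
on both strands (Watson adenine at $p$, Crick at $p+1$); ties at the cutoff
are called methylated, consistent with the inclusive conventions of the QC
rules. The four states partition the observations exactly.

* **Penetrance** of an adenine site: methylated molecules / covering
  molecules; each strand of a duplex is its own site. Sites with
  $\ge 3$ methylated molecules are **high-confidence**.
* **Genome-wide 6mApT/ApT**: high-confidence methylated sites over all
  *covered* ApT adenine sites (covered, not all genomic sites, so shallow
  regions do not deflate the estimate; switchable by filtering the
  penetrance table).
* **Full/hemi ratio**: Full over (Hemi-W + Hemi-C) duplex-molecule
  observations — molecule-level, each molecule's view of each duplex
  counted once. `Inf` when hemi observations are absent but full ones
  exist, `NA` when both are absent.
* **$\Sigma P$** of a gene: sum of site penetrance over sites whose duplex
  Watson-anchor lies in $[\mathrm{start}, \mathrm{end})$, strand-agnostic
  (penetrance is defined per adenine, so both adenines of a duplex
  contribute). This makes $\Sigma P$ exactly additive over any partition of
  the gene interval.
* **Metagene profile**: genes scaled to unit length and flanked by one unit
  on each side; each unit divided into 30 bins oriented from the TSS; the
  profile is summed penetrance per bin across genes.

```{r small-run}
g <- make_genome(seed = 1, chrom_len = 12000, n_genes = 3, apt_density = 100)
sim <- simulate_molecules(g, preset_6ma("WT"), n_molecules = 600,
                          mean_len = 800, seed = 2)
res <- analyze_molecules(sim, g, seed = 3)
res$qc
res$threshold$cutoff
c(estimated = res$fraction, configured = sim$truth$genome_fraction)
```

# Chromatin metrics

Fragments are length-selected to 120–260 bp (inclusive). "Fragments within
$k$ bp of a dyad" is interpreted as *fragment midpoint* within the closed
window $[d-k, d+k]$ — the midpoint approximates the fragment's own dyad;
the whole-fragment-overlap alternative is not implemented but the window
arithmetic is isolated in one function. On integer positions the
positioning degree (±25 over ±75 counts) has a floor of $51/151 \approx
0.338$ under fully random placement, and `simulate_fragments()` solves its
tight/loose mixture weight against that floor so the *expected measured*
degree equals the requested one. Gene-level positioning averages the 2–3
dyads nearest the TSS *inside* the gene body (the +1/+2/+3 nucleosomes;
genes with fewer than two usable dyads are undefined rather than
extrapolated). ChIP enrichment divides per-total-fragment normalized
midpoint counts (CPM-equivalent; "normalized number of fragments" is not
specified further, and any common rescaling cancels in the ratio).

# Spike-in normalization and the DE adapter

Size factors come straight from the exogenous spike-in totals:
$f_i = z_i / \exp\!\big(\tfrac1n \sum_j \ln z_j\big)$, i.e. centring on the
geometric mean, so $\prod_i f_i = 1$ exactly. Counts are divided by these
factors. This is the quantity of interest; the downstream test is a
deliberately simple, documented adapter — Welch's t on
$\log_2(\mathrm{normalized} + 0.5)$ with Benjamini–Hochberg adjustment —
because reimplementing shrinkage-based NB machinery is out of scope and
the adapter is replaceable. Fold-change and significance cutoffs follow the
co-downregulation rule: $\log_2\mathrm{FC} \le -1$ (inclusive; the stricter
of the two readings in circulation) and $p_{\mathrm{adj}} < 0.05$, further
intersected with reduced 6mA ($\Delta 6mA < 0$).

Two properties of the 3-vs-3 Welch design matter for interpretation: its
type-I error on log-NB counts is mildly conservative ($\approx 0.03$–0.05
at nominal 0.05), and with only 2–4 effective degrees of freedom a lone
true positive among thousands of genes cannot reach small BH-adjusted
p-values no matter how large its fold change. Recovery is therefore
validated on a contingent of affected genes (10% of the transcriptome at
$\log_2\mathrm{FC} = -2$, the realistic scale of a methyltransferase
knockdown), where both the fold-change estimates and
$p_{\mathrm{adj}} < 0.05$ for $\ge 90\%$ of affected genes hold. The NB
dispersion default is 0.01, typical of well-behaved biological replicates
at high counts.

# qPCR arithmetic

Both assays use the Livak form, fold $= 2^{-\Delta\Delta C_t}$ (the
equations define $\Delta\Delta C_t$; the exponentiation convention is the
standard one and matches using input DNA as the reference). IP enrichment:
$\Delta C_t = C_t(\mathrm{IP}) - C_t(\mathrm{Input})$ per locus,
$\Delta\Delta C_t$ against unmethylated rDNA. Relative expression:
$\Delta C_t = C_t(\mathrm{gene}) - C_t(\mathrm{JMJ1})$ per strain,
$\Delta\Delta C_t$ against the control strain. Technical replicates are
averaged before subtraction. Exact identities — strain-swap inversion and
invariance to adding a constant to all $C_t$ values — are enforced in the
tests. Amplification-efficiency correction is out of scope.

# Numerical and testing choices

Undefined statistics are sentinels, never errors: `NA` for 0/0-type ratios
(no covered sites, no dyad support), `Inf` for a full/hemi ratio with full
but no hemi observations. Degenerate EM fits (vanishing variance or
weight) fall back to the fixed cutoff. IPDs of exactly 0 are floored at
$10^{-8}$ before the log transform.

Problem sizes: the recovery tests simulate 8000 molecules of mean length
800 bp over a 50-kb genome per preset ($\approx 80\times$ raw coverage);
the acceptance script uses 20000 molecules of 1 kb in two regenerated
batches sharing one methylation-site model (`site_seed`), fitting a single
threshold on the pooled ApT adenine IPDs — equivalent to one large run at
half the peak memory. $\Sigma P$ recovery uses $\approx 20\times$ retained
coverage of a 3-kb gene, matching the depth regime of the original
sequencing. These sizes were chosen to keep Monte-Carlo error several-fold
below each tolerance.

# Known limitations

The generator's independence assumptions (sites, molecules, positions) make
recovered variances optimistic relative to real data. The full/hemi ratio
estimator inherits a small downward bias ($\approx 2\%$ at the default
emissions) from strand-level misclassification of Full duplexes, visible
only because hemi observations are rare; a cutoff fitted per strain removes
most but not all of it. The DE adapter is a placeholder for count-model
inference and should not be used for real differential-expression claims.
Dyad positions are consumed, not called; a nucleosome caller is outside the
package's scope.
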