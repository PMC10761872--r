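---
title: "Models and methods: regulatory divergence across a migratory divide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: regulatory divergence across a migratory divide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the tunable parameters, and the
numerical and design choices made where more than one defensible option
existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The biological setting

Two subspecies of a migratory songbird (here labelled *coastal* and
*inland*) differ in migratory behavior and hybridize in a narrow zone.
Captive birds can be driven through a non-migratory and a migratory
state by photoperiod, and their nocturnal restlessness scored with
motion sensors. Sampling brain tissue from parental and hybrid birds in
both states yields a 2 (subspecies) x 2 (state) expression design plus
hybrids, which together allow three questions to be separated:

1. *What* changes — genes responding to state (E), subspecies (G), or
   their interaction (GxE).
2. *How* it is regulated — cis (allele-linked) versus trans (diffusible)
   divergence, read out from allele-specific expression in hybrids.
3. *What breaks in hybrids* — transgressive expression outside the
   parental range, and its dependence on state.

# The generative model (synthetic data)

Downstream stages are validated against simulated data with known
ground truth, so the generator is explicit. With $s = 1$ in the
migratory state and $0$ otherwise, and per-gene parameters $b$
(baseline log2 mean), $c$ (cis), $t$ (trans), $e$ (state), $\gamma_c$,
$\gamma_t$ (state-dependent cis/trans), $h$ (hybrid offset):

$$
\begin{aligned}
\text{inland parent:}&\quad b + e s\\
\text{coastal parent:}&\quad b + c + t + (e + \gamma_c + \gamma_t) s\\
\text{hybrid inland allele:}&\quad b - 1 + t/2 + (e + \gamma_t/2) s\\
\text{hybrid coastal allele:}&\quad b - 1 + c + t/2 + (e + \gamma_c + \gamma_t/2) s
\end{aligned}
$$

and the hybrid total is the (log2 of the) sum of the two allelic means
plus $h$. The expected coastal-allele share in a hybrid is therefore
$p = 2^{c + \gamma_c s} / (1 + 2^{c + \gamma_c s})$: cis effects move
the allelic ratio, trans effects cancel from it. The hybrid trans term
is the parental midpoint ($t/2$ per allele) — the simplest model in
which a diffusible factor acts equally on both alleles.

Totals are negative binomial with per-gene dispersion
$\phi \sim \mathrm{logNormal}(\log 0.05,\ 0.4)$ (typical bulk RNA-seq
values); per-sample relative abundances are renormalized to a library
size drawn log-normally (sdlog 0.2) around the target depth, making the
data compositional exactly as real RNA-seq is. Hybrid allelic counts are
binomial splits of the gene total at probability $p$ (optionally
beta-binomial via `allelic_rho`; the default is pure binomial because no
allelic noise model is implied by the data the package emulates), spread
over the gene's diagnostic SNPs, and counts conserve:
coastal + inland = gene total per hybrid and gene.

Default design: 4 + 5 birds per parental population in the
non-migratory/migratory state and 8 + 10 hybrids, hybrids split over two
processing batches (per-gene batch effects $\mathcal N(0, 0.2^2)$ on
batches beyond the first) — the layout of the captive experiment this
package models. Every hybrid is heterozygous at all diagnostic SNPs by
default (`prob_het = 1`, an F1-like assumption); natural hybrid zones
violate this, which is why the parameter exists.

Genotype panels follow a Balding–Nichols model: ancestral frequency
uniform on (0.05, 0.95), population frequencies
$\mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$ with variance parameter
$F$ = `fst_target`, genotypes binomial(2, freq), independent
missingness. Under this model the Hudson ratio-of-averages estimator
recovers $F$ in expectation, which the tests check at $F = 0.3$ within
±0.03 on 10^4 sites.

Activity traces are Poisson: each 10-min bin bursts with a
state-dependent probability (defaults 0.005 quiet nights, 0.6 migratory
nights) at intensity 90 raw detections versus 6 otherwise. With 72 dark
bins (a 12-h night) these rates are well-separated: both
misclassification directions have probability below 10^-3.

All randomness flows from one integer seed; each generator and pipeline
stage derives a child seed through a fixed affine map into the 32-bit
range, so runs are bit-reproducible.

# Differential expression

Counts are filtered (< 1 CPM in fewer than 4 samples removed; CPM uses
raw column sums, the conventional definition, and the threshold is
inclusive — a gene at exactly 1 CPM in exactly 4 samples stays).
Size factors are plain median-of-ratios without further rescaling.

Each gene gets a negative-binomial GLM with log link and log
size-factor offset. The three main contrasts (state, subspecies,
interaction) are fit on parental samples under
`~ state * population + batch`; hybrids are excluded by default because
the hybrid contrasts (hybrid vs each parent, per state, under
`~ population + batch`) are what the transgressive caller consumes.
Single-level factors (e.g. batch in a parental-only subset) are dropped
from the design, as are aliased columns.

Dispersion is estimated per gene by maximum likelihood (`MASS::glm.nb`),
then bias-corrected: the ML estimate ignores the $p$ estimated mean
parameters, so $\phi$ is inflated by $n/(n-p)$ and the model refit at
the corrected value; if `glm.nb` fails, a method-of-moments estimate
(floored at $10^{-8}$) is used and the gene flagged non-convergent.
Wald statistics are referred to a $t$ distribution with residual
degrees of freedom rather than the normal. Both choices are small-sample
calibration: with 18 samples, the uncorrected normal-reference Wald test
rejects ~10% at nominal 5% under a fully null simulation; corrected, it
rejects ~5% with a near-uniform p-value distribution (checked in the
acceptance suite, bound ≤ 7%). A likelihood-ratio option (`test =
"lrt"`, reduced model refit at the full fit's dispersion) is provided.
No empirical-Bayes shrinkage across genes is applied — fold-change
estimates for low-count genes are noisier than DESeq2's, which is a
documented divergence, not an accident. FDR control is
Benjamini–Hochberg within each contrast, with non-convergent genes
excluded from the denominator; significance is $q < 0.10$.

# Allele-specific expression and the cis/trans readout

Allele counts are summed per individual and gene over that individual's
heterozygous SNPs, then averaged across individuals (mean-then-ratio).
The alternative — per-individual ratios averaged afterwards — agrees
closely (correlation ≥ 0.9 asserted on synthetic data). Eligibility:
≥ 3 heterozygous individuals for the overall contrast; ≥ 3 per state
*and* ≥ 10 covering reads for the GxE contrast. The read threshold is
pooled across states and alleles by default (`per_state_reads` flips
it); both 2-vs-3-individual and 9-vs-10-read boundaries are exercised in
the tests.

A pseudocount of 0.5 is added to every mean entering a log ratio. It
keeps ratios finite at zero counts and is symmetric under allele swap;
with the read thresholds in place its bias is negligible. Parental fold
changes use size-factor-normalized group means, pooled across states for
the overall mode (subspecies divergence regardless of state) and per
population x state for the double ratios.

The cis/trans inference is an OLS regression of hybrid allelic on
parental fold changes (Spearman offered as a sensitivity option). The
slope estimates the cis fraction of divergence: 1 for pure cis, 0 for
pure trans. The acceptance suite requires slope ∈ [0.9, 1.1] on pure-cis
and ∈ [−0.1, 0.1] on pure-trans architectures, and the same for the GxE
mode on state-dependent (cisE/transE) architectures; the "effect size 2"
of those fixtures is the SD of the effect distribution — with a point
mass all genes share one x value and measurement noise in the parental
ratio attenuates the OLS slope, an instance of regression dilution, not
an implementation error. A specificity property guards the key
inference: state-independent cis divergence must *not* produce a GxE
slope (asserted |slope| < 0.1).

The per-gene ASE test is an exact binomial test of pooled coastal reads
against 0.5, BH-adjusted. This default is a documented choice — the kind
of data the package handles does not pin down a unique test — and it
deliberately ignores individual-level overdispersion, which inflates
significance when allelic counts vary strongly among individuals; treat
per-gene calls as descriptive and the regression as the inference.

# Transgressive expression

Per state, a gene is `over` when both hybrid-vs-parent contrasts have
$q < 0.10$, both fold changes are positive, and the hybrid normalized
group mean exceeds both parental means (`under` symmetric; discordant
directions give `none`). "Outside the parental range" is evaluated on
group means, not per-individual ranges — the significance-plus-direction
clauses already encode the comparison against each parent, and
per-sample ranges would make the call depend on single outlier birds.
Calls are per state because context-dependent misexpression is the
phenomenon of interest; a pooled mode is one flag away.

# Population-genetic statistics at regulatory elements

All interval statistics are ratios of sums: per site, within-population
π counts differing pairs among non-missing allele copies over all pairs,
d~XY~ counts cross-population differing pairs over $n_1 n_2$; interval
values divide summed differences by summed comparisons. Invariant sites
therefore contribute comparisons with zero differences — omitting them
(a mean over variable sites only) inflates π and d~XY~, which is why a
regression test pins the ratio-of-sums convention on a fixture where the
two differ. Missing calls shrink comparison counts and can never create
differences (also asserted). Correctness is established against an
$O(n^2)$ all-pairs brute force on random fixtures with up to 30%
missingness — exact equality, not tolerance.

Two F~ST~ estimators are exposed because they serve different jobs:
Hudson ratio-of-averages ($1 - \bar\pi_w/\bar\pi_b$) as the interval
default, and per-site Weir–Cockerham (which uses observed
heterozygosity) for the nearly-fixed-SNP mask, mirroring the
windowed-versus-per-site split of the tools this workflow is built
around. The mask threshold is strict: a site at exactly F~ST~ = 0.90 is
not masked. Negative F~ST~ estimates are reported as computed — clamping
would bias averages of the estimator.

Elements are assigned to every gene whose interval ±10 kb they overlap
(BED 0-based half-open throughout; VCF positions converted on read).
Elements in several gene windows join all of them, and the association
model treats element–gene pairs as rows — no tie-break is defensible
without annotation the inputs do not carry. The association itself is
`statistic ~ DE + (1 | gene)` by maximum likelihood with a 1-df LRT
against the intercept-only null; the gene random intercept
absorbs the correlation among a gene's elements. If the random-effect
fit is singular, the model falls back to gene-level means and a Welch
t-test, flagged in the output. Null calibration (rejection rate within
[3%, 7%] at α = 0.05 over 500 replicates) is part of the acceptance
suite.

# Behavioral scoring

Raw detections are divided by 3 (the sensor re-arms three seconds after
each detection) without rounding; a bin is active strictly above 20
movements; a night is non-migratory strictly below 5% active dark bins
and migratory strictly above 40%. All three comparisons are strict, so
every boundary case falls toward "not called" — a corrected count of
exactly 20 is inactive, fractions of exactly 0.05 or 0.40 are
intermediate. The dark-bin set comes from the trace's optional `dark`
column because bins per night follow the photoperiod; absent that
column the trace is taken as scotophase-only. The stability rule marks a
night only when its call matches each of the ten preceding nights —
the criterion for considering a bird settled in a state before
sampling. The RFLP ancestry score is the inland-allele fraction over
the diagnostic loci, permutation-invariant and symmetric
(score(swapped alleles) = 1 − score).

# Chance overlap

Expected overlap is exactly $nK/N$; the test is the upper-tail
hypergeometric (draws without replacement). The binomial model would
give the same expectation, so printed expectations cannot distinguish
them; without-replacement is the correct model for drawing gene sets
from a finite background. The expectation is reported unrounded plus in
both common reporting styles (2 dp, nearest integer).

# Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to make every
stochastic bound comfortable on a single CPU: 500-gene pure-architecture
fixtures at depth 10^6 for slope recovery, a 2,000-gene fully conserved
transcriptome for null calibration of the interaction test, 500
replicates for the mixed-model LRT, 10^4 sites for F~ST~ recovery,
100 birds x 10 nights for the classifier, and a 2,000-gene 6%-
transgressive scenario for recall. All of them derive their seeds from
the single `--seed` argument, and the pipeline manifest hashes every
output file so a nondeterminism regression is immediately visible.

# Known limitations

* No read-level simulation: mapping bias, positional effects and
  reference bias are outside the generative model, so passing tests say
  nothing about them. The fixed-SNP mask addresses reference bias only
  at the design level.
* The DE module fits independent per-gene dispersions; with very few
  replicates its fold changes are noisier than shrinkage-based tools.
* The per-gene binomial ASE test ignores among-individual
  overdispersion.
* The hybrid model is F1-like by default; `prob_het` thins
  heterozygosity but does not model ancestry tracts.
* Multi-contig genome-wide F~ST~ must be pooled by the caller;
  `genome_fst_hudson()` handles one contig.
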