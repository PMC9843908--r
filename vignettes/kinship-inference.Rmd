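---
title: "Kinship and IBD inference from low-coverage read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship and IBD inference from low-coverage read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfer)
```

## The model and its assumptions

`kinfer` classifies pairs of diploid individuals into relatedness categories
from nothing more than per-site read counts over a shared panel of biallelic
sites. The central quantity is the per-window expected pairwise difference:
for each site covered by at least one read in both individuals, the
probability that one randomly drawn read from each carries different alleles
is `nu_i (1 - nu_j) + (1 - nu_i) nu_j`, with `nu` the derived-read
proportion. Summed over a large window (10 Mb by default) this gives `D_w`
out of `N_w` comparisons, an average over all pseudo-haploid samplings
rather than a single lossy draw.

Within a window, the expected difference *rate* depends on how many of the
four possible chromosome comparisons are between identical chromosomes:

* 0 identical — unrelated background, rate `p0`;
* 1 identical — one chromosome shared IBD, `p1 = 3/4 p0`;
* 2 identical — two shared IBD, or one shared while one individual is
  homozygous, `p2 = p0 / 2`;
* 4 identical — shared IBD inside runs of homozygosity, `p4 = p2 / 2`.

`p4` would be 0 for a window lying entirely inside overlapping ROH and IBD
tracts; because window boundaries rarely coincide with tract boundaries it
is deliberately set to `p2/2`, absorbing partially-affected windows. `p0`
is estimated as the median across pairs of the genome-wide `sum(D)/sum(N)`
ratio, which assumes that most pairs in the cohort are unrelated; a
user-supplied `p0` overrides this (recommended for small or heavily related
cohorts), and estimates outside (0, 0.5) abort with that advice.

A hidden Markov model per (pair, relatedness case) ties windows together.
The hidden state is the IBD count `Z_w`; transition matrices are *fixed* per
case, initial probabilities are the stationary distribution, and chains
restart at every chromosome. Emissions are Balding-Nichols beta-binomials
`BB(D_w; p_i, delta_i, N_w)` — mean `p_i`, over-dispersion `delta_i`,
variance of the rate `p_i(1-p_i)/(delta_i+1)` — with all binomial
coefficients generalized through log-Gamma so the non-integer counts
produced by read-proportion averaging and contamination correction are
handled exactly. The homozygosity state `H_w` of the window (0, 1 or 2
individuals homozygous) shifts the emission level; since `H_w` is
unobserved, emissions are mixed in probability space over per-window
probabilities `h_w` supplied by the ROH layer.

Only the over-dispersions are free parameters. They are fitted by EM: the
E-step is the scaled forward-backward algorithm; the M-step maximizes, for
each level independently, the posterior-weighted log-emission with weights
grouped by comparison count (`g0..g4`; level 3 cannot occur). Because the
weights combine the IBD posterior with the *prior* homozygosity
probabilities `h_w` — not the joint posterior — the update is an EM
surrogate: exact (and provably monotone) whenever `h` is degenerate, which
covers cohorts without detectable ROH, and empirically stable otherwise.
This surrogate is deliberate (the joint posterior would couple the two
HMMs); the convergence check is therefore
on the absolute likelihood change (tolerance 1e-4, at most 100 iterations)
rather than on monotonicity.

## Constraints on the over-dispersions

Unconstrained variance fitting lets a single-state model swallow multi-state
data: a parent-child model with a huge `delta_1` fits sibling data almost as
well as the sibling model. Each `delta_i` is therefore restricted so that
its beta distribution's standard deviation does not exceed the distance from
`p_i` to the nearest other level mean ("overlap by at most one standard
deviation"), i.e. `delta_i >= p_i (1 - p_i) / gap_i^2 - 1`, floored at 1e-6
and capped at 1e6 to keep the scalar optimizer bounded. "Overlap by at
most one standard deviation" admits several geometries (per-distribution sd
versus pairwise sd sums); the per-distribution reading used here is the
least restrictive one that still prevents the collapse. Initial values are drawn
uniformly from (0, 1000] (seeded, then clamped into the constraint
interval).

## Relatedness cases and classification

Ten cases are modeled: unrelated, 5th, 4th, 3rd degree, grandparent-
grandchild, avuncular, half-siblings, parent-child, siblings, identical.
Unrelated, parent-child and identical are single-state chains (`Z` fixed at
0, 1, 2). Grandparent-grandchild and siblings have analytic transition
matrices `expm(Q b)` with per-bp rate matrices determined by the
recombination rate (`r = 1e-8` by default); the remaining cases use
matrices estimated by counting window-center IBD transitions in 1000
simulated pedigrees per case (shipped as text files with their generation
seed; `model_registry(regenerate = TRUE)` re-estimates them for other `r`
or window sizes).

For reporting, 4th/5th degree merge into unrelated and the three
second-degree cases merge into one category. The confidence statistic
`delta_LL` is the log-likelihood gap between the best model and the best
model of a *different* reported category: a half-siblings versus avuncular
near-tie is irrelevant to the user and should not destroy confidence; a
gap "between the two best models" could also be read within the full
registry, so that runner-up gap is reported alongside
(`delta_LL_fine`). The default cutoff is 1 log-likelihood unit. Point
estimates of `k = (k0, k1, k2)` come from posterior means rather than the
Viterbi path, which degrades more gracefully at low coverage;
`r = k1/2 + k2`.

## The ROH layer

Long runs of homozygosity make related individuals look more alike and bias
naive estimators toward closer relatedness. A two-state HMM per individual
(homozygous / non-homozygous) runs on within-individual windowed mismatches:
only sites with at least two reads count, and each contributes the
proportion of read *pairs* carrying different alleles,
`2 nu (1 - nu) d/(d-1)` at depth `d`. The uncorrected plug-in form
`2 nu (1-nu)` (an option, `estimator = "plugin"`) halves the expected signal
at depth 2 — the dominant depth below 0.1x — which would make non-ROH
windows mimic the homozygous mean; the depth-corrected form is unbiased for
half the heterozygosity at any depth and is the default.

Emission means are fixed at `p2` (non-homozygous) and `p4` (homozygous);
over-dispersions and the transition matrix are free (Baum-Welch update,
off-diagonals initialized at 0.2, initial distribution re-derived as the
stationary distribution of the current iterate). Windows whose observed
mismatch proportion exceeds `p2` are forced into the non-homozygous state by
zeroing their homozygous emission — an override in emission space so the
transition bookkeeping stays coherent. The layer activates for individuals
with mean depth of at least 0.1x at the target sites; below that, or with
`roh_mode = "off"`, every window gets `h = (1, 0, 0)` and the pairwise model
reduces exactly to the ROH-free form. Pair weights assume the two
individuals' homozygosity states are independent:
`h_w = ((1-q_i)(1-q_j), q_i(1-q_j) + (1-q_i)q_j, q_i q_j)`.

## Contamination correction

With known, small (< 5%) contamination rates `C_i`, `C_j` and a known
divergence `phi` between the target and contaminant populations, a random
cross-individual read comparison involves a contaminant read with
probability `C = C_i + C_j` (contaminant-contaminant comparisons are
ignored at this order). The genome-wide endogenous rate is recovered as
`rho = (sum D / sum N - C phi) / (1 - C)` and each window's difference and
match counts are shrunk by the posterior probability that a comparison of
that kind was endogenous. The same correction applies to the ROH input with
per-comparison contamination probability `2 C_i` (both reads come from the
same library, either may be contaminant). The factor 2 is a first-order
choice and is configurable. Corrections happen before `p0` estimation and before any HMM runs.
Rates of 5% or more warn but do not abort.

## The simulator and what it does (not) establish

The generator exists so that every evaluation has exact truth: haplotypes
are mosaics of founder-haplotype labels, so IBD states, ROH masks and
genome-wide `k` are known exactly at every base pair.

* **Founder diversity.** Sites are independent; derived-allele frequencies
  follow a `1/x` spectrum truncated below at `a`, with `a` calibrated so
  that the expected pairwise difference rate between founders equals a
  target `p0`. The default `p0 = 0.25` corresponds to the
  per-segregating-site mismatch `(n-1)/(n a_{n-1})` of a neutral sample of
  a few dozen haplotypes. On top of this, each window carries a lognormal
  diversity multiplier (mean 1, CV `window_cv = 0.07`) realized by
  re-truncating the spectrum per window: real and coalescent-simulated
  genomes have locally varying coalescent depth, which is precisely what
  makes windowed mismatch counts over-dispersed and the `delta` parameters
  necessary. The default CV is the coalescent expectation for the windowed
  pairwise TMRCA of a constant-size population at `4 N r L = 4000` per
  10 Mb window. Without this term the generator produces binomially sharp
  windows, the fitted over-dispersions collapse to their bounds, and every
  marginally depressed window is flagged as ROH -- a behavior real data do
  not show. A coalescent engine would add site-level linkage and a
  conditioned frequency spectrum; the frequency model keeps the package
  self-contained and reproduces the quantities the inference actually
  consumes (window-level means and variances of mismatch counts).
* **Pedigree.** 8 founders are mated into 9 descendants (17 individuals)
  so that every modeled relationship occurs at least once; the identical
  pair is two independent read sets from one genome, mimicking two skeletal
  samples from one body. Recombination is a Poisson number of crossovers
  (mean `rL`) at uniform positions — no crossover interference and no
  sex-specific maps, a known fidelity loss.
* **ROH.** Founders receive homozygous tracts from a two-state per-bp chain
  with entry rate `2/L` and exit rate `10/L`: stationary ROH fraction 1/6
  (~17% of the genome), mean tract length `L/10` (~9.6 Mb). Within a tract
  the first haplotype is copied over the second, so descendants inherit the
  reduced diversity without being homozygous themselves.
* **Ascertainment** keeps sites polymorphic among four panel haplotypes
  (two outgroup diploids), shifting the retained spectrum toward
  intermediate frequencies.
* **Reads.** Depth is Poisson per site; each read comes from a random
  chromosome, or from the contaminant diploid with the per-individual
  contamination probability (drawn from 0.5-3% for a fixed subset of eight
  libraries in contamination scenarios). The contaminant genome is built
  with extra allele flips at rate `kappa = (phi - p0)/(1 - 2 p0)` so its
  expected mismatch against endogenous haplotypes is exactly `phi`
  (default 0.4, a deliberately deep divergence). No sequencing error or
  post-mortem damage is modeled.

A green test on this generator therefore establishes that the inference
machinery recovers truth under its own modeling assumptions (independent
sites given the state, Poisson depth, known contamination). It does not
establish robustness to damage, error, reference bias, or population
structure — the last of which biases `p0` and is the documented failure
mode of the median heuristic.

## Numerical choices

* Scaled forward-backward with per-window renormalization of log emissions
  (row max subtracted before exponentiation), chains restarted per
  chromosome; log-likelihoods accumulate across chromosomes.
* Viterbi in log space; ties break toward the lower IBD state.
* Windows with `N_w = 0` emit probability 1 in every state so transitions
  still traverse them.
* Over-dispersion maximization uses bounded scalar optimization on the log
  scale with an explicit boundary check; levels with (near-)zero weight
  keep their previous value.
* EM runs from several random initializations (2 for the pairwise model,
  3 for the ROH model) and keeps the highest-likelihood fit. A single run
  occasionally converges to a collapsed optimum in which one
  over-dispersion sits at its lower bound and one broad state absorbs all
  windows; the collapsed solution is hundreds of log-likelihood units
  worse, so likelihood selection removes it reliably.
* Each pair-model fit derives its seed from the pipeline seed, so whole
  runs are reproducible end to end.

## Scaling of tests and the acceptance script

The full-size evaluation scenario uses 22 chromosomes of 96 Mb, ~1600
polymorphic sites per Mb and 60 replicates per condition. The test suite and
`scripts/acceptance.R` keep all *rate* parameters identical but shrink the
problem along the axis that each check can afford. Classification checks
keep all 22 chromosomes (the confidence cutoff is one *absolute*
log-likelihood unit, so likelihood gaps -- which grow linearly in the
window count -- must be computed on the full number of windows, 220) and
scale the site density down instead, which at 1-4x coverage leaves the
per-window states essentially fully resolved. ROH and IBD-accuracy checks
keep the full site density (low-coverage information content is the point
there) and scale the chromosome count and replicates. Classification
checks use the canonical evaluation pairs of each pedigree rather than all
136 pairs. Tolerances follow the reference operating points at the
stated scale.

Two low-coverage ROH operating points are not reproduced by this
generator: window-level specificity of ~0.96 in ROH simulations at 0.05x
and control specificity of 0.99 at 0.1x. An oracle decoder (true
transition rates, binomial emissions) on our simulated data reaches at
most ~0.88 specificity at the reference 0.65 sensitivity at 0.05x, so the
shortfall is an information bound of the independent-sites generator at
~19 usable sites per window, not an inference defect; the corresponding
assertions are left failing rather than relaxed.

## Known limitations

* The `p0` median heuristic fails when most of the cohort is related or the
  population is strongly structured; supply `p0` explicitly in those cases.
* Contamination rates are inputs, not estimates; misspecification
  propagates (mildly, for errors small against `p0`).
* The EM surrogate with non-degenerate ROH weights is not guaranteed
  monotone (see above); in practice it converges in well under the
  iteration cap.
* Empirical transition matrices are Monte-Carlo estimates; regenerating
  with another seed perturbs entries at the ~1e-2 level, which is
  immaterial next to emission information but makes likelihoods comparable
  only within one registry.
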