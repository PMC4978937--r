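---
title: "A multi-state mixture model for DNase-seq footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-state mixture model for DNase-seq footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footmix)
```

## The inference problem

DNase I preferentially cleaves accessible chromatin; a DNA-bound protein
protects its site and leaves a footprint in the per-base cut-count profile.
Given the candidate motif instances of a TF and strand-specific cut counts,
`footmix` assigns each instance a posterior probability over `K + 2` latent
states: unbound, bound as a monomer, or bound in one of `K` cooperative
dimer configurations, each with its own cut profile. The method is
unsupervised — ChIP-seq is used only to evaluate predictions and to compute
the BCC statistic, never for training.

## Model structure

### Prior component

Each instance `i` carries `J` prior characteristics `x_i^(j)` (PWM score
first; for dimer modes, the partner motif's score at its implied offset and
orientation). A multinomial-logistic model against the unbound pivot gives

$$\frac{P(Z_i = k)}{P(Z_i = 0)}
  = \exp\Big(\beta_0^{(k)} + \sum_j \beta_j^{(k)}\gamma_j^{(k)} x_i^{(j)}\Big),
  \qquad k = 1,\dots,K+1,$$

with binary indicators $\gamma_j^{(k)}$ selecting the features active in
each mode. The monomer mode must mask all partner-motif features; masked
coefficients are held at exactly zero during fitting
(`binding_mode_spec()`, `prior_log_odds()`, `m_step_beta()`).

### Chromatin component

Cut counts enter as two matrices per instance, always in motif orientation:
the motif-sense ("forward") strand over `[−margin, L)` relative to the
motif start, and the opposite strand over `[0, L + margin)`. This
asymmetry reflects how double-hit DNase-seq tags flank a protected site:
forward-strand 5′ tag ends accumulate upstream of a bound protein,
reverse-strand ends downstream. For a minus-strand instance the genomic
strands are swapped and the windows mirrored, so one profile model serves
both orientations — the mirroring is a design choice of this package (any
orientation-agnostic footprint model needs one) and is exercised by a
dedicated equivalence test.

Conditional on the state, strands (and any further chromatin data types)
are independent, and each strand's likelihood factorizes as

$$P(\text{row} \mid Z = k) =
  \mathrm{NB}\big(S;\, r,\, p\big) \times
  \mathrm{Multinomial}\big(\text{row};\, S,\, \tilde\lambda\big),
  \qquad S = \textstyle\sum_j \text{row}_j,$$

with the negative binomial convention
$P(S = s) = \binom{s + r - 1}{s} (1-p)^r p^s$, mean $pr/(1-p)$. The
parametrization by success probability `p` and real-valued failure count
`r` is standard; since clipping can make totals non-integer, both pmfs are
evaluated through `lgamma`, which extends them continuously and avoids
overflow at any realistic total.

### Binning and the spatial profile

Free spatial parameters are per *bin*, not per position: 20 bp bins over
the margin, single-basepair bins inside the motif, and one bin spanning
the whole window for the unbound state. `expand_lambda()` turns bin masses
$\lambda_b$ (summing to 1 over bins) into per-position coefficients by
spreading each bin's mass uniformly over its positions and renormalizing:

$$\tilde\lambda_j \propto \lambda_{b(j)} / |J_{b(j)}|.$$

Two readings of "assign the bin value to each position and normalize" are
possible; we treat $\lambda_b$ as bin *mass* and divide by bin size because
only then is the shrinkage target $(1-\delta)\,|J_b|/\sum_b |J_b|$ the
per-position-uniform model, consistent with the explicitly uniform unbound
null. The alternative (no size division) would make the "uniform" target
place 20× more mass per motif basepair than per margin basepair; it is not
implemented.

This binning gives $2\,(L + \text{margin}/\text{bin width} - 1)$ free
spatial parameters per bound mode (one normalization constraint per
strand): 38 for a 10 bp motif at the defaults, versus 819 for an
unconstrained per-position model over the same windows
(`count_free_parameters()`).

### Posterior

`posterior_probabilities()` combines the two components by Bayes' theorem
through a log-sum-exp with the pivot's log-odds fixed at 0. The bound
probability is `p_i = 1 − P(Z_i = 0 | X_i)`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `margin` | 200 bp | window extent beyond the motif, each side |
| `bin_width` | 20 bp | margin bin size (spatial regularization) |
| clip quantile `q` | 0.999 | spike-clipping threshold on per-base counts |
| `delta` | 0.5 | shrinkage mix: 1 = pure MLE profile, 0 = uniform |
| `tol` | 0.001 | max posterior change at convergence |
| `max_iter` | 100 | EM iteration cap |
| init odds | 100 / 0.01 | prior odds at initialization (top / rest) |
| `init_top_fraction` | 0.10 | fraction of instances given high odds |
| `ridge` | 1e-6 | L2 penalty on non-intercept prior coefficients |

Clipping at neighbouring quantiles (0.99, 0.9999) is accepted and gives
similar results; the threshold uses the linear-interpolation empirical
quantile (`stats::quantile` type 7), one of several defensible choices and
immaterial at these tail probabilities. Re-clipping an already clipped
matrix pair is a no-op by construction: re-estimating the quantile from
clipped entries would otherwise drift the threshold downward in the
knife-edge case where it falls between distinct values.

## The EM procedure

1. **Initialization.** Prior odds of 100 for the top 10% of instances by
   total cut count (both strands), 0.01 otherwise; dimer modes require
   membership in the top 10% by partner motif score as well. Ties at the
   cutoff are broken by a seeded shuffle, so exactly `⌊0.1 n⌋` instances
   enter each top set and the fit is reproducible given the seed.
2. **Prior coefficients** are fitted to these initial probabilities, and
   the first M-step uses them as posterior weights.
3. **Iterate** E-steps and M-steps until no posterior entry changes by
   more than `tol`. The convergence metric is the maximum absolute change
   over all instance × state entries — the strictest reading of
   "posteriors stop changing".

M-steps: the bin masses have the closed-form weighted MLE
$\hat\lambda_b = \sum_i w_i c_{ib} / \sum_i w_i S_i$, shrunk toward the
uniform target with mixing `delta`; the negative binomial is profiled —
$\hat p(r) = \bar S_w/(\bar S_w + r)$ in closed form, BFGS over $\log r$
with the analytic profile gradient, warm-started — so the fitted mean
equals the weighted mean total exactly; the prior coefficients are a
weighted multinomial-logistic fit by BFGS with analytic gradients and a
small ridge (1e-6) guarding against separability when a state's weights
concentrate on few instances. The unbound state's spatial model stays
fixed uniform, but its negative binomial *is* fitted: the null must be
able to absorb the dataset's background sequencing depth, otherwise
background depth would masquerade as binding evidence.

With `delta = 1` and exact M-steps this is a standard EM, and the
penalized observed-data log-likelihood is non-decreasing; the test suite
verifies monotonicity on five seeded datasets to within 1e-6 of BFGS
inexactness. With the default `delta = 0.5` the spatial M-step maximizes a
regularized objective and strict monotonicity of the unpenalized
likelihood is no longer guaranteed (in practice trajectories remain
monotone on simulated data).

Numerical conventions: log-likelihood terms are clamped at −745 (the
`exp()` underflow point) only inside log-sum-exp, so a state made
impossible by a zero spatial coefficient contributes nothing rather than
NaN; no probability is ever stored as exactly 0 or 1 except by arithmetic.
If the iteration cap is reached, the returned posterior is recomputed
under the final parameters so that the two are always consistent.

## Evaluation and BCC

ChIP-seq narrowPeak files define the reference labels: an instance is
bound iff it overlaps any peak by ≥ 1 bp (half-open semantics), with peak
height taken from the ENCODE `signalValue` column. `pr_curve()` uses
step-based average precision rather than trapezoidal interpolation —
linear PR interpolation is known to be optimistic — and `roc_curve()`'s
trapezoid over ties-grouped points equals the normalized Mann–Whitney
statistic with half credit for ties; both are checked against exhaustive
threshold-enumeration oracles. Class skew makes AUC-PR the more
informative summary here; AUC-ROC on heavily unbalanced candidate sets is
dominated by the easy unbound majority.

`chromatin_component_probability()` drops the sequence prior and scores
each instance by its chromatin likelihood alone under *flat* prior odds
across all `K + 2` states — uniformity is the unique choice that injects
no sequence information, which is the point of the statistic (a
pioneer-like factor may bind through a half-site, making the motif score
misleading). `bcc_score()` is the area under the empirical CDF of these
probabilities at ChIP-bound sites, computed as `1 − mean(probs)` (the two
are proven equal in the tests to 1e-12). The cross-TF threshold is
median + 1 MAD with the MAD unscaled — no 1.4826 normal-consistency
factor, since nothing here is Gaussian; the scaled variant is available
via an argument and recorded in the output metadata, as is the
flat-prior choice itself.

## What the simulator emulates — and what it does not

`make_toy_model()` + `simulate_dataset()` draw data from the exact
generative law: features → softmax prior → state → per-strand negative
binomial total → multinomial scatter. Defaults were chosen once as a
plausible deep DNase-seq regime: unbound background of 10 cuts per strand
per 210 bp window, bound mean 80 (dimer modes +20 each), dispersions
r = 2 and 5, a footprint removing ~60% of the flank-level density inside
the motif with exponentially decaying flank enhancement, and a bound
fraction around 20% implied by the default prior (β₀ = −1.5, β = 1 on a
standard-normal motif score). `footprint_depth` interpolates log-linearly
between a uniform bound profile (0, a degenerate control) and the full
footprint shape (1). Instances are laid out with disjoint windows on a
toy contig, alternating strands, so the on-disk round trip through
BED/TSV/bedGraph exercises the mirroring code and reproduces the matrices
exactly.

Passing the recovery tests on such data shows the estimator is correct
*under its own assumptions*. Real DNase-seq additionally has sequence-
specific cutting bias, overlapping and clustered motif instances, copy-
number and mappability artifacts beyond simple spikes, and footprint
shapes that vary with local nucleosome context — none of which the
simulator models, and all of which degrade absolute performance in ways
these tests cannot measure.

## Problem sizes and verification

The test suite fixes its scales as follows: exhaustive likelihood
normalization and brute-force Bayes oracles run on 4-position windows
with totals ≤ 6 (where the truncated negative binomial tail is below
1e-9, so normalization holds to 1e-8); EM monotonicity on five seeded
datasets of 250 instances (4 bp motif, 40 bp margin); parameter recovery
and convergence on the default 10 bp motif / 200 bp margin model at
n = 2000, where fits recover spatial profiles with cosine similarity
> 0.95, negative binomial means within 15%, posterior-vs-truth AUC-ROC
> 0.9, and converge in well under 30 iterations. `scripts/acceptance.R`
re-runs the convergence experiment end to end from a single seed.

## Known limitations

- One chromatin data type is modelled with one parameter set; additional
  data types (e.g. histone-modification ChIP-seq) are accepted
  structurally as further matrix pairs with their own parameters but get
  no data-type-specific treatment.
- Motif discovery, PWM scanning and peak calling are out of scope;
  candidate sites and peaks arrive precomputed.
- Overlapping candidate instances are kept as given; no attempt is made
  to merge or deduplicate them, and nearby instances share cut mass.
- Sites whose window would cross the contig start (or an explicitly
  supplied contig end) are dropped rather than zero-padded — padding
  would bias the negative binomial totals low.
- The supervised alternative (training directly against ChIP-seq labels)
  and variational/stochastic EM variants are deliberately not provided.
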