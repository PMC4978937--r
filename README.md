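# footmix

Multi-state mixture modelling of strand-specific DNase I cut profiles for
transcription factor (TF) binding site identification, with support for
cooperative dimer binding modes and a Binding-in-Closed-Chromatin (BCC)
statistic that quantifies pioneer-factor-like activity.

## The problem

A TF bound to DNA protects its binding site from DNase I digestion, leaving a
*footprint*: a local depletion of cut sites inside a region of otherwise
elevated accessibility. Given the genome-wide motif instances of a TF (from a
PWM scan, supplied as BED) and per-base, strand-specific DNase-seq cut
counts, `footmix` infers for every candidate site the posterior probability
that it is bound — unsupervised, with no ChIP-seq input. ChIP-seq peaks enter
only for evaluation and for the BCC statistic.

## The model

Each motif instance `i` carries a latent state `Z_i ∈ {0, 1, …, K+1}`:
unbound (0), bound as a monomer (1), or bound in one of `K` cooperative
dimer modes. Two components are combined by Bayes' theorem:

**Prior (sequence) component.** A multinomial-logistic model against the
unbound pivot,

    P(Z_i = k) / P(Z_i = 0) = exp( β₀^(k) + Σ_j β_j^(k) γ_j^(k) x_i^(j) ),

where `x_i^(j)` are prior characteristics (PWM score, partner motif scores,
…) and `γ_j^(k) ∈ {0,1}` selects which features are active in mode `k`
(partner-motif features are masked out of the monomer mode).

**Chromatin component.** Cut counts are collected in motif orientation over
asymmetric windows — forward-strand cuts from 200 bp upstream through the
motif, reverse-strand cuts from the motif through 200 bp downstream — and
clipped at the 99.9% quantile to remove artifactual spikes. Per state and
strand the likelihood factorizes into a negative binomial on the total count
`S` (success probability `p`, real-valued failures `r`, mean `pr/(1−p)`)
and a multinomial on the spatial distribution of the `S` cuts. Spatial
profiles are regularized by binning: 20 bp bins over the margin,
single-basepair bins inside the motif, and a single bin (exactly uniform)
for the unbound state — `2·(L+9)` spatial free parameters per bound mode for
a motif of length `L`, an order of magnitude fewer than an unconstrained
per-position model.

All parameters are fitted by EM: initialization from total cut counts (prior
odds 100 for the top 10%, 0.01 otherwise), a shrinkage estimator
`δ·λ̂ + (1−δ)·|J_b|/Σ|J_b|` (δ = 0.5) for the bin masses, BFGS M-steps for
`β` and `r`, and convergence when no posterior entry changes by more than
0.001.

**BCC.** For ChIP-bound sites, the chromatin-component-only bound
probability (flat prior over states) measures how open the chromatin looks
at sites the TF actually occupies. BCC is the area under the empirical CDF
of these probabilities — equivalently `1 − mean(prob)` — so a factor binding
only open chromatin scores ≈ 0 and a pioneer-like factor scores high.
Across a TF collection, candidates are flagged above median + 1 MAD.

## Worked example

Simulate a dataset from the generative model, write it as standard files,
and fit the model back from those files:

```r
library(footmix)

model <- make_toy_model(K = 0, L = 10, margin = 200, seed = 1)
sim   <- simulate_dataset(model, n = 2000, seed = 42, dir = "fixture")

sites    <- read_candidate_sites("fixture/sites.bed", "fixture/features.tsv")
track    <- load_cut_track("fixture/cuts_fwd.bedGraph", "fixture/cuts_rev.bedGraph")
matrices <- clip_counts(build_cut_matrices(track, sites, margin = 200))

fit <- fit_footprint_model(sites, matrices, modes = sim$modes)
print(fit)
print(fit$params)

roc_curve(p_bound(fit$posterior), sim$true_states > 0)$auc
```

which prints

```
FitResult: converged after 7 iteration(s); final max posterior change 0.00066
ModelParams: K=0 dimer mode(s), motif 10 bp, margin 200 bp (bins of 20 bp), delta=0.5
  state 0: NB mean fwd 10.26 / rev 10.00
  state 1: NB mean fwd 81.28 / rev 78.54
[1] 1
```

The fitted negative binomial means recover the generative values (10 cuts
per strand for the unbound background, 80 for bound sites), and the
posterior bound probability separates the true states perfectly (AUC-ROC
1.000). The chromatin-component probabilities at the truly bound sites give
`bcc_score(...) = 0.003` — as expected for simulated sites that are all in
open chromatin.

The same pipeline is available from the shell via
`inst/scripts/footmix <fit|eval|bcc|simulate> …`.

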