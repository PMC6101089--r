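---
title: "One-bit matrix completion for binary association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-bit matrix completion for binary association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onebitmc)
```

## The problem and the model

Curated databases of microbe–disease associations (and of many other
bipartite biological relationships) record which pairs have been
experimentally linked. Arranged as a `p × q` adjacency matrix `A`, entries
are `+1` where a link is validated, `−1` where absence has been observed,
and unknown elsewhere; only a subset `Ω` of positions (of size `m`) is
observed at all. The prediction task is to rank the unknown pairs by how
likely they are true links.

`onebitmc` treats `A` as a one-bit observation of an underlying
real-valued matrix `X` whose magnitude encodes association strength. Each
observed label is a noisy thresholding:

$$a_{ij} = \mathrm{sign}(x_{ij} + z_{ij}), \qquad z_{ij} \sim N(0, \sigma^2)
\ \text{i.i.d.},$$

so that $P(a_{ij} = +1) = \Phi(x_{ij}/\sigma)$ — a probit regression per
entry. Two structural assumptions make recovery possible from a handful of
bits: `X` is (approximately) low-rank, reflecting that a few latent
factors drive which microbes associate with which diseases, and the
observed positions arrive independently with probability `m/(pq)`
(entrywise Bernoulli, so `|Ω|` is binomial rather than fixed).

The estimate is the constrained maximum-likelihood solution

$$\hat X = \arg\max_X \sum_{(i,j)\in\Omega} \log \Phi(a_{ij} x_{ij}/\sigma)
\quad \text{s.t.} \quad \|X\|_* \le \tau = \sqrt{r\,p\,q},$$

with the nuclear norm (the sum of singular values) as the convex surrogate
for rank and `r` the expected rank. The radius couples `r` to the problem
size: a rank-`r` matrix with entries of order 1 has nuclear norm of order
`√(rpq)`.

An important identifiability caveat: one-bit data determine `X` only up to
a joint rescaling of `X` and `σ`. Scores are therefore meaningful as a
ranking (and through the probabilities `Φ(x̂/σ)`), not as absolute latent
magnitudes, and the package's recovery diagnostics use scale-invariant
criteria — sign accuracy, AUC, rank correlation — never Frobenius error
against a "true" latent matrix.

## Tunable parameters

* `sigma` (> 0, default 0.2): the assumed noise standard deviation, which
  is also the softness of the link. Smaller values push fitted
  probabilities toward 0/1 and reward confident separation; larger values
  flatten the likelihood. Because of the scale coupling above, `sigma` is
  effectively the inverse signal-to-noise ratio the fit assumes.
* `r` (integer in `1..min(p, q)`) or `r_ratio` (fraction of
  `r_max = min(p, q)`, mapped to `r = max(1, round(ratio·r_max))`): the
  expected rank, entering only through the radius `τ = √(rpq)`. Larger
  `r` loosens the constraint toward the unregularised (and, for purely
  positive training data, divergent) MLE.
* Both are data-dependent; `tune_onebitmc()` searches a grid — by default
  `σ ∈ {0.1, …, 1.0}` by `ratio ∈ {1/10, …, 1/2, 1}`, ten by ten — under
  5-fold cross-validation, scored by AUPR, which is more informative than
  AUC when positives are heavily outnumbered. All grid cells share one
  fold assignment so the comparison is free of fold noise; ties go to the
  smaller `r`, then the smaller `σ` (prefer the stronger regulariser).

Solver settings (`spg_control()`) default to the standard spectral
projected gradient choices: 300 iterations, projected-gradient residual
tolerance `1e-6`, nonmonotone memory 10, Armijo parameter `1e-4`, spectral
step clamped to `[1e-10, 1e10]`, initial step `1/‖g(X₀)‖_∞`. These are
this package's defaults, recorded with every fit for reproducibility.

## Numerical choices

* **Objective.** Internally the solver minimises the negative
  log-likelihood (the standard minimisation form for projected-gradient
  methods); the public API reports the log-likelihood. `log Φ` is
  evaluated through `pnorm(log.p = TRUE)` and the gradient's inverse Mills
  ratio as `exp(log φ − log Φ)`, so margins as extreme as `x/σ = −40`
  (routine when cross-validation blinds an entry the rest of the data
  contradicts) stay finite.
* **Projection.** Projection onto the nuclear-norm ball is singular-value
  soft-thresholding; the threshold is the exact closed-form water-filling
  level per sorted prefix, not an iterative bisection, so the projection
  has no tolerance knob. Singular values below `1e-12` are zeroed first as
  numerical rank noise. A full dense SVD is used: at the target problem
  sizes (hundreds of rows by tens of columns) it is cheap, and the exact
  threshold needs the full spectrum.
* **Solver.** The SPG2 variant: feasible direction
  `d = P(X − αg) − X`, nonmonotone backtracking against the maximum of the
  last 10 objective values with safeguarded quadratic interpolation,
  Barzilai–Borwein step `⟨s,s⟩/⟨s,y⟩` (set to the upper clamp on
  nonpositive curvature). Every iterate is feasible by construction.
  Initialisation is the zero matrix — feasible for any radius, symmetric
  between the two classes, and deterministic: a fit has no random element,
  so identical inputs give bitwise-identical traces.
* **Degenerate inputs.** An empty `Ω` is a hard error ("nothing to fit"),
  as is a cross-validation fold whose training part has no positives. A
  `0` label on input is refused rather than guessed (ambiguous between
  "negative" and "unknown"). Score-table ties are broken by (row, column)
  index so output files are deterministic.

## Evaluation protocols

`run_cv()` blinds held-out entries, refits on the remainder, and scores
the blinded entries with the refit latent matrix. AUC is computed as the
Mann–Whitney statistic with midrank tie handling; AUPR as the
non-interpolated step-curve area (average precision) with tied scores
grouped at one threshold — trapezoidal PR interpolation is avoided because
it overestimates.

Two blinding schemes reflect two views of positives-only data:

* `blind = "all_observed"`: every observed entry, positive and negative,
  is cross-validated against its own label.
* `blind = "positives_only"` (default): only positives are blinded, and in
  each fold the held-out positives are ranked against the *candidate
  background* — every pair never observed as positive. Pooled across
  folds this yields a single ROC/PR, mirroring how leave-one-out
  evaluations of association predictors are usually reported; the
  per-fold average is also returned, since with single-positive LOOCV
  folds the pooled and averaged framings genuinely differ (the negative
  pool enters once per fold, which matters for AUPR magnitudes).

The choice of candidate background is itself a modelling decision: when a
database records only positives, `read_association_list()` exposes it as
the `unknown = "negative"` (all unlisted pairs are observed negatives,
the default) versus `unknown = "missing"` (unlisted pairs are unknown)
policy.

## The synthetic-data generator

`generate_latent()` draws `X = L Rᵀ` with i.i.d. Gaussian factors scaled
so the entrywise standard deviation equals `latent_scale` (default 1) and
the rank equals `true_rank` almost surely; `sample_observations()` applies
exactly the observation model above — Gaussian noise, sign thresholding,
entrywise-Bernoulli observation mask (`|Ω|` binomial, not fixed).
`make_benchmark()` additionally holds out a fraction of the observed
entries as a labelled test set. The reference conditions used throughout
the tests and the acceptance script are `p = 60, q = 30, true_rank = 3,
noise_sigma = 0.2, obs_frac = 0.8, test_frac = 0.2` — a shape and
signal-to-noise regime where model-consistent recovery is comfortably
measurable on one CPU in seconds, with smaller instances (tens by tens)
for the cross-validation drivers so the full suite stays fast.

What the generator emulates is the model's own assumptions; what it does
not emulate is everything real association data add on top: the extreme
degree skew of curated databases (a few heavily studied diseases), study
bias in *which* pairs get observed (the Bernoulli-mask assumption is
certainly wrong for literature-curated data, where observation correlates
with publication effort), and any taxonomic or ontological structure among
rows and columns. Green recovery tests therefore certify that the
estimator recovers what the model assumes — internal consistency — not
that real databases satisfy those assumptions.

## Known limitations

* The probit link is the only link; there is no logit variant.
* The constraint is the nuclear-norm ball only — no max-norm or
  entrywise-bound variants from the wider one-bit completion literature.
* Cold-start prediction (a microbe or disease with no observed links) is
  out of scope: such a row or column is unconstrained by the likelihood
  except through the nuclear-norm coupling, and its scores are not
  meaningful.
* The truncated-SVD baseline fills unknowns with a constant (0 by
  default, the midpoint of the ±1 coding; −1 optionally) before
  decomposing; no iterative soft-impute is provided.
* Leave-one-out evaluation refits once per blinded positive; at database
  scale (hundreds of positives) this is hundreds of fits, which is
  tractable but not instant — the k-fold scheme is the practical default.
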