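---
title: "Active-learning campaigns on combinatorial protein landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning campaigns on combinatorial protein landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alde)
```

## The problem

Protein engineering by site-saturation mutagenesis confines the search to a
small set of `k` active-site residues, each of which may carry any of the 20
canonical amino acids: a design space of `20^k` variants (160,000 at `k = 4`)
of which a wet-lab campaign can screen only a few hundred. `alde` implements
batch Bayesian optimization for this setting — fit an uncertainty-aware
surrogate to the variants screened so far, score the unscreened design space
with an acquisition rule that trades off exploitation against exploration,
propose the next plate of variants, repeat — together with the simulation
harness needed to benchmark it against classical directed evolution (DE) on
combinatorially complete landscapes.

## Landscapes

A landscape maps combo strings (one letter per mutated site) to scalar
fitness. Loading from CSV drops combos containing the stop symbol `*`,
upper-cases, and averages replicate rows for the same combination
(arithmetic mean — the natural estimator when replicate yields are pooled).
Fitness is usually max-normalized so the global optimum sits at 1 and a
campaign's "final normalized max fitness" is directly comparable across
landscapes; normalization to a parent/reference variant is also supported
for wet-lab-style objectives.

Real combinatorially complete datasets are only *nearly* complete. When a
simulation queries an unmeasured combo the package treats it as
non-functional (fitness 0) by default, with `missing = "skip"` available to
drop such queries instead; both readings are defensible and the switch makes
the choice explicit.

## The synthetic landscape generator

`generate_synthetic_landscape()` builds a complete landscape from per-site
additive effects plus random interaction effects up to a chosen order, all
drawn from standard normals under a fixed seed:

* each component (additive, epistatic) is standardized to unit variance
  over the full design space and they are combined as
  `sqrt(1 - w) * additive + sqrt(w) * epistatic`, so `epistasis_weight = w`
  is exactly the fraction of noise-free fitness variance carried by
  interactions (linear weights would not have that property);
* Gaussian measurement noise of standard deviation `noise_sd` is then
  added and the result is affinely rescaled to [0, 1].

Defaults (`k = 4`, 20 amino acids, pairwise interactions, `w = 0.5`,
no noise) emulate a four-residue site-saturation library with substantial
pairwise epistasis — the regime in which greedy DE walks start to fail while
model-guided search still has exploitable structure. What the generator does
*not* emulate: measurement heteroscedasticity, missing variants, the heavy
right-skew of enrichment-based fitness assays, and higher-order epistasis
beyond the requested order. Passing tests on synthetic landscapes therefore
demonstrates correctness of the machinery and the expected qualitative
ordering of methods, not performance guarantees on any particular
experimental dataset. Because the rescaling to [0, 1] is monotone and
affine, additive landscapes remain additive, which is what makes the
exhaustive greedy-walk checks exact.

## Encodings

Each site contributes one feature block; blocks are concatenated in site
order, so the feature length is `k * per_residue_dim`:

| encoder | per-residue dim | nature |
|---|---|---|
| `onehot` | 20 | categorical indicators |
| `aaindex` | 4 | continuous physicochemical descriptors |
| `physchem19` | 19 | continuous physicochemical descriptors |
| `embedding_table` | inferred (e.g. 1280) | precomputed learned embeddings |

The 4-dim table is the first four principal components of the 531 complete,
non-constant published AAIndex properties (68.6% of their variance),
computed once and frozen into the package. The 19-dim table is a **synthetic
stand-in** at the dimensionality of the Georgiev descriptor set: the 19
principal components of the same AAIndex matrix (its full rank over 20
residues); only the dimension, not the exact values, matches the published
descriptors, and the bundled file is named accordingly.
Descriptor columns are z-standardized over the 20 alphabet rows at encoder
construction, which keeps GP length scales well-conditioned. Embedding
tables are consumed as plain CSV (global per-symbol or per-(site, symbol)
rows); the package never runs a language model.

## Surrogates

All four surrogates satisfy one predictive contract —
`posterior_stats()` returns a mean and standard deviation per candidate,
`sample_function()` returns a seeded function realization — so acquisition
rules and campaign drivers are model-agnostic. Targets are z-standardized
inside every surrogate and de-standardized on output.

**Gaussian process** (`fit_gp`). Exact GP regression; Matern-5/2 kernel by
default with a single shared length scale (automatic relevance
determination off — with a few hundred observations per campaign round
there is too little data to fit per-dimension scales), squared-exponential
available. Hyperparameters maximize the log marginal likelihood (L-BFGS-B
on log parameters, 100 iterations by default). Numerical choices: noise
variance floored at `1e-6`; Cholesky jitter escalation `0 → 1e-8 → 1e-6 →
1e-4` before declaring the kernel singular; predictive variances clamped at
zero. A feature-dimension cap (default 512) turns the known failure of
plain GPs on protein-language-model-scale inputs into an explicit,
overridable error.

**Deep kernel learning** (`fit_dkl`). A squared-exponential kernel on the
output of a feed-forward feature map (ReLU, hidden widths 64/32, feature
width 8 — small frozen defaults chosen for reproducibility). Network
weights and kernel hyperparameters are optimized jointly by full-batch Adam
(200 epochs, learning rate 1e-2) on the same marginal likelihood, with the
gradient propagated analytically through the kernel matrix into the
network. With the feature map frozen to the identity the model reduces
exactly to `fit_gp`, which the tests exploit as a correctness check.

**Ensembles** (`fit_ensemble`). Five members by default, each trained on a
uniform subsample *without replacement* of 90% of the rows — subsampling
rather than a classical with-replacement bootstrap because the latter would
not give each member exactly 90% unique rows. Members also differ by seeded
weight initialization (for the MLP members), so ensemble spread reflects
both data and initialization variance. The posterior mean is the arithmetic
member mean; the standard deviation is the *sample* (n−1) standard
deviation across members — with five members the n vs n−1 choice changes
sigma by ~12%, so it is frozen and documented here. Base learners: the
package's own MLP (64/32 ReLU, Adam, 300 epochs, early stop after 30
stalled epochs) or gradient-boosted trees via xgboost (100 rounds, depth 3,
learning rate 0.1, single-threaded so fits are reproducible).

## Acquisition

Scores follow `alpha(x) = mu(x) + sqrt(beta) * sigma(x)` with `beta = 4` by
default; greedy is the `beta = 0` special case. Batches are the top-`q`
heuristic: the `q` highest-scoring candidates across the enumerated design
space, with every already-measured variant excluded (re-measuring a known
variant wastes a well and is never useful in simulation). Ties are broken
lexicographically on the combo string under C collation — an arbitrary but
deterministic rule that makes exact-reproducibility tests possible.

Thompson sampling draws one posterior function per batch slot and proposes
its argmax: via 1000 random Fourier features for GP/DKL (Matern-5/2
frequencies are sampled as multivariate-t with 5 degrees of freedom,
squared-exponential as Gaussians; the posterior over feature weights is
sampled exactly by Cholesky), and by drawing one member uniformly for
ensembles. Batch draws are independent, but each pick is excluded from
later draws within the batch so a proposal never contains duplicates — a
deliberate addition on top of plain independent sampling, since duplicate
wells are wasted. Per-draw seeds derive from the acquisition seed by a
counter scheme, so batches are reproducible and order-stable.

## Campaign simulators

`run_alde()` starts from a uniform random batch of `n0` variants (default
96), then for each of `R` rounds (default 4) refits the surrogate *from
scratch* on all accumulated observations, proposes `q` new variants
(default 96), and observes their stored landscape fitness verbatim —
measurement noise, if wanted, belongs in the landscape generator, not the
loop. Budget accounting counts distinct variants; no variant is ever
observed twice. `run_mlde()` is the single-round greedy reduction at
matched budget; `run_random_baseline()` draws the whole budget uniformly.
Replicate campaigns (default 70, the conventional count for reporting mean
and standard deviation of the final normalized max fitness) run under
derived seeds via `run_replicates()`.

`run_de_greedy_walk()` simulates classical DE: sites are visited in a given
order, all 20 substitutions at the focal site are screened *including the
incumbent* — so the walk may keep the current residue rather than being
forced into a deleterious move, which is the only reading under which the
walk is guaranteed never to lose fitness — and the best is fixed.
`run_de_all()` enumerates every active starting variant crossed with all
`k!` site orders (24 at `k = 4`).

Everything downstream of a `(landscape seed, campaign seed)` pair is
bit-reproducible, and `write_campaign()` emits byte-identical CSV/JSON logs
for identical runs; this determinism is itself under test.

## Uncertainty calibration

For a calibrated model an n% central predictive interval should contain n%
of true values. Intervals are taken as Gaussian with the surrogate's
(mu, sigma) — for the frequentist ensembles too, a distributional
assumption that has to be made somewhere and is made explicitly here. The
calibration curve is evaluated on 101 evenly spaced levels with endpoints
pinned at (0,0)/(1,1), and the miscalibration area is the trapezoidal
integral of the absolute deviation from the diagonal (0 = perfect; 0.5 =
the zero-width-interval limit). The Spearman correlation between per-point
predictive sigma and per-point absolute error is computed with average-rank
ties; constant inputs return 0 flagged `degenerate` rather than erroring,
so batch evaluations keep running. Evaluation uses *all measured points*,
training data included — matching the protocol of scoring a campaign's
final-round model on the full measured design space — with held-out
evaluation available but flagged as a different protocol.

## Problem sizes used in the tests and acceptance script

Exhaustive and statistical checks run on deliberately small spaces chosen
so that brute-force enumeration stays exact and replicated campaigns stay
cheap: `k = 3` over 4 amino acids (64 variants) for walk enumeration and
campaign comparisons (20 paired replicates, `n0 = 16`, `R = 2`, `q = 8`,
budget 32); `k = 4` over 3 amino acids for the 24-site-order check; 2000
Monte-Carlo draws for the random-Fourier-feature prior check; 5000 points
for the calibration limits. These sizes are the package's own choices for
fast, exact verification; the defaults users run at (`k = 4`, 20 amino
acids, 96-variant batches) are set by the campaign configuration.

## Known limitations

* Acquisition is single-objective; multi-objective trade-offs must be
  collapsed into one scalar upstream.
* No expected-improvement family and no joint batch acquisition (qEI);
  batches are the top-q heuristic or independent Thompson draws.
* GP hyperparameters are point estimates; no length-scale priors or fully
  Bayesian treatment.
* No recalibration (temperature/isotonic), no NLL/sharpness metrics.
* The DE walk and ALDE loop assume the fitness oracle is deterministic;
  replicate measurement noise lives in the landscape, not the loop.
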