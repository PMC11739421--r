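# alde

Batch Bayesian optimization for protein engineering over combinatorial
variant libraries, plus the simulation harness to benchmark it against
classical directed evolution.

## The problem

Site-saturation mutagenesis at `k` active-site residues defines a design
space of `20^k` amino-acid combinations (160,000 at `k = 4`), of which a
wet-lab campaign screens only a few 96-well plates. Classical directed
evolution (DE) walks this space greedily — fix the best substitution at one
site, move to the next — and gets trapped whenever sign epistasis makes the
path to the optimum pass through deleterious intermediates. `alde`
implements active learning-assisted directed evolution: iterated rounds of

1. fitting an uncertainty-aware surrogate `f` to the screened variants
   `D_n = {(x_i, y_i)}`,
2. scoring every unscreened variant with an acquisition rule
   `alpha_n(x) = mu_n(x) + sqrt(beta_n) * sigma_n(x)` (UCB; `beta_n = 0` is
   greedy) or by Thompson sampling (propose the argmax of a random posterior
   function draw),
3. proposing the top-`q` batch for the next plate.

Surrogates: exact Gaussian processes (Matern-5/2 or squared-exponential),
deep kernel learning `K(x, x') = k(phi_w(x), phi_w(x'))` for
high-dimensional encodings, and bootstrapped boosting / DNN ensembles (5
members, each seeing 90% of the data) whose member spread supplies
`sigma_n`. Thompson sampling uses 1000 random Fourier features for GP/DKL
and a uniform member draw for ensembles. Variant encodings: one-hot (20 per
residue), physicochemical descriptors (4 or 19 per residue), or precomputed
per-residue embedding tables (e.g. 1280-dim protein-language-model
vectors). Uncertainty quality is scored by MAE, calibration curves with
miscalibration area, and the Spearman correlation between predictive sigma
and absolute error.

For whom: protein engineers planning model-guided campaigns (the `propose`
CLI mode consumes an observations CSV and emits the next batch), and method
developers who need reproducible simulated campaigns on complete or
synthetic epistatic landscapes.

## Worked example

Simulate an epistatic 3-site landscape over 4 amino acids (64 variants,
80% of fitness variance from pairwise interactions), run exhaustive DE, one
active-learning campaign, and a replicate comparison:

```r
library(alde)

spec <- synthetic_spec(k = 3, alphabet_size = 4, interaction_order = 2,
                       epistasis_weight = 0.8, noise_sd = 0, seed = 7)
land <- generate_synthetic_landscape(spec)   # complete, max-normalized

de <- run_de_all(land, threshold = 0)        # every active start x all 3! orders
round(de$summary, 3)
#>   mean median     sd    max
#>  0.887  0.985  0.138  1.000

cfg <- campaign_config(encoder = "onehot",
                       model = list(kind = "dnn_ensemble"),
                       acquisition = list(rule = "thompson"),
                       n0 = 16, rounds = 2, q = 8, seed = 3)
run_alde(land, cfg)
#> <alde_campaign> alde: 32 variants observed, final max 1.0000
#>   trajectory: 0.8356 -> 0.9851 -> 1.0000

reps <- run_replicates(land, cfg, replicates = 10, method = "alde")
rand <- run_replicates(land, cfg, replicates = 10, method = "random")
summarize_campaigns(c(reps, rand))
#>   method  n mean_final_max sd_final_max single_replicate
#> 1   alde 10      1.0000000    0.0000000            FALSE
#> 2 random 10      0.9577672    0.0828011            FALSE
```

Reading the numbers: the average DE walk ends at 0.887 of the global
optimum (the median walk does better; the spread comes from walks trapped
on local optima), random screening of 32 variants reaches 0.958 on
average, while the active-learning campaign at the same 32-variant budget
(16 random + 2 rounds of 8 proposals) finds the global optimum in all 10
replicates. The campaign trajectory prints the running maximum of
normalized fitness after the initial batch and after each round.

See `vignettes/active-learning-campaigns.Rmd` for the models, their
assumptions, all tunable parameters, and the numerical choices.

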