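# phasetree

Macroevolutionary analysis with **Coxian phase-type (PH) waiting times**:
simulate species trees in which the time a lineage waits before speciating
or going extinct depends on its age, measure the shape of the resulting
reconstructed phylogenies, and fit competing waiting-time models to branch
lengths by maximum likelihood.

Classic constant-rate birth–death models assume memoryless (exponential)
waiting times and predict trees that are more balanced than real
phylogenies. A Coxian PH distribution routes each lineage through a chain
of phases — from phase *i* it either speciates, at rate
(1−p<sub>i</sub>)λ<sub>i</sub>, or matures into phase *i+1*, at rate
p<sub>i</sub>λ<sub>i</sub> — so the speciation hazard can rise or fall
with age while density, distribution function and moments stay in closed
matrix form:

f(t) = α e<sup>Qt</sup> q,  F(t) = 1 − α e<sup>Qt</sup>**1**,
E[T] = −α Q<sup>−1</sup>**1**,
Var[T] = 2 α Q<sup>−2</sup>**1** − E[T]².

The package is aimed at researchers who want to ask, for a reconstructed
(extant-species) phylogeny or a simulated treeset: *does an age-dependent
speciation process explain these branch lengths better than exponential or
Weibull waiting times or a constant-rate birth–death process?*

## What's inside

* `coxian_ph()`, `ph_dec()`, `ph_inc()` — Coxian PH distributions with
  density/CDF/hazard/moments/CV (`ph_pdf`, `ph_cdf`, `ph_hazard`,
  `ph_mean`, `ph_var`, `ph_cv`, closed forms `moments_dec`/`moments_inc`)
  and exact phase-walk sampling (`ph_sample`).
* `simulate_tree()` / `simulate_trees()` — forward-in-time birth–death
  simulation with arbitrary waiting-time families (PH, exponential,
  Weibull) for speciation and extinction, symmetric or asymmetric
  speciation, and reconstructed (extant-only, ultrametric) views;
  `classify_branches()` splits edges into pendant/internal with the
  elapsed-to-present times the likelihoods need; Newick I/O.
* `extract_splits()`, `beta_mle()`, `beta_ci()` — tree balance via the
  beta-splitting model, pooled over whole treesets ("treeset β"), with
  profile 95% confidence intervals; `gamma_statistic()` for node-time
  spacing.
* `loglik_ph`, `loglik_exp`, `loglik_weibull`, `loglik_crbd`,
  `loglik_nee` — matrix-exponential and closed-form log-likelihoods of
  reconstructed trees, including the constant-rate birth–death factors
  `extinct_prob`, `g_branch`, `d_pendant`.
* `fit_model()`, `aic()`, `model_table()`, `gof_ks()`,
  `hazard_profile()` — multi-start maximum likelihood (L-BFGS-B +
  Nelder–Mead polish), AIC/ΔAIC comparison, simulation-based
  Kolmogorov–Smirnov goodness of fit, and fitted hazard curves.
* A command-line interface (`pt_main()`, installed script
  `exec/phasetree`) with subcommands `simulate`, `beta`, `gamma`, `fit`,
  `compare`, `gof`, `hazard`.

## Worked example

Build the decreasing-rate four-phase distribution, simulate a treeset,
measure its balance, and compare fitted waiting-time models:

```r
library(phasetree)

ph_dec(0.1, 0.93, 10)
#> Coxian phase-type distribution with 4 phase(s)
#>   exit rates q: 9.3000 0.9514 0.8124 0.0010
#>   mean: 2.0232  CV: 30.0809

set.seed(42)
trees <- simulate_trees(wt_model("ph_dec", x = 0.1, y = 0.93, z = 10),
                        n_tips = 50, n_trees = 50)
sum(sapply(trees, function(t) nrow(t$recon$edge)))
#> [1] 4900

s <- extract_splits(trees)
beta_ci(s, beta_mle(s))
#> beta estimate: -0.41709
#>   log-likelihood: -2534.2632  splits: 1250
#>   SE: 0.07591   95% CI: [ -0.55933 , -0.26117 ]
```

The pooled treeset β is about −0.42: a high-dispersion (CV ≈ 30)
age-dependent speciation process produces markedly *imbalanced* trees,
in the direction of empirical phylogenies, whereas a pure-birth process
would sit at β = 0.

```r
set.seed(1)
fits <- list(fit_model(trees, "exponential", n_starts = 10),
             fit_model(trees, "weibull",     n_starts = 10),
             fit_model(trees, "ph_dec",      n_starts = 10))
model_table(fits)
#>         model n_branches n_parameters    logL      AIC delta_AIC
#> 1      PH_Dec       4900            3 2770.22 -5534.45    0.0000
#> 2     Weibull       4900            2 2745.29 -5486.58   47.8718
#> 3 Exponential       4900            1 2735.81 -5469.63   64.8205
```

The generating family wins by ΔAIC ≈ 48 over Weibull and ≈ 65 over the
exponential — age dependence in the speciation process is clearly
detectable from branch lengths alone. An absolute goodness-of-fit check
(`gof_ks(trees, fits[[3]], n_sim = 50)`) simulates trees from the fitted
model and compares pooled log branch lengths by a two-sample KS test;
at 4900 branches the test resolves CDF differences of about 0.03, so even
a refit of the true family gives a marginal verdict (here D = 0.0339) —
worth keeping in mind when interpreting such tests on large trees.

The same pipeline from a shell:

```sh
phasetree simulate --speciation ph_dec:x=0.1,y=0.93,z=10 --ntips 50 \
          --ntrees 50 --seed 42 -o trees.nwk
phasetree beta --trees trees.nwk --ci -o beta.tsv
phasetree fit --trees trees.nwk --model ph_dec --seed 1 -o fit.json
phasetree gof --trees trees.nwk --fit fit.json --nsim 50 --seed 2
phasetree hazard --fit fit.json --grid 0:5:0.05 -o hazard.tsv
```

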