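# sicsreg

Phylogeny-regularized sparse regression for predictive modeling of
microbial community data.

Microbiome studies summarize each sample as read counts over OTUs related
by a phylogenetic tree, and a central task is predicting a phenotype —
disease state, treatment response, an exposure — from those abundances.
Microbiome signals are typically **sparse** (few marker taxa) and
**clustered** on the tree (related taxa act together).  `sicsreg` fits a
sparse generalized linear model whose penalty encodes both: the Sparse
Inverse Correlation Shrinkage (SICS) estimator

$$
\hat\beta = \arg\min_{\beta_0,\beta}\;
\frac{1}{n}\sum_{i=1}^n -\,l(\beta_0,\beta; y_i, x_i)
+ \sum_{j=1}^p \rho(|\beta_j|;\lambda_1,\gamma)
+ \lambda_2\,\beta^\top C(\alpha)^{-1}\beta ,
$$

where $\rho$ is the minimax concave penalty (MCP) and
$C(\alpha)_{ij} = e^{-2\alpha d_{ij}}$ is the phylogeny-induced correlation
on patristic distances $d_{ij}$.  The inverse-correlation penalty smooths
coefficients of phylogenetically close OTUs *locally* (influence decays
fast with tree distance) and keeps a data-driven ridge component; the rate
parameter $\alpha$ tunes the phylogenetic depth of the smoothing.  Lasso,
MCP, Mnet (MCP + ridge) and Sparse Laplacian Shrinkage are special
configurations of the same coordinate-descent/IRLS engine.  The package
also ships the matching simulation framework (Dirichlet-multinomial counts
on a coalescent tree, four signal-placement scenarios, calibrated signal
strength), a real-data preprocessing pipeline (Bray-Curtis outlier
flagging, prevalence filter, GMPR, winsorization, square-root and
rank-normal transforms), cross-validation tuning and a repeated-split
benchmarking harness.

## Worked example

Simulate the phylogeny-informative scenario (one associated clade of 12
OTUs among 200, continuous outcome, strong signal), tune by
cross-validation, and evaluate on held-out samples:

```r
library(sicsreg)

sim <- make_dataset(scenario = "S1", family = "gaussian", signal = "L",
                    seed = 42)
#> simulated dataset: scenario S1, gaussian outcome, signal 2
#>   100 train / 200 test samples, 200 OTUs, 12 associated

cv <- cv_sics(sim$proportions_train, sim$y_train, sim$D,
              family = "gaussian",
              grid = default_grid(alpha_values = c(0, 2^-5, 1, 32),
                                  lambda2_values = c(0, 2^-5, 1, 32)),
              seed = 1)
#> cross-validated SICS (PMSE criterion)
#>   best: alpha = 1, lambda2 = 0.03125, lambda1 = 0.001586 (PMSE = 0.0003472)
#>   65 OTUs selected

pred <- predict(cv, sim$proportions_test)
round(c(R2 = r_squared(sim$y_test, pred),
        PMSE = pmse(sim$y_test, pred)), 4)
#>     R2   PMSE
#> 0.6002 0.0004

selection_metrics(which(abs(cv$fit$beta_std) > 1e-8), sim$A, p = 200)
#> sensitivity specificity
#>   1.0000000   0.7180851
```

Cross-validation lands on a moderate phylogenetic depth (alpha = 1) with a
light smoothness penalty: the model explains 60% of the held-out outcome
variance and recovers all 12 truly associated OTUs (sensitivity 1), at the
cost of carrying some extra OTUs (specificity 0.72) — the smoothing pulls
in neighbours of the associated clade, which is the intended trade-off.

For real data, start from `read_count_table()` / `align_inputs()` /
`preprocess_pipeline()`, then `cv_sics()`.  A thin command-line wrapper
with `simulate`, `preprocess`, `fit`, `cv`, `predict` and `benchmark`
subcommands is installed at `inst/cli/sicsreg.R`:

```sh
Rscript inst/cli/sicsreg.R simulate --scenario S1 --signal L \
    --family gaussian --seed 1 --out sim_out
```

The methods vignette
(`vignettes/phylogeny-regularized-regression.Rmd`) documents the model,
the solver, the tuning procedure, the simulator and all numerical choices.

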