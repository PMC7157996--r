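# smcia — sparse and structured sparse multiple co-inertia analysis

Integrative analysis of two or more omics matrices measured on the same
samples (e.g. transcript abundance from two platforms plus protein
abundance on a common cell-line panel).  Multiple co-inertia analysis
(mCIA) finds, for K sample-matched blocks X₁, …, X_K, per-block loading
vectors u_k and a common *synthetic center* v maximizing the weighted sum
of squared covariances

    max  Σ_k  w_k (vᵀ D X_k Q_k u_k)²    s.t.  u_kᵀ Q_k u_k = 1,  vᵀ D v = 1,

with diagonal sample and feature metrics D and Q_k.  Classical mCIA gives
every feature a nonzero coefficient, which makes the axes hard to
interpret in high dimensions.  This package adds:

* **smCIA** — an ℓ₀ cardinality constraint ‖a_k‖₀ ≤ s_k on each
  transformed loading a_k = Q_k^{1/2} u_k, solved per block by a
  truncated Rayleigh flow (gradient step plus hard thresholding) inside
  an alternating, monotone block-coordinate ascent;
* **ssmCIA** — an additional graph-Laplacian penalty λ_k a_kᵀ L̃_k a_k
  that discourages loadings disagreeing with a prior feature network
  (pathway or regulatory graph);
* T-fold cross-validation for tuning s_k, λ_k and the flow step size;
* a latent-factor synthetic data generator with star-shaped feature
  networks, an eight-scenario benchmark grid, and Monte-Carlo drivers;
* selection/estimation metrics (sensitivity, specificity, Matthews
  correlation, loading angle) and tidy/broom-style accessors.

Who it is for: anyone doing joint dimension reduction of co-sampled
omics blocks who needs *interpretable* (sparse, optionally
network-guided) loadings rather than dense ones.

## Worked example

Simulate two blocks driven by a shared latent factor (true supports of
10 features each), fit a sparse two-axis model, and inspect it:

```r
library(smcia)

cfg    <- scenario_config(NULL, n = 60, p = c(40, 50), sigma2 = 2.5,
                          n_el = 5, n_en = c(2, 2), n_networks = 4)
x      <- sample_dataset(cfg, seed = 42)   # list of 2 matrices, 60 x 40/50
design <- cia_design(x)                    # standardize + default weights
fit    <- fit_smcia(design, s = c(10, 10), n_axes = 2)
fit
#> <cia_fit> method = smcia, 2 axis/axes, K = 2 blocks
#>   axis 1: pseudo-eigenvalue 3.564, nonzeros (10, 10)
#>   axis 2: pseudo-eigenvalue 2.237, nonzeros (10, 10)
```

The pseudo-eigenvalue is the co-inertia objective attained by each axis;
each block's loading has exactly the requested 10 nonzero coefficients.
`tidy()` returns the loadings as a tibble (here the strongest axis-1
features, which lie in the true supports):

```r
tidy(fit) |> dplyr::filter(axis == 1, loading != 0) |>
  dplyr::arrange(dplyr::desc(abs(loading))) |> head(5)
#> # A tibble: 5 × 4
#>    axis block  feature loading
#>   <int> <chr>  <chr>     <dbl>
#> 1     1 block1 b1_f5     -2.69
#> 2     1 block2 b2_f5     -2.66
#> 3     1 block2 b2_f3     -2.56
#> 4     1 block2 b2_f8     -2.43
#> 5     1 block2 b2_f7     -2.32
```

Against the generator's ground truth, the axis-1 estimate of block 1
has absolute cosine 0.912 with the true loading and recovers its support
with sensitivity 0.90, specificity 0.97, MCC 0.87:

```r
truth <- true_loadings(cfg)
loading_angle(fit$axes[[1]]$a[[1]], truth[[1]])
#> [1] 0.912
selection_metrics(fit$axes[[1]]$a[[1]], truth[[1]])
#>      sens      spec       mcc
#> 0.9000000 0.9666667 0.8666667
```

For network-guided fits pass graphs and penalty weights
(`fit_smcia(design, s, lambda, graphs = ...)`), tune with
`tune_smcia()`, and plot with `autoplot(fit)`.  A command-line front end
(`exec/smcia`) exposes `fit`, `tune`, `simulate` and `benchmark`
subcommands over delimited text files.  See the vignette
(`vignettes/smcia-methods.Rmd`) for the model, algorithmic details and
the reasoning behind the defaults.

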