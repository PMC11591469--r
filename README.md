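# mdfuse

Predicting miRNA-disease associations by **gated fusion of dual graph
encoders**, in pure R.

miRNAs are short (~19-24 nt) non-coding RNAs whose dysregulation marks many
diseases; experimentally validated miRNA-disease links form a sparse binary
matrix `G_md` over M miRNAs and N diseases, and inferring the unobserved
cells prioritises candidate biomarkers for wet-lab validation.  `mdfuse`
treats the problem as link prediction on the bipartite heterogeneous graph

```
G = [[0, G_md], [G_md^T, 0]]
```

and scores pairs with a model that combines:

* a **graph-convolutional attention encoder** (GCN pre-encoding, multi-head
  edge attention `alpha_ij = softmax_j LeakyReLU(a^T[W h_i || W h_j])`,
  learnable skip fusion of layer outputs) capturing local neighbourhood
  structure;
* a **graph-convolutional transformer** whose self-attention logits carry a
  negative Gaussian bias in squared hop distance, `-|omega k_ij^2 + b|`,
  blending global dependencies with distance-aware locality;
* a **fine-grained multi-layer gating mechanism**,
  `G = sigmoid(W_g[H_AG || H_TR] + b_g)`,
  `H_fused = G * H_AG + (1 - G) * H_TR`, plus mean-residual and tanh
  interaction units, fusing the two embeddings;
* an **MLP scorer** on `[h_i || h_j || h_i * h_j]` trained with
  cross-entropy on balanced (undersampled) pairs under a stratified 8:2
  split with 5-fold cross-validation.

Node features combine supplied similarity views (miRNA functional, disease
semantic) with Gaussian interaction profile (GIP) kernels computed from the
association matrix.  Every forward/backward pass runs on a small
reverse-mode autodiff tape written for this package and verified against
finite differences; no deep-learning framework is required.

The package is tidyverse-native: edge lists and score tables are tibbles,
fits have `tidy()` / `glance()` / `autoplot()` methods, and a thin CLI
(`inst/cli/mdfuse`) wraps the exported functions.

## Worked example

Simulate a dataset with planted rank-4 latent structure, train, and inspect:

```r
library(mdfuse)

dat <- simulate_mda_data(synthetic_spec(m = 60, n = 40, rank = 4,
                                        density = 0.1, seed = 7))
cfg <- mda_config(dim = 32, heads = 4, max_epochs = 100, patience = 30)
fit <- train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = cfg, seed = 1)
fit
#> miRNA-disease association fit (variant: full )
#>   nodes: 60 miRNA x 40 disease, dim 32
#>   stopped at epoch 57; test AUC 0.8140, AUPRC 0.8311
tidy(fit)
#> # A tibble: 2 x 8
#>   split        acc    f1 recall precision   auc auprc     n
#>   <chr>      <dbl> <dbl>  <dbl>     <dbl> <dbl> <dbl> <int>
#> 1 validation 0.679 0.682  0.690     0.674 0.778 0.753    84
#> 2 test       0.760 0.731  0.654     0.829 0.814 0.831   104
```

The test AUC of ~0.81-0.90 per seed (mean ~0.87 over seeds 1-3) is read
against two controls: an untrained model scores ~0.49, and a ridge-logistic
baseline on raw interaction profiles scores ~0.63.  Ranking candidates for
one disease:

```r
rank_candidates(fit, "dis-007", k = 5)
#> # A tibble: 5 x 5
#>    rank mirna   disease score known
#>   <int> <chr>   <chr>   <dbl> <lgl>
#> 1     1 mir-006 dis-007 0.694 FALSE
#> 2     2 mir-036 dis-007 0.689 FALSE
#> 3     3 mir-034 dis-007 0.681 FALSE
#> 4     4 mir-015 dis-007 0.670 FALSE
#> 5     5 mir-017 dis-007 0.644 FALSE
```

`run_ablation()` (or `mdfuse ablate` on the command line) trains the full
model and its four ablations -- transformer without self-attention, plain
graph attention encoder, concatenation instead of gating, conventional
transformer -- and reports a test-metric table per variant.

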