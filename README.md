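# multignn

Composite graph-neural-network regression for small-molecule
bioactivity, with descriptor-based QSAR baselines and a consensus
vote-scoring ranker for virtual screening.

## The problem

Ligand-based virtual screening needs a model that maps a molecular
structure to its inhibitory potency, expressed as
pIC50 = −log10(IC50 in mol/L). `multignn` implements this pipeline for
graph inputs: a SMILES string becomes a heavy-atom graph with a
46-slot one-hot feature vector per atom (atom symbol, degree,
hybridization, valence, formal charge, ring-size membership,
aromaticity, attached hydrogens) and a directed COO edge list, and a
graph neural network regresses pIC50 from it. The reference use case
is screening inhibitors of dihydroorotate dehydrogenase (DHODH), a
validated target in small cell lung cancer.

## Models

Four graph-layer operators are provided as composable building blocks:

* **GIN** — graph isomorphism layer,
  `h'_v = MLP((1+ε) h_v + Σ_{u∈N(v)} h_u)`
* **GAT** — attention layer,
  `e_ij = LeakyReLU(a·[Wh_i‖Wh_j])`, `α_ij = softmax_j(e_ij)`,
  `h'_i = σ(Σ_j α_ij W h_j)`
* **ARMA** — spectral filter of K parallel stacks of
  graph-convolutional-skip updates
  `X̄^(t+1) = σ(L̃ X̄^(t) W^(t) + X V^(t))`, `L̃ = D^{-1/2} A D^{-1/2}`
* **SGC** — simple graph convolution `S^K X W`,
  `S = D̃^{-1/2}(A+I)D̃^{-1/2}`

The three composite ("multi-GNN") architectures chain two different
layer types with batch normalization between them — **GIAN**
(GIN + ARMA), **GIAT** (GIN + GAT) and **SGCA** (SGC + ARMA) — followed
by pooled readout and a shared fully connected head
(100 → 200 → 300 → 200 → 1, unactivated output). Training is Adam
(learning rate 0.001, minibatch 32) with early stopping on a held-out
validation RMSE (patience 60, max 1000 epochs) and 10-fold
cross-validation for model selection. Classical baselines (random
forest, RBF-kernel SVR) run on descriptor tables through a fixed
variance-filter → standardize → Lasso-selection pipeline.

Candidates from a docking campaign are ranked by **vote scoring**: per
criterion (docking score, each model's predicted activity) every
candidate in the top 50% earns one point — with N candidates the
threshold is the ⌈N/2⌉-th best score and boundary ties are promoted —
plus one bonus point for multi-target compounds; the summed score
ranks the candidates.

## Worked example

```r
library(multignn)

# deterministic synthetic library: 200 valid SMILES with activity
# pIC50 = 4 + 0.4 (#N + #O) + 0.05 #aromatic - 0.1 #rings + N(0, 0.2^2)
d <- make_synthetic_dataset(synthetic_spec(n_molecules = 200, seed = 7,
                                           sigma = 0.2))
sp <- split_dataset(d, test_fraction = 0.2, seed = 11)

fit <- train_gnn(sp$train, model_config("GIAN", seed = 1),
                 train_config(seed = 1))
fit
#> <multignn_fit> GIAN: 144 epochs (best 84), validation RMSE 0.5119

regression_metrics(predict(fit, sp$test), sp$test$pic50)
#> # A tibble: 1 × 4
#>    rmse r_squared pearson_r     n
#>   <dbl>     <dbl>     <dbl> <int>
#> 1 0.369     0.730     0.865    40
```

The fitted object supports `tidy()` (per-epoch history), `glance()`
(one-row summary) and `autoplot()` (training curves). A test RMSE of
0.37 against a label noise floor of 0.2 and R² of 0.73 says the model
recovered most of the structural signal in the synthetic activity.

Ranking screening candidates:

```r
scores <- zinc_top10_scores()   # docking score + 5 model predictions
total_votes(scores)[, c("id", "total", "rank")]
#> # A tibble: 10 × 3
#>    id           total  rank
#>    <chr>        <dbl> <int>
#>  1 ZINC95618747     5     1
#>  2 ZINC8577218      4     2
#>  3 ZINC2036915      4     2
#>  4 ZINC4261765      4     2
#>  ...
```

The three top-scoring compounds (ZINC95618747, ZINC8577218,
ZINC4261765) are the shortlist a screening campaign would carry into
molecular dynamics.

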