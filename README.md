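# mdagcl

Prediction of candidate miRNA–disease associations (MDAs) from a binary
bipartite association graph, for computational biologists prioritizing
pairs for experimental validation. The package learns node embeddings by
LightGCN-style graph collaborative filtering and regularizes them with two
contrastive objectives designed for sparse neighborhoods, then scores pairs
with an MLP head.

## Model

Given the 0/1 association matrix $A$ ($N_m$ miRNAs × $N_d$ diseases), base
embeddings $X^{(0)}$ are propagated $L$ times through the degree-normalized
bipartite operator

$$X_m^{(l+1)} = \sum_{d \in N_m} \tfrac{1}{\sqrt{|N_m||N_d|}} X_d^{(l)},
\qquad
X_d^{(l+1)} = \sum_{m \in N_d} \tfrac{1}{\sqrt{|N_m||N_d|}} X_m^{(l)},$$

read out as the layer mean $X = \frac{1}{L+1}\sum_l X^{(l)}$, and trained
with

$$L \;=\; L_{BPR} \;+\; \beta_1 L_S \;+\; \beta_2 L_P \;+\; \beta_3\|\Theta\|^2,$$

where $L_{BPR}$ is the Bayesian personalized ranking loss over (positive,
sampled-negative) triples, $L_S$ an InfoNCE contrast between each node's
even-layer and layer-0 embeddings (topological neighbors), $L_P$ an InfoNCE
contrast against k-means prototypes refreshed each epoch in an EM schedule
(semantic neighbors), and $\|\Theta\|^2$ an L2 penalty. Final pair
probabilities come from an MLP on the concatenated readout embeddings,
trained with binary cross-entropy. Defaults: `dim = 64`, `L = 4`, contrast
layer `k = 2`, `tau = 0.1`, 10 prototypes/side, `alpha = 1`,
`beta1 = 1e-6`, `beta2 = 1e-8`, `beta3 = 1e-6`. See the methods vignette
(`vignettes/model-methods.Rmd`) for the full account.

## Worked example

```r
library(mdagcl)

# two-community bipartite graph: within-block edge prob. 0.25, cross 0.02
pg  <- planted_graph(200, 150, n_blocks = 2, p_in = 0.25, p_out = 0.02,
                     seed = 0)
fit <- mdagcl(pg$graph, seed = 1)
print(fit)
#> Contrastive graph collaborative-filtering model
#>   graph: 200 miRNAs x 150 diseases, 4075 associations
#>   dim 64, 4 layers, contrast layer 2, tau 0.1, 10 prototypes
#>   60 encoder epochs run (final total loss 1842.5081)
#>   MLP head (128-32) final BCE 0.5358

# probability that miRNA 7 is associated with disease 3 (same planted block)
predict(fit, pairs = cbind(7, 3))
#> [1] 0.658029

report <- cross_validate(pg$graph, k = 5, seed = 1)
print(report)
#> 5-fold cross-validation (full model, seed 1)
#>     fold    AUC    ACC    SPE    PRE    REC     F1
#>        1 0.7330 0.7117 0.5730 0.6657 0.8503 0.7468
#>        2 0.7216 0.7092 0.6025 0.6724 0.8160 0.7373
#>        3 0.7446 0.7466 0.5804 0.6851 0.9129 0.7827
#>        4 0.7480 0.7160 0.5975 0.6746 0.8344 0.7460
#>        5 0.7351 0.7429 0.5656 0.6793 0.9202 0.7817
#>  Average 0.7365 0.7253 0.5838 0.6754 0.8667 0.7589
```

The `AUC` column is the rank probability that a held-out true association
outscores a sampled non-association; `ACC`/`SPE`/`PRE`/`REC`/`F1` threshold
the MLP probability at 0.5 on balanced test folds. On this instance a
perfect block oracle tops out near AUC 0.75 (both positives and negatives
are mostly within-block), so the model is close to the attainable ceiling;
the numbers say the planted structure is recovered, nothing more.

Other entry points: `rank_candidates()` (leave-one-out case-study ranking),
`ablation_study()` (matched-seed removal of each contrastive term),
`stability_summary()` (boxplot-style five-number summaries over repeated
runs), and a thin CLI (`inst/cli/mdagcl.R`) with subcommands
`simulate | train | cv | predict | rank | sweep`.

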