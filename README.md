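# psciNet

Multimodal hierarchical graph networks for predicting **post-stroke
cognitive impairment (PSCI)** from brain-network data.

## The problem

Roughly a third to a half of stroke survivors develop cognitive impairment
within months of an otherwise small lacunar infarct. The damage is rarely
local: a lesion transects white-matter pathways and disrupts regions far
from the infarct (diaschisis), so prediction benefits from modeling the
whole brain network rather than the lesion alone. psciNet is aimed at
neuroimaging methods researchers who want a tested, reproducible
implementation of that idea: each patient is a graph over `N` cortical
parcels with multimodal radiomic node features, edges fused from anatomy
and an individualized lesion disconnectome, and clinical covariates guiding
the network's attention. The binary outcome is PSCI at 3-month follow-up,
defined by education-specific MoCA cutoffs (≤ 13 illiterate, ≤ 19 primary,
≤ 24 junior high or higher).

## The model

For a patient with node features `X ∈ R^{N×D}`, anatomical adjacency `A_s`,
structural-disconnection matrix `SD ∈ [0,1]^{N×N}` and clinical vector
`X_t`:

1. **Clinically guided node attention** — embed the clinical vector,
   `F_t = LReLU(X_t W_t + b_t)`, use it as a single attention query over
   regions, `A_node = softmax(QKᵀ/√D_k)`, and rescale node `i` by
   `N·A_node[i]`.
2. **Dynamic edges over a fused prior** — `A_prior = SD + A_s`; per layer a
   multi-head self-attention adjacency `A_learn` (row-stochastic, head
   average) gates the prior elementwise, symmetrized:
   `Ã = ½(A_learn ⊙ A_prev + (A_learn ⊙ A_prev)ᵀ)`.
3. **Graph convolution** — `LReLU(D̂^{-1/2}(Ã+I)D̂^{-1/2} X W)`.
4. **Hierarchical-clustering pooling** — average-linkage clustering on the
   blend `α·scale(D_path) + (1−α)·scale(D_feat)` of shortest-path hops and
   squared feature distances, cut into `C` clusters (then `C/2` after the
   second layer); pooling is hard (`X' = SᵀX`, `A' = SᵀÃS`), while the link
   and entropy regularizers `L_link = ‖Ã − SSᵀ‖²_F` and
   `L_entropy = −Σ S log S` are evaluated on a soft companion assignment so
   they carry gradients.
5. **Classification** — global average pooling, concatenation with the
   clinical embedding, dropout, softmax; total loss
   `L = L_cls + L_link + L_entropy`.

The package also implements the upstream steps: lesion-disconnectome
construction from a parcellation, lesion mask and normative streamlines
(`lesionDamageMatrix()`), and two-step radiomic feature selection (Spearman
redundancy filter → mRMR, frequency-aggregated across regions;
`selectNodeFeatures()`), plus TopK/k-means pooling baselines, ablation
switches for every component, stratified cross-validation, and a synthetic
cohort generator that reproduces the reference cohort's clinical
distributions (152 subjects, 44 PSCI / 108 non-PSCI). Training runs through
a compiled RcppArmadillo core with hand-derived backpropagation; the R-level
operations define the reference semantics and the two are cross-checked in
the tests.

## Worked example

```r
library(psciNet)

sim <- simulationConfig(n_subjects = 60, n_psci = 20, n_regions = 40,
                        seed = 42)
cohort <- makeCohort(sim)
cohort
#> BrainCohort: 60 subjects (20 PSCI / 40 non-PSCI), 40 regions

# lesion disconnectome on a small fixture: 40% of the streamlines between
# parcels 1-2 and 75% between parcels 2-3 are transected by the lesion box
fx <- makeTractogramFixture(nParcels = 3, nStreamlines = 12,
                            lesionSpec = list(x = c(5, 7), y = c(4, 6),
                                              z = c(0, 11)), seed = 1)
round(lesionDamageMatrix(fx)$damage, 3)
#>      [,1] [,2] [,3]
#> [1,]  0.0 0.40 0.00
#> [2,]  0.4 0.00 0.75
#> [3,]  0.0 0.75 0.00

model <- mdhcConfig(D_h = 32, H = 4, C = 8, lr = 1e-3, epochs = 40,
                    seed = 42)
report <- crossValidate(cohort, model, k = 5)
report
#> CVReport (5 folds, seed 42):
#>   ACC: 0.967 ± 0.046
#>   AUC: 1.000 ± 0.000
#>   SEN: 0.900 ± 0.137
#>   SPE: 1.000 ± 0.000
```

The cohort above plants a strong feature shift (effect size 2 at 10 hub
regions) plus a 3× damage-intensity contrast, so near-perfect recovery is
the expected behavior — the point of the example is the mechanics, not the
numbers. `mdhcForward()` returns per-subject diagnostics (node attention,
learned adjacencies, cluster assignments) that
`exportInterpretability()` turns into region-named tables.

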