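# scmoclust

Joint clustering of **paired single-cell multi-omics data** — several
molecular layers (scRNA, scATAC, ADT, methylation, ...) measured in the same
cells — for analysts who want one cell partition that uses every layer and
down-weights the noisy ones automatically.

## Method

Each omics layer `X^v` (features x cells) is modelled by low-rank
self-representation with a locality-aware penalty and row-sparse noise:

```
min  ||C*||_*  +  sum_v [ lambda1 * sum_ij p_ij^v ||x_i^v - x_j^v||^2 z_ij^v
                          + w^v ||C^v - C*||_F^2  +  lambda2 ||E^v||_{2,1} ]
s.t. X^v = X^v Z^v + E^v ,   Z^v = L^v C^v R^v'  (L, R orthonormal),
     diag(Z^v) = 0 ,  z_ij^v >= 0 ,  sum_j z_ij^v = 1
```

* `p_ij = exp(-||x_i - x_j||^2 / 2 sigma^2)` for k-nearest neighbours
  (1 otherwise) makes large affinities between near neighbours cheap —
  local, nonlinear structure enters the otherwise linear subspace model.
* Each representation factors as `Z^v = L^v C^v R^v'`; the core matrices are
  pulled toward a shared low-rank consensus `C*` with adaptive per-layer
  weights `w^v = 1 / (2 ||C^v - C*||_F)`, so unreliable layers count less.
* The `l2,1` term absorbs corrupted feature rows.

The problem is solved by an inexact augmented Lagrangian with closed-form
block updates (Cholesky-based representation update + simplex projection,
Procrustes factors, singular value thresholding for the consensus, row-wise
shrinkage for the noise). The per-view representations are then summed,
truncated column-wise to an information-retention ratio
`tau = eps1 + 1/(eps2 n + eps3)` (percent), converted to an angle-based
similarity `W_ij = cos(m_i, m_j)^2` via the skinny SVD `M = U Lambda`, and
clustered spectrally, with the cluster number chosen by the eigengap when
not given.

## Worked example

```r
library(scmoclust)

# a paired two-modality benchmark: 200 cells, 1,000- and 5,000-feature
# views, 3 planted clusters, dropout 0.3, unit-norm cell profiles
ds <- generate_multiomics(synth_spec(seed = 1))
ds
#> multi_omics_dataset: 2 view(s), 200 cells
#>   view_1: 1000 features x 200 cells
#>   view_2: 5000 features x 200 cells
#>   labels: 3 classes

res <- cluster_multiomics(ds, solver_config(seed = 1))
res
#> pipeline_result
#>   solver: 39 iteration(s), converged
#>   tau = 85.833%, clusters = 3
#>   ACC = 1.0000, NMI = 1.0000
```

The solver converged in 39 iterations; the retention ratio at n = 200 is
85.8%; the eigengap found the 3 planted clusters without being told, and the
recovered partition matches the planted one exactly (accuracy under optimal
label matching and normalised mutual information both 1). For real data,
normalise cells first (`normalize_view(X, "l2")`) — the default bandwidth
`sigma = 1` and unit regularisation weights assume unit-norm profiles — and
inspect `res$state$w` for the per-layer reliability weights and
`res$fusion$W` for the learned similarity.

From the shell:

```sh
Rscript inst/cli/scmoclust generate --out-dir sim --seed 1
Rscript inst/cli/scmoclust run --view sim/view_1.tsv --view sim/view_2.tsv \
    --labels sim/labels.txt --out-dir out --n-clusters auto --seed 1
Rscript inst/cli/scmoclust metrics --pred out/predicted_labels.txt --labels sim/labels.txt
```

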