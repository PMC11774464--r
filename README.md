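# apflux

Estimation of per-sample reaction fluxes of the MHC class I and class II
antigen-presentation pathways from nonnegative expression data (bulk,
single-cell, or spatial transcriptomics/proteomics), with downstream
in-silico perturbation and spatial colocalization analysis.

## The problem and the model

Antigen processing and presentation is a chain of macromolecule-processing
reactions: proteins are ubiquitinated and degraded, peptides are transported
into the ER, loaded onto MHC complexes, and trafficked to the cell surface.
How *active* each of these steps is in a given cell or sample cannot be read
off any single gene's expression, but at (quasi-)steady state the pathway
must satisfy **flux balance**: for every intermediate molecule C_k, total
production equals total consumption across the reactions that touch it.

`apflux` represents a pathway as a **directed factor graph**: reaction
modules R_m (variables, each carrying a gene set) connected to intermediates
C_k (factors, each carrying a balance weight γ_k) by consume/produce edges.
The flux F_mj of reaction m in sample j is modelled as a small neural
network 𝓕_m(X_j^m; Θ_m) of the module's gene expression, and the networks
are trained under the constrained-learning loss

    L = Σ_j Σ_k γ_k ( Σ_{m ∈ producers(C_k)} F_mj − Σ_{m' ∈ consumers(C_k)} F_m'j )² + L_p,

where L_p adds an L1 variable-selection term on first-layer weights and a
hinge that anchors the total per-sample flux away from the all-zero
solution. Optimization alternates:

1. **Initialization** — brief gradient descent on the loss above;
2. **Projection (message-passing step)** — each sample's predicted flux
   vector is projected exactly onto {S f = 0, f ≥ 0}, where S is the signed
   incidence matrix (equivalently, Gaussian belief propagation on the
   quadratic factor graph, solved here as an exact quadratic program);
3. **Supervised refit** — the projected fluxes serve as labels for an
   L1-regularized regression refit of each module's network;

with steps 2–3 repeated until the predicted flux matrix stops moving. The
per-module agreement between the supervised and projected fluxes
("coherence") doubles as a diagnostic: a module whose data cannot be mapped
onto the balance solution space shows low coherence, flagging
pathway-structure misfit.

Downstream tools: per-sample ∂flux/∂gene gradients with importance
embedding, k-means sample subgrouping and per-cluster gene ranking; a paired
one-sided test for whether adding a gene to a module improves balance;
Gaussian signal amplification, local bivariate Moran's I with permutation
pseudo-p-values, and four-way antigen × T-cell segmentation for spatial
data.

## Worked example

Simulate the default synthetic world (a 5-module chain with one branch, 12
genes per module, n = 200 here, multiplicative lognormal noise) and estimate
fluxes:

```r
library(apflux)
spec <- simulation_spec(n_samples = 200, seed = 42)
sim  <- simulate_dataset(spec)
fit  <- fit_flux(sim$expression, sim$graph)
fit
#> Constrained-learning pathway flux fit
#>   pathway 'synthetic_chain_branch': 6 modules, 4 intermediates
#>   samples: 200
#>   iterations: 100 (max reached)
#>   final loss: total 50.97 (imbalance 0.8749)
summary(fit)
#> Per-module flux estimates:
#>   module mean_flux sd_flux coherence
#> 1     m1     1.684   0.391     0.999
#> 2     m2     1.689   0.396     0.999
#> 3     m3     0.931   0.310     0.998
#> 4     m4     0.929   0.309     0.998
#> 5     m5     0.931   0.310     0.998
#> 6     m6     0.753   0.378     0.999
#>
#> RMS imbalance:0.03307 (2.62% of RMS flux)
#> Iterations: 100 (max reached)
```

The mean fluxes reproduce the balance structure of the graph (m1 = m2 feeds
the branch split m3 + m6, and m3 = m4 = m5 along the chain), the coherence
column shows every module's network agrees with its projection, and the RMS
imbalance is a few percent of the flux scale. Against the simulated ground
truth the per-module recovery correlations here are

```r
sapply(rownames(fit$flux), function(m) cor(fit$flux[m, ], sim$flux[m, ]))
#>    m1    m2    m3    m4    m5    m6
#> 0.952 0.954 0.975 0.972 0.972 0.956
```

Real pathways ship as builtins with placeholder gene sets; load full curated
gene lists from a two-column `module_id`/`gene_id` export:

```r
g <- load_pathway("mhc1")   # 8 reaction modules, ubiquitination -> recycling
g <- set_module_genes(g, read_module_gene_table("my_curated_genes.tsv"))
fit <- fit_flux(my_expression_matrix, g)
```

A command-line interface wraps the same functions
(`exec/apflux estimate|simulate|perturb|spatial|gamma-search|validate-pathway`);
see `exec/apflux --help`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
it simulates the default synthetic world, fits the constrained-learning
model, runs the perturbation and spatial analyses, and writes its JSON
output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
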