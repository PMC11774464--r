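---
title: "Constrained learning of antigen-presentation pathway fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained learning of antigen-presentation pathway fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apflux)
```

## The model and its assumptions

`apflux` estimates the per-sample activity (flux) of each reaction step in
an antigen-presentation pathway from a nonnegative gene-by-sample expression
matrix. Three assumptions carry the whole construction:

1. **Factor-graph structure.** The pathway is a bipartite directed graph of
   reaction modules (each with a gene set) and intermediate molecules.
   Writing S for the signed incidence matrix (+1 produce, −1 consume), a
   flux vector f is balanced when S f = 0.
2. **Quasi-steady state.** Samples are snapshots of a system near
   steady state, so estimated fluxes should (approximately) satisfy balance.
   The γ_k weights let individual intermediates be held to balance more or
   less strictly; the loss is quadratic rather than a hard constraint
   precisely so that samples in a non-steady regime are penalized, not
   forbidden.
3. **Expression-to-flux monotonicity.** The genes assigned to a reaction are
   assumed to be positively informative about its rate. This matters for
   identifiability (below).

Each module's flux is a small fully connected network of the module's
preprocessed gene expression with a softplus-rectified output, so predicted
fluxes are nonnegative by construction — reaction rates are rates, and every
downstream interpretation (perturbation signs, spatial segmentation)
relies on it.

## Why the optimizer is split in three

Minimizing the balance loss over network parameters directly is neither
supervised nor unsupervised learning, and the L1 selection penalty cannot be
co-optimized cleanly with it. The optimizer therefore alternates an exact
**projection** of the current flux predictions onto the balance solution
space (the message-passing step — for quadratic factors Gaussian belief
propagation and the quadratic program coincide, and the QP is exact and
testable) with a **supervised refit** of the networks to the projected
fluxes, where regularization is ordinary regression machinery.

The projection is solved per sample by a primal active-set method on
min ‖f′ − f‖² s.t. S f′ = 0, f′ ≥ 0 (SVD-based equality projections plus
KKT multiplier checks). It is exact, idempotent, and non-expansive; the test
suite checks it against an independent enumeration-based QP oracle. In
`"soft"` mode balance enters as a quadratic penalty
soft_lambda · Σ_k γ_k (S f′)_k² instead; this is the mode in which γ has any
effect on the projection (in hard mode the feasible set S f = 0 does not
depend on γ), so γ-modulation experiments default to it.

## Identifiability and the two non-obvious design choices

**Sign of the association.** The balance loss is invariant under flipping
every learned map from increasing to decreasing: if all modules track the
*negative* of the true flux, balance is satisfied equally well. The data
cannot break this tie; the generative prior can. We therefore initialize
every network with nonnegative weights, making the initial map monotone
*increasing* in every input (assumption 3 above); training is unconstrained
afterwards. Without this, the recovered fluxes are equally likely to be
anti-correlated with the truth.

**The degenerate attractor.** A constant flux vector (same value across
samples, balanced across modules) satisfies S f = 0 exactly and defeats the
hinge anchor, so it is a global minimizer of the loss that carries no
per-sample information. Two symptoms follow. First, long balance-only
initialization collapses the per-sample variance of the predictions and
scrambles the learned signs — hence the deliberately brief default
`init_epochs = 10` (initialization only needs to bring modules onto a
common scale). Second, the projection/refit alternation is itself a slow
contraction toward that attractor: each projection averages modules, each
regression recovers slightly less variance than its targets. On
well-specified data the contraction is uniform and harmless (correlations
with the truth are preserved for over a hundred iterations), but once the
per-sample variation approaches numerical noise the coherence diagnostics
become meaningless. The `collapse_guard` therefore stops the alternation
when the mean per-module flux standard deviation falls below 10% of its
level after the first iteration. The spec-style relative-Frobenius stopping
rule (`flux_tolerance = 1e-4`, `max_iterations = 100`) remains the primary
rule; on realistic noise levels the relative change plateaus around 10⁻³
(the contraction is geometric, so the *relative* change never vanishes),
and the guard or the iteration cap is what actually terminates the run.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden` | (16, 8) | hidden widths of each per-module network; small because module gene sets are small |
| `lambda1` | 1e-4 | L1 on first-layer weights (variable selection) |
| `lambda2`, `tau` | 1, #modules | hinge `lambda2 · Σ_j max(0, tau − Σ_m F_mj)` anchoring the flux scale (about one flux unit per module) against the all-zero solution |
| `init_epochs` | 10 | balance-descent initialization epochs (kept brief, see above) |
| `sl_epochs` | 50 | refit epochs per alternation |
| `learning_rate` | 0.01 | Adam step size (full-batch, hence deterministic) |
| `max_iterations`, `flux_tolerance` | 100, 1e-4 | alternation cap and relative-Frobenius stop |
| `collapse_guard` | 0.1 | variance-collapse stop (0 disables) |
| `projection_mode`, `soft_lambda` | hard, 10 | exact vs penalized balance projection |
| γ_k | 1.0 | per-intermediate balance weight; override via the schema or `set_gamma()` |

The exact composition of the penalty L_p is not fixed by the method's
published description beyond its two purposes (avoid trivial solutions,
select variables); the L1 + hinge pair here is the minimal form serving
both, and all coefficients are configurable.

Inputs are preprocessed as log1p followed by per-gene standardization with
statistics frozen from the training data; the source data's normalization is
taken as given. Gradients for perturbation analysis are taken on this
preprocessed scale by default, with `scale = "raw"` applying the chain rule
back to the raw scale.

## What the synthetic generator emulates — and what it does not

`simulation_spec()` defines the stated world: balanced fluxes drawn from the
null space of the incidence matrix (exact balance by construction),
per-gene expression `loading · link(flux) · exp(noise_sd · Z)` with positive
loadings, a linear or saturating monotone link, multiplicative lognormal
noise (default sd 0.2 on the log scale), optional independent dropout
zeroing, and a default graph of a 5-module chain with one branch at 12
genes per module and n = 500 samples. Spatial fixtures place spots on a
regular grid with a shared kernel-smoothed latent field ("strong"
colocalization) or independent noise ("none").

The generator deliberately does *not* emulate library-size variation, batch
structure, gene–gene correlation beyond shared module flux, count noise, or
real spot geometries. A green recovery test therefore establishes that the
estimator inverts its own stated generative family under realistic noise and
dropout — not that it is calibrated on any particular real platform.

## Numerical choices

- Projection tolerances: active-set feasibility/multiplier tolerance 1e-9;
  entries in (−1e-9, 0) are clamped to zero; already-feasible columns pass
  through the equality projection untouched (≈ machine precision).
- Degenerate graphs: an incidence matrix with trivial null space makes
  balanced simulation impossible and is reported as such; a graph whose
  ablation disconnects it is refused with the components listed. After
  ablation, intermediates left one-sided are treated as pathway boundaries
  and dropped — keeping them would force the adjacent flux to zero through
  their balance rows.
- Ties: gene rankings break ties lexicographically by gene id; segmentation
  z-scores of exactly zero resolve to the "low" side; γ-search ties resolve
  by lower final loss, then grid order.
- ε = 1e-12 inside the log-abs transform of gradients guards exact zeros
  (structural zeros of genes outside the target module).
- All randomness (initialization, k-means restarts, permutations,
  simulation) flows through one master seed via a deterministic sub-seed
  stream; training itself is full-batch and deterministic.

## Statistical conventions

- The gene-inclusion test ("does adding gene g to module M improve
  balance?") is realized as a one-sided paired t statistic on per-sample
  imbalance losses: the normal-based Wald statistic and the t statistic
  coincide asymptotically, and the t reference is exact-level under normal
  differences. Degenerate (zero-variance) difference vectors are an error,
  not a p-value. Whether the model is *refit* per candidate gene or the
  losses are merely re-evaluated with the gene added is left to the caller —
  both routes are exposed (refit via `fit_flux` on the modified graph;
  re-evaluation via `imbalance_loss`), since the published analysis does not
  pin down which was used.
- Permutation pseudo-p-values use the add-one correction
  (1 + #{I_perm ≥ I_obs}) / (n_perm + 1), so p > 0 always; the bare
  proportion is available behind `add_one = FALSE`. The printed formula for
  the local bivariate Moran statistic is upper-tail; detecting *discordant*
  dependency (high antigen / low T cell and vice versa), which the four-way
  segmentation requires, needs the two-sided variant
  (`alternative = "two.sided"`), which compares |I|. `segment_regions()`
  documents this; the one-sided default reproduces the printed formula
  exactly.
- The printed amplification formula multiplies the *centre* value inside the
  kernel sum, which makes the result a constant multiple of the centre value
  and defeats smoothing; consistent with its description as a Gaussian
  smoothing filter, the default amplifies with neighbour values and
  normalizes by the summed kernel weights (a convex combination), and the
  literal centre-value form is retained behind `literal = TRUE`.
- Moran inputs are z-scored by default ("normalized" levels); `scale =
  FALSE` gives the raw form. The kernel is the zero-mean Gaussian density in
  distance with σ defaulting to 1.5× the median nearest-neighbour distance
  and radius 3σ.

## Known limitations

- Flux scale is not identified: the hinge anchors the *total* around
  `tau`, so estimates are comparable across samples and modules but not in
  physical units. Recovery is assessed by correlation for this reason.
- The sign prior (monotone initialization) is an assumption; a pathway
  whose reporter genes are repressed by activity would need its own
  convention.
- The eight/seven-module builtin pathways ship with small placeholder gene
  sets; module membership beyond genes named in the literature must be
  supplied via `set_module_genes()`. Which auxiliary branches count among
  the canonical eight MHC-I modules is not enumerated in the published
  description; the builtin follows the eight-module count with the branch
  assignment visible in `inst/extdata/pathways/mhc1.pw`.
- Gene identifiers are opaque case-sensitive tokens; no symbol/alias
  mapping is attempted.
- The belief-propagation "trust region" of the original description is
  unspecified; hard projection ignores it and `soft_lambda` plays that role
  in soft mode, without claiming the original's value.

```{r}
# a compact end-to-end run at reduced size
spec <- simulation_spec(n_samples = 120, seed = 1)
sim <- simulate_dataset(spec)
fit <- fit_flux(sim$expression, sim$graph,
                config = list(max_iterations = 15))
summary(fit)
```
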