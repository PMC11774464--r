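# ---------------------------------------------------------------------------
# Synthetic data with known ground truth: balanced fluxes drawn from the
# null space of the incidence matrix, expression generated through known
# monotone maps with multiplicative lognormal noise and optional dropout,
# and spatial fields with controlled colocalization.
# ---------------------------------------------------------------------------

#' Default synthetic pathway: a 5-module chain with one branch
#'
#' Modules m1 -> m2 -> m3 -> m4 -> m5 in a chain through intermediates
#' c1..c4, plus a branch module m6 that also consumes c2 (so balance at c2
#' reads f2 = f3 + f6). Each module carries `genes_per_module` synthetic
#' genes named `<module>_g<k>`.
#'
#' @param genes_per_module Genes per reaction module (default 12).
#' @return A validated `pathway_graph`.
#' @export
default_synthetic_graph <- function(genes_per_module = 12L) {
  mods <- paste0("m", 1:6)
  modules <- lapply(mods, function(m) list(
    id = m, name = paste("synthetic module", m),
    genes = sprintf("%s_g%02d", m, seq_len(genes_per_module))))
  names(modules) <- mods
  cids <- paste0("c", 1:4)
  intermediates <- lapply(cids, function(ci) list(
    id = ci, name = paste("intermediate", ci), gamma = 1.0))
  names(intermediates) <- cids
  produce <- data.frame(module = c("m1", "m2", "m3", "m4"),
                        intermediate = c("c1", "c2", "c3", "c4"),
                        stringsAsFactors = FALSE)
  consume <- data.frame(intermediate = c("c1", "c2", "c2", "c3", "c4"),
                        module = c("m2", "m3", "m6", "m4", "m5"),
                        stringsAsFactors = FALSE)
  g <- new_pathway_graph("synthetic_chain_branch", modules, intermediates,
                         produce, consume)
  validate_pathway(g)
  g
}

#' Simulation settings
#'
#' The stated world of the generator: defaults are n = 500 samples, lognormal
#' multiplicative noise with sd 0.2 on the log scale, no dropout, 12 genes
#' per module on the chain-plus-branch graph, and a linear flux-to-expression
#' link (a monotone-saturating link is available).
#'
#' @param graph Pathway graph (default [default_synthetic_graph()]).
#' @param n_samples Number of samples (>= 1).
#' @param flux_scale Median scale of the drawn fluxes.
#' @param noise_sd Standard deviation of the lognormal log-noise (>= 0).
#' @param dropout_rate Probability in [0, 1) of zeroing an entry.
#' @param genes_per_module Used only when `graph` is NULL.
#' @param link `"linear"` or `"saturating"` (Michaelis-Menten-like,
#'   half-saturation at `flux_scale`).
#' @param seed Integer master seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(graph = NULL, n_samples = 500L, flux_scale = 1,
                            noise_sd = 0.2, dropout_rate = 0,
                            genes_per_module = 12L,
                            link = c("linear", "saturating"), seed = 1L) {
  link <- match.arg(link)
  if (is.null(graph)) graph <- default_synthetic_graph(genes_per_module)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (flux_scale <= 0) stop("flux_scale must be > 0", call. = FALSE)
  structure(list(graph = graph, n_samples = as.integer(n_samples),
                 flux_scale = flux_scale, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, link = link,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw exactly balanced ground-truth fluxes
#'
#' Per sample, a positive lognormal flux proposal is projected onto the null
#' space of the incidence matrix (so `S F = 0` exactly); proposals whose
#' projection leaves the nonnegative orthant are rejected and redrawn.
#' Deterministic given `seed`.
#'
#' @param graph A validated `pathway_graph`.
#' @param n_samples Number of samples.
#' @param flux_scale Median flux scale.
#' @param seed Integer seed.
#' @return Nonnegative flux matrix (modules x samples) with `S F = 0`.
#' @export
simulate_balanced_flux <- function(graph, n_samples, flux_scale = 1,
                                   seed = 1L) {
  S <- incidence_matrix(graph)
  m <- ncol(S)
  sv <- svd(S, nu = 0, nv = m)
  r <- sum(sv$d > 1e-10 * max(sv$d[1], 1e-300))
  if (r >= m)
    stop("incidence matrix has trivial null space: no nonzero balanced flux exists",
         call. = FALSE)
  Nb <- sv$v[, (r + 1L):m, drop = FALSE]  # orthonormal null-space basis
  FF <- matrix(NA_real_, nrow = m, ncol = n_samples,
               dimnames = list(colnames(S), paste0("s", seq_len(n_samples))))
  with_seed(seed, {
    for (j in seq_len(n_samples)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        v <- stats::rlnorm(m, meanlog = log(flux_scale), sdlog = 0.5)
        x <- drop(Nb %*% crossprod(Nb, v))
        if (min(x) >= 0) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not draw a nonnegative balanced flux for sample ", j,
             call. = FALSE)
      FF[, j] <- x
    }
  })
  FF
}

.apply_link <- function(FF, link, flux_scale) {
  switch(link,
         linear = FF,
         saturating = FF / (flux_scale + FF))
}

#' Generate expression from ground-truth fluxes
#'
#' Each gene of module m is `loading * link(F_m) * exp(noise_sd * Z)` with a
#' per-gene positive loading drawn once (Uniform(0.5, 2)); dropout zeroes
#' entries independently. The generative map (loadings, link) is recorded in
#' the `"generative_map"` attribute.
#'
#' @param flux Flux matrix (modules x samples) on `spec$graph`.
#' @param spec A [simulation_spec()].
#' @return Nonnegative expression matrix (genes x samples).
#' @export
simulate_expression <- function(flux, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  graph <- spec$graph
  mids <- names(graph$modules)
  if (!all(mids %in% rownames(flux)))
    stop("flux rows do not match spec graph modules", call. = FALSE)
  genes <- unlist(lapply(mids, function(id) graph$modules[[id]]$genes),
                  use.names = FALSE)
  n <- ncol(flux)
  D <- matrix(0, nrow = length(genes), ncol = n,
              dimnames = list(genes, colnames(flux)))
  loadings <- stats::setNames(numeric(length(genes)), genes)
  with_seed(seed_stream(spec$seed, "expression"), {
    for (id in mids) {
      u <- .apply_link(flux[id, ], spec$link, spec$flux_scale)
      for (g in graph$modules[[id]]$genes) {
        a <- stats::runif(1, 0.5, 2)
        loadings[g] <- a
        noise <- exp(spec$noise_sd * stats::rnorm(n))
        D[g, ] <- a * u * noise
      }
    }
    if (spec$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(D)) < spec$dropout_rate, nrow = nrow(D))
      D[mask] <- 0
    }
  })
  attr(D, "generative_map") <- list(loadings = loadings, link = spec$link,
                                    flux_scale = spec$flux_scale)
  D
}

#' Simulate a complete dataset
#'
#' Convenience wrapper drawing balanced fluxes and the matching expression.
#'
#' @param spec A [simulation_spec()].
#' @return List with `expression`, `flux` (ground truth), `graph`, `spec`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  flux <- simulate_balanced_flux(spec$graph, spec$n_samples, spec$flux_scale,
                                 seed = seed_stream(spec$seed, "flux"))
  expr <- simulate_expression(flux, spec)
  list(expression = expr, flux = flux, graph = spec$graph, spec = spec)
}

#' Simulate with one module decoupled from its flux
#'
#' As [simulate_dataset()], but the named module's genes are generated from
#' an independent random signal instead of the module's flux. All other
#' modules' values are identical to the coupled simulation under the same
#' seed (stream isolation), making two-condition contrasts exact.
#'
#' @param spec A [simulation_spec()].
#' @param module_id Module to decouple.
#' @return List with `expression`, `flux`, `graph`, `spec`, `decoupled`.
#' @export
simulate_module_decoupled <- function(spec, module_id) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!module_id %in% names(spec$graph$modules))
    stop("unknown module id: '", module_id, "'", call. = FALSE)
  out <- simulate_dataset(spec)
  genes <- spec$graph$modules[[module_id]]$genes
  n <- spec$n_samples
  with_seed(seed_stream(spec$seed, paste0("decouple:", module_id)), {
    indep <- stats::rlnorm(n, meanlog = log(spec$flux_scale), sdlog = 0.5)
    u <- .apply_link(indep, spec$link, spec$flux_scale)
    for (g in genes) {
      a <- stats::runif(1, 0.5, 2)
      noise <- exp(spec$noise_sd * stats::rnorm(n))
      out$expression[g, ] <- a * u * noise
    }
    if (spec$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(genes) * n) < spec$dropout_rate,
                     nrow = length(genes))
      out$expression[genes, ][mask] <- 0
    }
  })
  out$decoupled <- module_id
  out
}

#' Simulate a pair of spatial fields
#'
#' Regular `grid_size` x `grid_size` grid. In `"strong"` mode a shared
#' smooth latent field (kernel-smoothed white noise) drives both fields plus
#' independent noise, giving controlled colocalization; in `"none"` mode the
#' two fields are independent white noise, the null for permutation tests.
#'
#' @param grid_size Grid side length (>= 3).
#' @param colocalization `"strong"` or `"none"`.
#' @param seed Integer seed.
#' @param noise_sd Noise level added on top of the shared latent field.
#' @return List with spatial fields `x` and `y` (see [spatial_field()]).
#' @export
simulate_spatial_pair <- function(grid_size = 20L,
                                  colocalization = c("strong", "none"),
                                  seed = 1L, noise_sd = 0.4) {
  colocalization <- match.arg(colocalization)
  if (grid_size < 3L) stop("grid_size must be >= 3", call. = FALSE)
  coords <- as.matrix(expand.grid(x = seq_len(grid_size),
                                  y = seq_len(grid_size)))
  n <- nrow(coords)
  ids <- paste0("spot", seq_len(n))
  with_seed(seed, {
    if (colocalization == "strong") {
      z <- stats::rnorm(n)
      kw <- kernel_weights(coords, sigma = 1.5, radius = 4.5,
                           self_weight = TRUE)
      latent <- drop(kw$weights %*% z) / rowSums(kw$weights)
      latent <- (latent - mean(latent)) / stats::sd(latent)
      xv <- latent + noise_sd * stats::rnorm(n)
      yv <- latent + noise_sd * stats::rnorm(n)
    } else {
      xv <- stats::rnorm(n)
      yv <- stats::rnorm(n)
    }
    list(x = spatial_field(coords, xv, ids),
         y = spatial_field(coords, yv, ids))
  })
}
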