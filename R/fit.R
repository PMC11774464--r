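# ---------------------------------------------------------------------------
# Three-step constrained-learning optimizer:
#   1. initialization   - gradient descent on imbalance + penalty loss
#   2. projection (MPO) - exact per-sample projection onto the balance space
#   3. supervised refit - regression of the networks onto the projected flux
# steps 2-3 alternate until the predicted flux matrix stops moving.
# ---------------------------------------------------------------------------

# gradient of the imbalance + penalty loss w.r.t. the flux matrix
.loss_flux_grad <- function(FF, S, gam, lambda2, tau) {
  G <- 2 * crossprod(S, gam * (S %*% FF))
  below <- colSums(FF) < tau
  if (any(below)) G[, below] <- G[, below] - lambda2
  G
}

#' Initialize flux approximators by balance-loss descent
#'
#' Step 1 of the optimizer: full-batch Adam on the flux-imbalance loss plus
#' penalty for `config$init_epochs` epochs. Deterministic given the model's
#' initialization seed (training itself uses no randomness).
#'
#' @param model A `flux_model` from [build_flux_model()].
#' @param data Expression matrix.
#' @param config Settings from [flux_config()]; defaults to the model's.
#' @return The updated `flux_model`.
#' @export
init_flux_model <- function(model, data, config = model$config) {
  config <- flux_config(config)
  if (is.na(config$tau)) config$tau <- length(model$nets)
  if (config$init_epochs == 0L) return(model)
  graph <- model$graph
  S <- incidence_matrix(graph)
  gam <- pathway_gamma(graph)
  mids <- names(graph$modules)
  Xs <- lapply(mids, function(id)
    .preprocess_apply(data, model$preprocess, graph$modules[[id]]$genes))
  names(Xs) <- mids
  states <- lapply(model$nets, adam_init)
  for (epoch in seq_len(config$init_epochs)) {
    fwds <- lapply(mids, function(id)
      mlp_forward(model$nets[[id]], Xs[[id]]))
    names(fwds) <- mids
    FF <- do.call(rbind, lapply(fwds, `[[`, "f"))
    rownames(FF) <- mids
    if (any(!is.finite(FF)))
      stop("non-finite flux prediction during initialization", call. = FALSE)
    G <- .loss_flux_grad(FF, S, gam, config$lambda2, config$tau)
    for (id in mids) {
      gr <- mlp_backward(model$nets[[id]], fwds[[id]], df = G[id, ])
      gr$W[[1]] <- gr$W[[1]] + config$lambda1 * sign(model$nets[[id]]$W[[1]])
      upd <- adam_step(model$nets[[id]], gr, states[[id]], config$learning_rate)
      model$nets[[id]] <- upd$par
      states[[id]] <- upd$state
    }
  }
  model
}

#' Supervised refit of the flux approximators
#'
#' Step 3 of the optimizer: the projected fluxes serve as known labels and
#' each module's network is refit by squared-error regression with an L1
#' penalty on first-layer weights, `config$sl_epochs` full-batch Adam epochs.
#'
#' @param model A `flux_model`.
#' @param data Expression matrix.
#' @param target Nonnegative flux matrix (modules x samples), e.g. from
#'   [mpo_project()].
#' @param config Settings; defaults to the model's.
#' @return The updated `flux_model`.
#' @export
sl_fit <- function(model, data, target, config = model$config) {
  config <- flux_config(config)
  if (config$sl_epochs == 0L) return(model)
  if (any(!is.finite(target)))
    stop("non-finite values in supervised target", call. = FALSE)
  graph <- model$graph
  mids <- names(graph$modules)
  if (!is.null(rownames(target))) target <- target[mids, , drop = FALSE]
  n <- ncol(target)
  for (id in mids) {
    X <- .preprocess_apply(data, model$preprocess, graph$modules[[id]]$genes)
    tt <- target[id, ]
    state <- adam_init(model$nets[[id]])
    for (epoch in seq_len(config$sl_epochs)) {
      fwd <- mlp_forward(model$nets[[id]], X)
      gr <- mlp_backward(model$nets[[id]], fwd, df = 2 * (fwd$f - tt) / n)
      gr$W[[1]] <- gr$W[[1]] + config$lambda1 * sign(model$nets[[id]]$W[[1]])
      upd <- adam_step(model$nets[[id]], gr, state, config$learning_rate)
      model$nets[[id]] <- upd$par
      state <- upd$state
    }
  }
  model
}

#' Run the alternating projection / refit loop
#'
#' Alternates [mpo_project()] and [sl_fit()] from an initialized model until
#' the relative Frobenius change of the predicted flux matrix falls below
#' `config$flux_tolerance` or `config$max_iterations` is reached.
#'
#' @param model An initialized `flux_model`.
#' @param data Expression matrix.
#' @param config Settings.
#' @return List with `flux` (final supervised-learning flux), `flux_mpo`
#'   (its final projection), `model`, and `diagnostics` (iterations run,
#'   convergence flag, loss trace, per-module coherence trace, burn-in
#'   iteration).
#' @export
fit_mpsl <- function(model, data, config = model$config) {
  config <- flux_config(config)
  graph <- model$graph
  loss_trace <- list()
  coh_trace <- NULL
  F_prev <- predict_flux(model, data)
  converged <- FALSE
  stop_reason <- "max_iterations"
  iters <- 0L
  F_mpo <- F_prev
  sd_ref <- NA_real_
  for (t in seq_len(config$max_iterations)) {
    iters <- t
    F_mpo <- mpo_project(F_prev, graph, config)
    model <- sl_fit(model, data, F_mpo, config)
    F_new <- predict_flux(model, data)
    lb <- imbalance_loss(F_new, graph)
    lb$penalty <- penalty_loss(model, F_new, config)
    lb$total <- lb$flux_balance + lb$penalty
    loss_trace[[t]] <- lb
    coh <- coherence(F_new, F_mpo)
    coh_trace <- rbind(coh_trace, stats::setNames(coh$correlation, coh$module))
    rel <- norm(F_new - F_prev, "F") / max(norm(F_prev, "F"), 1e-12)
    F_prev <- F_new
    sd_now <- mean(apply(F_new, 1, stats::sd))
    if (t == 1L) sd_ref <- sd_now
    if (rel < config$flux_tolerance) {
      converged <- TRUE; stop_reason <- "flux_tolerance"; break
    }
    # the alternation's degenerate attractor is a constant balanced flux;
    # stop before per-sample variation is consumed by it
    if (config$collapse_guard > 0 && t > 1L &&
        sd_now < config$collapse_guard * max(sd_ref, 1e-12)) {
      stop_reason <- "collapse_guard"; break
    }
  }
  totals <- vapply(loss_trace, `[[`, numeric(1), "total")
  burn_in <- NA_integer_
  if (length(totals) >= 2L) {
    rel_loss <- abs(diff(totals)) / pmax(abs(totals[-length(totals)]), 1e-12)
    hit <- which(rel_loss < config$flux_tolerance)
    if (length(hit)) burn_in <- hit[1] + 1L
  }
  list(flux = F_prev, flux_mpo = F_mpo, model = model,
       diagnostics = list(iterations_run = iters, converged = converged,
                          stop_reason = stop_reason,
                          loss_trace = loss_trace,
                          coherence_trace = coh_trace,
                          burn_in_iteration = burn_in))
}

#' Fit antigen-presentation pathway fluxes to expression data
#'
#' The main modelling interface. Estimates a nonnegative per-sample flux for
#' every reaction module of a pathway from a gene-by-sample expression matrix
#' by constrained learning: per-module neural approximators trained under the
#' steady-state flux-balance condition via alternating projection and
#' supervised refitting.
#'
#' @param data Nonnegative expression matrix, genes x samples, with gene and
#'   sample identifiers (see [expression_matrix()]).
#' @param pathway A `pathway_graph`, or a builtin name (`"mhc1"`, `"mhc2"`),
#'   or a path to a pathway schema file.
#' @param config Settings from [flux_config()] (or a named list of
#'   overrides).
#' @param gamma Optional per-intermediate balance-weight overrides, passed to
#'   [set_gamma()].
#' @return An object of class `flux_fit` with components `flux` (modules x
#'   samples), `flux_mpo`, `model`, `graph`, `config`, `diagnostics`, and
#'   supporting print/summary/coef/predict/fitted/residuals/plot/simulate
#'   methods.
#' @examples
#' spec <- simulation_spec(n_samples = 60, seed = 7)
#' sim <- simulate_dataset(spec)
#' fit <- fit_flux(sim$expression, sim$graph,
#'                 config = list(init_epochs = 20, sl_epochs = 10,
#'                               max_iterations = 3))
#' fit
#' @export
fit_flux <- function(data, pathway = "mhc1", config = flux_config(),
                     gamma = NULL) {
  cl <- match.call()
  config <- flux_config(config)
  graph <- if (is.character(pathway)) load_pathway(pathway) else pathway
  validate_pathway(graph)
  if (!is.null(gamma)) graph <- set_gamma(graph, gamma)
  graph <- subset_to_genes(graph, rownames(data))
  model <- build_flux_model(graph, data, config)
  model <- init_flux_model(model, data, config)
  res <- fit_mpsl(model, data, config)
  structure(list(
    flux = res$flux, flux_mpo = res$flux_mpo, model = res$model,
    graph = graph, config = res$model$config, diagnostics = res$diagnostics,
    sample_ids = colnames(data), call = cl
  ), class = "flux_fit")
}

#' Grid search over balance weights
#'
#' Refits the model for each candidate gamma weighting and selects the
#' candidate maximizing mean per-module coherence (agreement between the
#' supervised and projected fluxes); ties are broken by lower final total
#' loss, then grid order. Because the hard-mode feasible set is
#' gamma-independent, the search defaults to soft projection.
#'
#' @param data Expression matrix.
#' @param pathway Pathway graph or builtin name.
#' @param gamma_grid Nonempty list of gamma candidates (each a scalar or a
#'   named per-intermediate vector, see [set_gamma()]).
#' @param config Settings; `projection_mode` defaults to `"soft"` here.
#' @return List with `best_index`, `best_gamma`, `summary` (per-candidate
#'   mean coherence and final loss), and `best_fit`.
#' @export
gamma_search <- function(data, pathway, gamma_grid,
                         config = flux_config(projection_mode = "soft")) {
  if (length(gamma_grid) == 0L) stop("gamma_grid is empty", call. = FALSE)
  config <- flux_config(config)
  fits <- vector("list", length(gamma_grid))
  mean_coh <- numeric(length(gamma_grid))
  final_loss <- numeric(length(gamma_grid))
  for (i in seq_along(gamma_grid)) {
    fits[[i]] <- fit_flux(data, pathway, config, gamma = gamma_grid[[i]])
    ct <- fits[[i]]$diagnostics$coherence_trace
    mean_coh[i] <- mean(ct[nrow(ct), ], na.rm = TRUE)
    lt <- fits[[i]]$diagnostics$loss_trace
    final_loss[i] <- lt[[length(lt)]]$total
  }
  ord <- order(-mean_coh, final_loss, seq_along(gamma_grid))
  best <- ord[1]
  list(best_index = best, best_gamma = gamma_grid[[best]],
       summary = data.frame(candidate = seq_along(gamma_grid),
                            mean_coherence = mean_coh,
                            final_loss = final_loss),
       best_fit = fits[[best]])
}

# ------------------------------- S3 methods --------------------------------

#' @export
print.flux_fit <- function(x, ...) {
  d <- x$diagnostics
  cat("Constrained-learning pathway flux fit\n")
  cat("  pathway '", x$graph$name, "': ", length(x$graph$modules),
      " modules, ", length(x$graph$intermediates), " intermediates\n", sep = "")
  cat("  samples: ", ncol(x$flux), "\n", sep = "")
  cat("  iterations: ", d$iterations_run,
      if (d$converged) " (converged)" else " (max reached)", "\n", sep = "")
  lt <- d$loss_trace[[length(d$loss_trace)]]
  cat("  final loss: total ", format(lt$total, digits = 4),
      " (imbalance ", format(lt$flux_balance, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.flux_fit <- function(object, ...) {
  ct <- object$diagnostics$coherence_trace
  tab <- data.frame(
    module = rownames(object$flux),
    mean_flux = rowMeans(object$flux),
    sd_flux = apply(object$flux, 1, stats::sd),
    coherence = unname(ct[nrow(ct), ]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  S <- incidence_matrix(object$graph)
  imb <- S %*% object$flux
  out <- list(modules = tab,
              imbalance_rms = sqrt(mean(imb^2)),
              flux_rms = sqrt(mean(object$flux^2)),
              iterations = object$diagnostics$iterations_run,
              converged = object$diagnostics$converged,
              burn_in = object$diagnostics$burn_in_iteration)
  class(out) <- "summary.flux_fit"
  out
}

#' @export
print.summary.flux_fit <- function(x, ...) {
  cat("Per-module flux estimates:\n")
  print(x$modules, digits = 3)
  cat("\nRMS imbalance:", format(x$imbalance_rms, digits = 4),
      " (", sprintf("%.2f%%", 100 * x$imbalance_rms / max(x$flux_rms, 1e-12)),
      " of RMS flux)\n", sep = "")
  cat("Iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max reached)", "\n")
  invisible(x)
}

#' @export
fitted.flux_fit <- function(object, ...) object$flux

#' Per-gene first-layer weight mass
#'
#' `coef()` for a flux fit returns, per module, the summed absolute
#' first-layer weight attached to each input gene -- the quantity the L1
#' variable-selection penalty acts on.
#'
#' @param object A `flux_fit`.
#' @param ... Unused.
#' @return Named list (one element per module) of named numeric vectors.
#' @export
coef.flux_fit <- function(object, ...) {
  out <- list()
  for (id in names(object$model$nets)) {
    w <- colSums(abs(object$model$nets[[id]]$W[[1]]))
    names(w) <- object$graph$modules[[id]]$genes
    out[[id]] <- w
  }
  out
}

#' @export
predict.flux_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$flux)
  predict_flux(object$model, newdata)
}

#' Per-intermediate imbalance residuals
#'
#' @param object A `flux_fit`.
#' @param ... Unused.
#' @return Matrix (intermediates x samples) of net production `S F`; zero
#'   rows mean exact balance.
#' @export
residuals.flux_fit <- function(object, ...) {
  incidence_matrix(object$graph) %*% object$flux
}

#' @export
plot.flux_fit <- function(x, ...) {
  d <- x$diagnostics
  totals <- vapply(d$loss_trace, `[[`, numeric(1), "total")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(totals), totals, type = "b", xlab = "iteration",
                 ylab = "total loss", main = "optimization trace", ...)
  ct <- d$coherence_trace
  graphics::matplot(seq_len(nrow(ct)), ct, type = "l", lty = 1,
                    xlab = "iteration", ylab = "coherence",
                    main = "per-module coherence", ylim = c(-1, 1))
  graphics::legend("bottomright", legend = colnames(ct), col = seq_len(ncol(ct)),
                   lty = 1, cex = 0.7)
  invisible(x)
}

#' Simulate data from a fitted pathway structure
#'
#' Draws balanced ground-truth fluxes on the fitted graph and generates
#' expression through the package's generative model (monotone link with
#' multiplicative lognormal noise), giving datasets whose structure matches
#' the fit.
#'
#' @param object A `flux_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_spec()].
#' @return List of length `nsim`; each element has `expression`, `flux`,
#'   `graph`.
#' @export
simulate.flux_fit <- function(object, nsim = 1, seed = 1, ...) {
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    spec <- simulation_spec(graph = object$graph,
                            n_samples = ncol(object$flux),
                            seed = seed_stream(seed, i), ...)
    out[[i]] <- simulate_dataset(spec)
  }
  out
}
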