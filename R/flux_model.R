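# ---------------------------------------------------------------------------
# Flux approximators and the constrained-learning loss.
#
# One small neural network per reaction module maps the (preprocessed)
# expression of the module's genes in a sample to a nonnegative flux. The
# loss is a gamma-weighted quadratic flux-imbalance term over intermediates
# plus a penalty: an L1 term on first-layer weights (variable selection) and
# a hinge anchoring total per-sample flux away from the all-zero solution.
# ---------------------------------------------------------------------------

#' Construct an expression matrix
#'
#' @param values Nonnegative numeric matrix, genes in rows, samples in
#'   columns.
#' @param gene_ids,sample_ids Optional identifiers; default to existing
#'   dimnames.
#' @return A validated numeric matrix with gene/sample dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix needs gene and sample identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative expression value at gene '", gene_ids[neg[1, 1]],
         "', sample '", sample_ids[neg[1, 2]], "'", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

# log1p then per-gene standardization; statistics frozen at build time
.preprocess_stats <- function(data, genes) {
  tl <- log1p(data[genes, , drop = FALSE])
  ctr <- rowMeans(tl)
  scl <- apply(tl, 1, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.preprocess_apply <- function(data, prep, genes) {
  tl <- log1p(data[genes, , drop = FALSE])
  (tl - prep$center[genes]) / prep$scale[genes]
}

#' Default model/optimizer settings
#'
#' Returns the resolved configuration used by [build_flux_model()] and
#' [fit_flux()]. Any element can be overridden by passing a named list.
#'
#' @param ... Named overrides.
#' @return Named list of settings: `hidden` (hidden-layer widths of each
#'   per-module network), `lambda1` (L1 weight on first-layer weights),
#'   `lambda2`, `tau` (total-flux hinge anchor; `tau = NA` means one flux
#'   unit per module), `init_epochs`, `sl_epochs`, `learning_rate`,
#'   `max_iterations`, `flux_tolerance` (relative Frobenius stopping rule),
#'   `collapse_guard` (stop alternating when the mean per-module flux
#'   standard deviation drops below this fraction of its level after the
#'   first iteration -- the alternation's degenerate attractor is a constant
#'   balanced flux, and running into it erases the per-sample signal; 0
#'   disables the guard), `projection_mode` (`"hard"` or `"soft"`),
#'   `soft_lambda`, `seed`.
#' @export
flux_config <- function(...) {
  cfg <- list(
    hidden = c(16L, 8L),
    lambda1 = 1e-4,
    lambda2 = 1.0,
    tau = NA_real_,          # resolved to #modules at build time
    init_epochs = 10L,
    sl_epochs = 50L,
    learning_rate = 0.01,
    max_iterations = 100L,
    flux_tolerance = 1e-4,
    collapse_guard = 0.1,
    projection_mode = "hard",
    soft_lambda = 10,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots)))
    dots <- dots[[1]]
  dots <- dots[!vapply(dots, is.null, logical(1))]  # null (e.g. JSON) = default
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  if (any(unlist(cfg[c("lambda1", "lambda2")]) < 0))
    stop("penalty coefficients must be >= 0", call. = FALSE)
  if (!is.na(cfg$tau) && cfg$tau < 0)
    stop("tau must be >= 0", call. = FALSE)
  if (cfg$init_epochs < 0 || cfg$sl_epochs < 0)
    stop("epoch counts must be >= 0", call. = FALSE)
  if (cfg$learning_rate <= 0 || cfg$flux_tolerance <= 0 ||
      cfg$max_iterations < 1 || cfg$soft_lambda <= 0)
    stop("learning_rate, flux_tolerance, soft_lambda must be > 0 and max_iterations >= 1",
         call. = FALSE)
  if (cfg$collapse_guard < 0 || cfg$collapse_guard >= 1)
    stop("collapse_guard must be in [0, 1)", call. = FALSE)
  if (!cfg$projection_mode %in% c("hard", "soft"))
    stop("projection_mode must be 'hard' or 'soft'", call. = FALSE)
  cfg
}

#' Build per-module flux approximators
#'
#' Creates one small fully connected network per reaction module, taking the
#' module's gene expression (log1p then per-gene standardization, statistics
#' frozen from `data`) to a nonnegative flux via a softplus-rectified output.
#' Initialization is deterministic given `config$seed`.
#'
#' @param graph A validated `pathway_graph` whose module genes are all
#'   measured in `data` (use [subset_to_genes()] first).
#' @param data Expression matrix (genes x samples) used only for
#'   preprocessing statistics.
#' @param config Settings from [flux_config()].
#' @return An object of class `flux_model`.
#' @export
build_flux_model <- function(graph, data, config = flux_config()) {
  validate_pathway(graph)
  config <- flux_config(config)
  missing <- setdiff(pathway_genes(graph), rownames(data))
  if (length(missing))
    stop("module genes not measured: ", paste(missing, collapse = ", "),
         call. = FALSE)
  prep <- .preprocess_stats(data, pathway_genes(graph))
  nets <- list()
  for (id in names(graph$modules)) {
    d_in <- length(graph$modules[[id]]$genes)
    nets[[id]] <- mlp_init(d_in, config$hidden,
                           seed = seed_stream(config$seed, paste0("init:", id)))
  }
  if (is.na(config$tau)) config$tau <- length(graph$modules)
  structure(list(
    graph = graph,
    nets = nets,
    preprocess = prep,
    config = config
  ), class = "flux_model")
}

#' Predict per-module fluxes
#'
#' @param model A `flux_model`.
#' @param data Expression matrix covering every module's genes.
#' @return Nonnegative flux matrix, modules x samples.
#' @export
predict_flux <- function(model, data) {
  stopifnot(inherits(model, "flux_model"))
  missing <- setdiff(pathway_genes(model$graph), rownames(data))
  if (length(missing))
    stop("missing genes in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  mids <- names(model$graph$modules)
  FF <- matrix(0, nrow = length(mids), ncol = ncol(data),
               dimnames = list(mids, colnames(data)))
  for (id in mids) {
    genes <- model$graph$modules[[id]]$genes
    X <- .preprocess_apply(data, model$preprocess, genes)
    FF[id, ] <- mlp_forward(model$nets[[id]], X, keep_cache = FALSE)$f
  }
  FF
}

#' Flux-imbalance loss
#'
#' Gamma-weighted quadratic imbalance summed over samples:
#' for intermediate k, `per_intermediate[k] = gamma_k * sum_j (S F)_k,j ^ 2`
#' where `S` is the signed incidence matrix; `flux_balance` is the sum over
#' intermediates.
#'
#' @param flux Flux matrix (modules x samples) matching `graph`.
#' @param graph A `pathway_graph`.
#' @return A list of class `loss_breakdown` with elements `flux_balance`,
#'   `penalty` (0 here), `per_intermediate`, `total`.
#' @export
imbalance_loss <- function(flux, graph) {
  S <- incidence_matrix(graph)
  if (nrow(flux) != ncol(S))
    stop("flux has ", nrow(flux), " modules but graph has ", ncol(S),
         call. = FALSE)
  if (!is.null(rownames(flux)) && !identical(rownames(flux), colnames(S)))
    flux <- flux[colnames(S), , drop = FALSE]
  gam <- pathway_gamma(graph)
  imb <- S %*% flux                          # K x n net production
  per_k <- gam * rowSums(imb^2)
  structure(list(flux_balance = sum(per_k), penalty = 0,
                 per_intermediate = per_k, total = sum(per_k)),
            class = "loss_breakdown")
}

#' Penalty loss
#'
#' `lambda1 * sum(|first-layer weights|)` (variable selection) plus
#' `lambda2 * sum_j max(0, tau - sum_m F_mj)` (a hinge anchoring the total
#' per-sample flux away from the trivial all-zero solution).
#'
#' @param model A `flux_model` (its first-layer weights enter the L1 term).
#' @param flux Flux matrix (modules x samples).
#' @param config Settings with `lambda1`, `lambda2`, `tau`; defaults from the
#'   model.
#' @return Nonnegative scalar.
#' @export
penalty_loss <- function(model, flux, config = model$config) {
  config <- flux_config(config)
  if (is.na(config$tau)) config$tau <- nrow(flux)
  l1 <- sum(vapply(model$nets, function(p) sum(abs(p$W[[1]])), numeric(1)))
  hinge <- sum(pmax(0, config$tau - colSums(flux)))
  config$lambda1 * l1 + config$lambda2 * hinge
}

#' Agreement between supervised and projected fluxes
#'
#' Per-module Pearson correlation across samples between two flux matrices
#' (typically the supervised-learning prediction and its flux-balance
#' projection), plus the root-mean-square of their difference. Low agreement
#' for a module diagnoses data that cannot be mapped onto the balance
#' solution space, i.e. pathway-structure misfit. Undefined correlations
#' (zero variance) are reported as `NA`, not 0.
#'
#' @param flux_sl,flux_mpo Flux matrices of identical shape, >= 3 samples.
#' @return Data frame with columns `module`, `correlation`, `rms`.
#' @export
coherence <- function(flux_sl, flux_mpo) {
  if (!all(dim(flux_sl) == dim(flux_mpo)))
    stop("flux matrices have different shapes", call. = FALSE)
  if (ncol(flux_sl) < 3L)
    stop("need >= 3 samples for correlation", call. = FALSE)
  mods <- rownames(flux_sl)
  if (is.null(mods)) mods <- paste0("m", seq_len(nrow(flux_sl)))
  cors <- vapply(seq_len(nrow(flux_sl)), function(m) {
    a <- flux_sl[m, ]; b <- flux_mpo[m, ]
    if (stats::sd(a) < 1e-14 || stats::sd(b) < 1e-14) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  rms <- sqrt(rowMeans((flux_sl - flux_mpo)^2))
  data.frame(module = mods, correlation = cors, rms = unname(rms),
             stringsAsFactors = FALSE)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Loss breakdown: total =", format(x$total),
      "(flux balance =", format(x$flux_balance),
      ", penalty =", format(x$penalty), ")\n")
  invisible(x)
}

#' @export
print.flux_model <- function(x, ...) {
  cat("Per-module flux approximators (", length(x$nets), " modules)\n", sep = "")
  cat("  hidden widths: ", paste(x$config$hidden, collapse = ", "), "\n", sep = "")
  cat("  inputs: log1p + per-gene standardization; output: softplus\n")
  invisible(x)
}
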