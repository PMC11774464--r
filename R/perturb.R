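# ---------------------------------------------------------------------------
# Gradient-based in-silico perturbation: per-sample partial derivatives of a
# target module's predicted flux w.r.t. each gene, importance embedding and
# clustering of sample subgroups, per-cluster gene ranking, fold-change
# perturbation, and the paired test for gene-to-module inclusion.
# ---------------------------------------------------------------------------

#' Per-sample gradients of a module's predicted flux
#'
#' Computes, by reverse-mode differentiation through the module's network,
#' the partial derivative of the target module's predicted flux with respect
#' to each input gene, per sample. Genes not feeding the target module get an
#' exact 0. By default gradients are taken with respect to the preprocessed
#' (log1p + standardized) inputs; `scale = "raw"` applies the chain rule
#' through the preprocessing back to the raw expression scale.
#'
#' @param model A `flux_model` (or a `flux_fit`, whose model is used).
#' @param data Expression matrix.
#' @param target_module Module id whose flux is differentiated.
#' @param scale `"preprocessed"` (default) or `"raw"`.
#' @return Matrix (genes x samples) over the model's gene universe, with
#'   attribute `"target_module"`.
#' @export
compute_gradients <- function(model, data, target_module,
                              scale = c("preprocessed", "raw")) {
  if (inherits(model, "flux_fit")) model <- model$model
  stopifnot(inherits(model, "flux_model"))
  scale <- match.arg(scale)
  graph <- model$graph
  if (!target_module %in% names(graph$modules))
    stop("unknown module id: '", target_module, "'", call. = FALSE)
  all_genes <- pathway_genes(graph)
  missing <- setdiff(all_genes, rownames(data))
  if (length(missing))
    stop("missing genes in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  G <- matrix(0, nrow = length(all_genes), ncol = ncol(data),
              dimnames = list(all_genes, colnames(data)))
  genes <- graph$modules[[target_module]]$genes
  X <- .preprocess_apply(data, model$preprocess, genes)
  dX <- mlp_input_grad(model$nets[[target_module]], X)
  rownames(dX) <- genes
  if (scale == "raw") {
    # x_pre = (log1p(x_raw) - c) / s  =>  d x_pre / d x_raw = 1/((1+x_raw) s)
    raw <- data[genes, , drop = FALSE]
    dX <- dX / ((1 + raw) * model$preprocess$scale[genes])
  }
  if (any(!is.finite(dX)))
    stop("non-finite gradients", call. = FALSE)
  G[genes, ] <- dX
  attr(G, "target_module") <- target_module
  G
}

#' Importance embedding of perturbation gradients
#'
#' Transforms gradients as `log(|g| + eps)` (eps = 1e-12), treats samples as
#' observations, centres, and projects onto the top `min(6, rank)` principal
#' components.
#'
#' @param grad Gradient matrix (genes x samples) from [compute_gradients()].
#' @param max_components Component cap (default 6).
#' @return List of class `importance_embedding`: `coordinates` (samples x
#'   components), `explained` (variance shares), `rotation`.
#' @export
importance_embedding <- function(grad, max_components = 6L) {
  if (any(!is.finite(grad))) stop("gradients must be finite", call. = FALSE)
  if (all(grad == 0))
    stop("all-zero gradient matrix: no variance to embed", call. = FALSE)
  M <- t(log(abs(grad) + 1e-12))          # samples x genes
  Mc <- scale(M, center = TRUE, scale = FALSE)
  rank <- qr(Mc)$rank
  ncomp <- min(max_components, rank)
  if (ncomp < 1L)
    stop("transformed gradient matrix has rank 0", call. = FALSE)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ncomp <- min(ncomp, ncol(pc$x))
  vars <- pc$sdev^2
  structure(list(coordinates = pc$x[, seq_len(ncomp), drop = FALSE],
                 explained = vars[seq_len(ncomp)] / sum(vars),
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE]),
            class = "importance_embedding")
}

#' Cluster samples by gradient importance
#'
#' K-means (default k = 3, matching the three antigen-presenting-cell
#' subgroup analysis) on the importance embedding, with seeded restarts so
#' labels are deterministic given the seed.
#'
#' @param embedding An `importance_embedding`.
#' @param k Number of clusters (<= number of samples).
#' @param seed Integer seed.
#' @param n_start Random restarts (default 10).
#' @return Integer vector of cluster labels (1..k), named by sample.
#' @export
cluster_importance <- function(embedding, k = 3L, seed = 1L, n_start = 10L) {
  stopifnot(inherits(embedding, "importance_embedding"))
  co <- embedding$coordinates
  if (k > nrow(co))
    stop("k = ", k, " exceeds the number of samples (", nrow(co), ")",
         call. = FALSE)
  if (k == nrow(co))  # trivial partition; stats::kmeans requires k < n
    return(stats::setNames(seq_len(nrow(co)), rownames(co)))
  km <- with_seed(seed, stats::kmeans(co, centers = k, nstart = n_start,
                                      iter.max = 100L))
  stats::setNames(km$cluster, rownames(co))
}

#' Rank genes by mean importance within clusters
#'
#' Within each cluster, genes are sorted by mean `log(|gradient| + eps)`
#' across the cluster's samples, descending; ties break lexicographically by
#' gene id. The paper-scale default reports the top 10 genes per cluster.
#'
#' @param grad Gradient matrix (genes x samples).
#' @param labels Cluster labels aligned with the samples.
#' @param top_n Genes to report per cluster (default 10).
#' @return Named list (one element per cluster) of data.frames with columns
#'   `gene`, `mean_importance`.
#' @export
rank_genes <- function(grad, labels, top_n = 10L) {
  if (length(labels) != ncol(grad))
    stop("labels do not align with samples", call. = FALSE)
  imp <- log(abs(grad) + 1e-12)
  out <- list()
  for (cl in sort(unique(labels))) {
    means <- rowMeans(imp[, labels == cl, drop = FALSE])
    ord <- order(-means, rownames(grad))
    take <- utils::head(ord, top_n)
    out[[as.character(cl)]] <- data.frame(
      gene = rownames(grad)[take],
      mean_importance = unname(means[take]),
      stringsAsFactors = FALSE)
  }
  out
}

#' Fold-change perturbation of one gene
#'
#' Multiplies the gene's raw expression by `fold_change`, re-applies the
#' frozen preprocessing, and re-predicts the target module's flux. Returns
#' the per-sample change and its mean; a gene outside the target module's
#' gene set gives exactly zero change.
#'
#' @param model A `flux_model` or `flux_fit`.
#' @param data Raw expression matrix.
#' @param gene Gene to perturb (must be measured).
#' @param fold_change Positive multiplier; 1 is the identity.
#' @param target_module Module whose flux is read out.
#' @return List with `delta` (per-sample change) and `mean_delta`.
#' @export
perturb_gene <- function(model, data, gene, fold_change, target_module) {
  if (inherits(model, "flux_fit")) model <- model$model
  stopifnot(inherits(model, "flux_model"))
  if (!gene %in% rownames(data))
    stop("unknown gene: '", gene, "'", call. = FALSE)
  if (fold_change <= 0) stop("fold_change must be > 0", call. = FALSE)
  if (!target_module %in% names(model$graph$modules))
    stop("unknown module id: '", target_module, "'", call. = FALSE)
  base <- predict_flux(model, data)[target_module, ]
  data2 <- data
  data2[gene, ] <- data2[gene, ] * fold_change
  pert <- predict_flux(model, data2)[target_module, ]
  delta <- pert - base
  list(delta = delta, mean_delta = mean(delta))
}

#' Paired test for gene-to-module inclusion
#'
#' Given per-sample flux-imbalance losses with (`L_X`) and without (`L_Y`) a
#' candidate gene included in a module, tests H0: mu_X - mu_Y = 0 against
#' the one-sided alternative mu_X - mu_Y < 0 (inclusion improves balance).
#' The Wald statistic on paired differences, mean(d) / (sd(d)/sqrt(n)), is
#' referred to the t distribution with n - 1 degrees of freedom.
#'
#' @param with_gene_losses Nonnegative per-sample losses with the gene
#'   included.
#' @param without_gene_losses Same samples, gene excluded.
#' @param alternative Only `"less"` is offered (the inclusion hypothesis).
#' @return List with `statistic`, `p_value`, `mean_difference`, `df`.
#' @export
gene_inclusion_test <- function(with_gene_losses, without_gene_losses,
                                alternative = "less") {
  alternative <- match.arg(alternative, "less")
  lx <- as.numeric(with_gene_losses)
  ly <- as.numeric(without_gene_losses)
  if (length(lx) != length(ly))
    stop("paired losses must have equal length", call. = FALSE)
  n <- length(lx)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- lx - ly
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d < 1e-300)
    stop("degenerate paired sample: differences have zero variance",
         call. = FALSE)
  stat <- mean(d) / (sd_d / sqrt(n))
  list(statistic = stat,
       p_value = stats::pt(stat, df = n - 1L),
       mean_difference = mean(d),
       df = n - 1L)
}
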