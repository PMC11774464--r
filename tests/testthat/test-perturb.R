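# In-silico perturbation: gradients, importance embedding, clustering,
# ranking, fold-change perturbation, and the paired inclusion test.

fitted_toy <- function(seed = 1, n = 30) {
  sim <- simulate_dataset(simulation_spec(n_samples = n, seed = seed,
                                          genes_per_module = 4))
  fit <- fit_flux(sim$expression, sim$graph,
                  flux_config(init_epochs = 10L, sl_epochs = 15L,
                              max_iterations = 2L, seed = seed))
  list(sim = sim, fit = fit)
}

test_that("gradients have structural zeros and match finite differences", {
  tt <- fitted_toy()
  G <- compute_gradients(tt$fit, tt$sim$expression, "m2")
  expect_identical(dim(G), dim(tt$sim$expression))
  # genes outside the target module get an exact 0
  outside <- setdiff(rownames(G), tt$fit$graph$modules$m2$genes)
  expect_true(all(G[outside, ] == 0))
  expect_error(compute_gradients(tt$fit, tt$sim$expression, "mX"),
               "unknown module")
  # central finite differences on the preprocessed inputs
  genes <- tt$fit$graph$modules$m2$genes
  X <- apflux:::.preprocess_apply(tt$sim$expression,
                                  tt$fit$model$preprocess, genes)
  h <- 1e-4
  for (gi in seq_along(genes)) {
    Xp <- X; Xp[gi, ] <- Xp[gi, ] + h
    Xm <- X; Xm[gi, ] <- Xm[gi, ] - h
    fd <- (apflux:::mlp_forward(tt$fit$model$nets$m2, Xp)$f -
             apflux:::mlp_forward(tt$fit$model$nets$m2, Xm)$f) / (2 * h)
    rel <- max(abs(G[genes[gi], ] - fd)) / max(max(abs(fd)), 1e-8)
    expect_lt(rel, 1e-3)
  }
})

test_that("an affine surrogate has constant gradients that scale linearly", {
  # no hidden layers: softplus(w'x + b); large b makes softplus ~ identity,
  # so the gradient w.r.t. each input is the weight itself
  tt <- fitted_toy()
  model <- tt$fit$model
  w <- c(0.3, -0.2, 0.5, 0.1)
  for (id in names(model$nets))
    model$nets[[id]] <- list(W = list(matrix(w, 1, 4)), b = list(30),
                             dims = c(4L, 1L))
  G <- compute_gradients(model, tt$sim$expression, "m1")
  for (gi in 1:4)
    expect_equal(unname(G[model$graph$modules$m1$genes[gi], ]),
                 rep(w[gi], ncol(G)), tolerance = 1e-8)
  # doubling the weights doubles every gradient
  model2 <- model
  model2$nets$m1$W[[1]] <- 2 * model2$nets$m1$W[[1]]
  G2 <- compute_gradients(model2, tt$sim$expression, "m1")
  genes1 <- model$graph$modules$m1$genes
  expect_equal(G2[genes1, ], 2 * G[genes1, ], tolerance = 1e-7)
})

test_that("raw-scale gradients apply the preprocessing chain rule", {
  tt <- fitted_toy()
  Gp <- compute_gradients(tt$fit, tt$sim$expression, "m2")
  Gr <- compute_gradients(tt$fit, tt$sim$expression, "m2", scale = "raw")
  genes <- tt$fit$graph$modules$m2$genes
  raw <- tt$sim$expression[genes, ]
  jac <- 1 / ((1 + raw) * tt$fit$model$preprocess$scale[genes])
  expect_equal(Gr[genes, ], Gp[genes, ] * jac, tolerance = 1e-12)
})

test_that("importance embedding mirrors an independent eigendecomposition", {
  set.seed(8)
  G <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:40)))
  emb <- importance_embedding(G)
  expect_lte(ncol(emb$coordinates), 6L)
  M <- t(log(abs(G) + 1e-12))
  Mc <- scale(M, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Mc) / (nrow(Mc) - 1), symmetric = TRUE)
  scores <- Mc %*% ev$vectors[, seq_len(ncol(emb$coordinates))]
  for (k in seq_len(ncol(emb$coordinates))) {
    agree <- min(max(abs(emb$coordinates[, k] - scores[, k])),
                 max(abs(emb$coordinates[, k] + scores[, k])))
    expect_lt(agree, 1e-8)
  }
  # rank cap: a rank-2 gradient matrix yields 2 components
  low <- outer(exp(rnorm(10)), exp(rnorm(12))) *
    rep(c(1, 2), length.out = 10)
  rownames(low) <- paste0("g", 1:10); colnames(low) <- paste0("s", 1:12)
  emb_low <- importance_embedding(low)
  expect_lte(ncol(emb_low$coordinates), 2L)
  # duplicate samples map to identical coordinates
  Gd <- cbind(G, G[, 1, drop = FALSE])
  colnames(Gd) <- c(colnames(G), "dup")
  emb_d <- importance_embedding(Gd)
  expect_equal(emb_d$coordinates["dup", ], emb_d$coordinates["s1", ],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(importance_embedding(G * 0), "all-zero")
})

test_that("k-means clustering of importance recovers separated groups", {
  set.seed(12)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  truth <- rep(1:3, each = 15)
  co <- centers[truth, ] + matrix(rnorm(90, sd = 0.3), 45, 2)
  emb <- structure(list(coordinates = `rownames<-`(co, paste0("s", 1:45)),
                        explained = c(0.6, 0.4)),
                   class = "importance_embedding")
  labels <- cluster_importance(emb, k = 3, seed = 5)
  expect_identical(length(unique(labels)), 3L)
  # perfect agreement up to relabelling
  expect_identical(length(unique(paste(truth, labels))), 3L)
  # determinism given the seed
  expect_identical(labels, cluster_importance(emb, k = 3, seed = 5))
  # k = number of samples puts every sample in its own cluster
  one_each <- cluster_importance(emb, k = 45, seed = 5)
  expect_identical(length(unique(one_each)), 45L)
  expect_error(cluster_importance(emb, k = 46), "exceeds")
})

test_that("gene ranking equals a brute-force sort of cluster means", {
  set.seed(3)
  G <- matrix(rnorm(12 * 20), 12, 20,
              dimnames = list(paste0("g", sprintf("%02d", 1:12)),
                              paste0("s", 1:20)))
  labels <- rep(1:2, each = 10)
  ranked <- rank_genes(G, labels, top_n = 5)
  expect_length(ranked, 2L)
  for (cl in 1:2) {
    means <- rowMeans(log(abs(G[, labels == cl]) + 1e-12))
    ord <- order(-means, names(means))
    expect_identical(ranked[[as.character(cl)]]$gene,
                     names(means)[ord][1:5])
    expect_equal(ranked[[as.character(cl)]]$mean_importance,
                 unname(means[ord][1:5]))
  }
  # ranking is invariant to sample order
  perm <- sample(20)
  expect_identical(rank_genes(G[, perm], labels[perm], top_n = 5), ranked)
  # a dominating gene ranks first in every cluster
  G2 <- G; G2["g07", ] <- 100
  r2 <- rank_genes(G2, labels, top_n = 3)
  expect_true(all(vapply(r2, function(df) df$gene[1] == "g07", logical(1))))
})

test_that("fold-change perturbation behaves like the model's local slope", {
  tt <- fitted_toy()
  # identity perturbation changes nothing
  p1 <- perturb_gene(tt$fit, tt$sim$expression, "m2_g01", 1, "m2")
  expect_true(all(p1$delta == 0))
  # a gene outside the target module's gene set has no effect
  p0 <- perturb_gene(tt$fit, tt$sim$expression, "m4_g01", 2, "m2")
  expect_true(all(p0$delta == 0))
  expect_error(perturb_gene(tt$fit, tt$sim$expression, "nope", 2, "m2"),
               "unknown gene")
  expect_error(perturb_gene(tt$fit, tt$sim$expression, "m2_g01", 0, "m2"),
               "> 0")
  # affine surrogate: delta equals coefficient x input increment exactly
  model <- tt$fit$model
  w <- c(0.4, 0.1, -0.3, 0.2)
  model$nets$m2 <- list(W = list(matrix(w, 1, 4)), b = list(30),
                        dims = c(4L, 1L))
  pa <- perturb_gene(model, tt$sim$expression, "m2_g01", 2, "m2")
  raw <- tt$sim$expression["m2_g01", ]
  dx <- (log1p(2 * raw) - log1p(raw)) / model$preprocess$scale["m2_g01"]
  expect_equal(unname(pa$delta), unname(w[1] * dx), tolerance = 1e-7)
  expect_gt(pa$mean_delta, 0)
})

test_that("the paired inclusion test matches the t reference and its symmetry", {
  expect_error(gene_inclusion_test(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_error(gene_inclusion_test(1, 2), "at least 2")
  lx <- c(1, 2, 0.5, 1.5); ly <- lx + c(2, 1, 3, 2)
  res <- gene_inclusion_test(lx, ly)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$mean_difference, mean(lx - ly))
  # oracle: one-sided paired t
  ref <- t.test(lx, ly, paired = TRUE, alternative = "less")
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # swapping the roles maps p to 1 - p
  swapped <- gene_inclusion_test(ly, lx)
  expect_equal(swapped$p_value, 1 - res$p_value, tolerance = 1e-12)
})

test_that("the inclusion test holds its level under exchangeable losses", {
  set.seed(2024)
  rej <- mean(replicate(2000, {
    gene_inclusion_test(rexp(20), rexp(20))$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
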