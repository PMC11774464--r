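# Flux approximators, imbalance/penalty losses, coherence.

make_sim <- function(n = 40, seed = 1, genes_per_module = 4) {
  simulate_dataset(simulation_spec(n_samples = n, seed = seed,
                                   genes_per_module = genes_per_module))
}

test_that("build_flux_model creates one deterministic approximator per module", {
  sim <- make_sim()
  g3 <- chain2_graph(genes1 = c("m1_g01", "m1_g02"), genes2 = "m2_g01")
  m3 <- build_flux_model(g3, sim$expression)
  expect_length(m3$nets, 2L)
  m <- build_flux_model(sim$graph, sim$expression, flux_config(seed = 9))
  expect_length(m$nets, length(sim$graph$modules))
  m_again <- build_flux_model(sim$graph, sim$expression, flux_config(seed = 9))
  expect_identical(m$nets, m_again$nets)
  m_other <- build_flux_model(sim$graph, sim$expression, flux_config(seed = 10))
  expect_false(identical(m$nets, m_other$nets))
  # architecture echo
  mw <- build_flux_model(sim$graph, sim$expression,
                         flux_config(hidden = c(16L, 8L)))
  expect_identical(dim(mw$nets[[1]]$W[[1]])[1], 16L)
  expect_identical(dim(mw$nets[[1]]$W[[2]])[1], 8L)
  # module with no measured genes is refused
  expect_error(build_flux_model(sim$graph, sim$expression[-(1:4), ]),
               "not measured")
})

test_that("predict_flux is nonnegative, per-sample, and keyed by gene id", {
  sim <- make_sim(n = 25)
  model <- build_flux_model(sim$graph, sim$expression)
  FF <- predict_flux(model, sim$expression)
  expect_identical(dim(FF), c(length(sim$graph$modules), 25L))
  expect_true(all(FF >= 0))
  # duplicating a sample duplicates its flux column
  dup <- cbind(sim$expression, dup_sample = sim$expression[, 3])
  colnames(dup) <- c(colnames(sim$expression), "dup")
  Fd <- predict_flux(model, dup)
  expect_equal(unname(Fd[, "dup"]), unname(FF[, 3]))
  # permuting samples permutes columns identically
  perm <- sample(ncol(sim$expression))
  Fp <- predict_flux(model, sim$expression[, perm])
  expect_equal(Fp, FF[, perm])
  # permuting gene rows changes nothing (inputs keyed by id, not position)
  Fg <- predict_flux(model, sim$expression[rev(rownames(sim$expression)), ])
  expect_equal(Fg, FF)
  expect_error(predict_flux(model, sim$expression[-1, ]), "missing genes")
})

test_that("imbalance_loss matches its closed forms", {
  g <- chain2_graph()
  # chain R1 -> C1 -> R2, one sample, flux (1, 2), gamma 1 -> loss 1
  flux <- matrix(c(1, 2), 2, 1, dimnames = list(c("r1", "r2"), "s1"))
  lb <- imbalance_loss(flux, g)
  expect_equal(lb$flux_balance, 1)
  expect_equal(lb$total, lb$flux_balance + lb$penalty)
  expect_equal(sum(lb$per_intermediate), lb$flux_balance)
  # linear in gamma
  g2 <- set_gamma(g, 2)
  expect_equal(imbalance_loss(flux, g2)$flux_balance, 2)
  # balanced flux -> 0
  bal <- matrix(c(3, 3), 2, 1, dimnames = list(c("r1", "r2"), "s1"))
  expect_equal(imbalance_loss(bal, g)$flux_balance, 0)
  expect_error(imbalance_loss(flux[1, , drop = FALSE], g), "modules")
})

test_that("imbalance_loss equals the weighted matrix formula and is additive", {
  for (s in 1:20) {
    g <- random_test_graph(s)
    S <- incidence_matrix(g)
    gam <- pathway_gamma(g)
    set.seed(s + 900)
    FF <- matrix(runif(ncol(S) * 6, 0, 4), ncol(S), 6,
                 dimnames = list(colnames(S), paste0("s", 1:6)))
    lb <- imbalance_loss(FF, g)
    ref <- sum(vapply(seq_len(ncol(FF)), function(j)
      sum((sqrt(gam) * (S %*% FF[, j]))^2), numeric(1)))
    expect_equal(lb$flux_balance, ref, tolerance = 1e-10)
    # invariant under sample permutation, additive over samples
    perm <- sample(6)
    expect_equal(imbalance_loss(FF[, perm], g)$flux_balance, lb$flux_balance)
    parts <- sum(vapply(seq_len(6), function(j)
      imbalance_loss(FF[, j, drop = FALSE], g)$flux_balance, numeric(1)))
    expect_equal(parts, lb$flux_balance, tolerance = 1e-10)
  }
})

test_that("penalty_loss combines the L1 and hinge terms as configured", {
  sim <- make_sim(n = 10)
  model <- build_flux_model(sim$graph, sim$expression)
  FF <- predict_flux(model, sim$expression)
  expect_equal(penalty_loss(model, FF, flux_config(lambda1 = 0, lambda2 = 0)), 0)
  # all-zero flux, lambda2 = 1, tau = 1, one sample -> hinge contributes 1
  z <- matrix(0, nrow(FF), 1, dimnames = list(rownames(FF), "s1"))
  p <- penalty_loss(model, z, flux_config(lambda1 = 0, lambda2 = 1, tau = 1))
  expect_equal(p, 1)
  # totals above tau everywhere -> anchor term 0
  big <- FF + 10
  expect_equal(penalty_loss(model, big,
                            flux_config(lambda1 = 0, lambda2 = 1, tau = 1)), 0)
  expect_error(flux_config(lambda2 = -1), ">= 0")
  expect_error(flux_config(tau = -2), ">= 0")
})

test_that("coherence reports per-module correlation and residual", {
  set.seed(4)
  A <- matrix(runif(5 * 200), 5, 200,
              dimnames = list(paste0("m", 1:5), NULL))
  expect_error(coherence(A, A[, 1:199]), "shapes")
  same <- coherence(A, A)
  expect_true(all(same$correlation == 1))
  expect_true(all(same$rms == 0))
  # slope-reversed construction anti-correlates each module
  B2 <- t(apply(A, 1, function(v) max(v) + min(v) - v))
  anti <- coherence(A, B2)
  expect_true(all(anti$correlation < -0.999))
  # independent matrices: small correlation, matching cor() to 1e-12
  C <- matrix(runif(5 * 200), 5, 200)
  ind <- coherence(A, C)
  expect_true(all(abs(ind$correlation) < 0.25))
  for (m in 1:5)
    expect_equal(ind$correlation[m], cor(A[m, ], C[m, ]), tolerance = 1e-12)
  # zero variance reported as NA, not 0
  Z <- A; Z[2, ] <- 7
  expect_true(is.na(coherence(Z, C)$correlation[2]))
  expect_error(coherence(A[, 1:2], C[, 1:2]), ">= 3 samples")
})
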