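# ---------------------------------------------------------------------------
# Message-passing optimization step: exact per-sample projection of a
# predicted flux vector onto the flux-balance solution space.
#
# Hard mode solves, per sample,
#     min ||f' - f||^2   s.t.  S f' = 0,  f' >= 0
# with a primal active-set method (SVD-based equality projections + KKT
# multiplier checks). For quadratic factors this QP minimizer coincides with
# Gaussian belief propagation on the factor graph, and is exact and testable.
# Soft mode solves
#     min ||f' - f||^2 + soft_lambda * sum_k gamma_k (S f')_k^2   s.t. f' >= 0
# (the trust-region flavour; gamma matters only here, since hard mode's
# feasible set S f = 0 is gamma-independent).
# ---------------------------------------------------------------------------

# orthonormal basis of the row space of A (right singular vectors with
# nonnegligible singular value); NULL if A has no rows
.rowspace_basis <- function(A, tol = 1e-10) {
  if (is.null(A) || nrow(A) == 0L) return(NULL)
  sv <- svd(A, nu = 0)
  keep <- sv$d > tol * max(sv$d[1], 1e-300)
  if (!any(keep)) return(NULL)
  sv$v[, keep, drop = FALSE]
}

# exact projection of a single column onto {S x = 0, x >= 0} by active sets
.project_hard_one <- function(f, S, tol = 1e-9, max_iter = 100L) {
  m <- length(f)
  active <- integer(0)
  E <- diag(m)
  for (it in seq_len(max_iter)) {
    C <- rbind(S, E[active, , drop = FALSE])
    V <- .rowspace_basis(C)
    x <- if (is.null(V)) f else f - V %*% crossprod(V, f)
    x <- drop(x)
    x[active] <- 0
    viol <- which(x < -tol)
    viol <- setdiff(viol, active)
    if (length(viol)) {
      active <- sort(c(active, viol[which.min(x[viol])]))
      next
    }
    if (length(active)) {
      # least-norm multipliers: C^T lambda = f - x ; bound multiplier mu_i =
      # -lambda_i must be >= 0 for optimality
      sv <- svd(C)
      keep <- sv$d > 1e-10 * max(sv$d[1], 1e-300)
      r <- f - x
      lam <- sv$u[, keep, drop = FALSE] %*%
        ((crossprod(sv$v[, keep, drop = FALSE], r)) / sv$d[keep])
      mu <- -lam[nrow(S) + seq_along(active)]
      drop_i <- which(mu < -tol)
      if (length(drop_i)) {
        active <- active[-drop_i[which.min(mu[drop_i])]]
        next
      }
    }
    x[x < 0] <- 0
    return(x)
  }
  # defensive fallback: exhaustive active-set enumeration (small m only)
  if (m <= 12L) return(.project_hard_enum(f, S))
  stop("active-set projection failed to converge", call. = FALSE)
}

# brute-force exact projection by enumerating all bound active sets;
# independent of the active-set path, also used as a test oracle
.project_hard_enum <- function(f, S, feas_tol = 1e-8) {
  m <- length(f)
  best <- NULL; best_d <- Inf
  E <- diag(m)
  for (mask in 0:(2^m - 1)) {
    active <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    C <- rbind(S, E[active, , drop = FALSE])
    V <- .rowspace_basis(C)
    x <- if (is.null(V)) f else drop(f - V %*% crossprod(V, f))
    x[active] <- 0
    if (min(x) < -feas_tol) next
    d <- sum((x - f)^2)
    if (d < best_d - 1e-15) { best <- x; best_d <- d }
  }
  best[best < 0] <- 0
  best
}

# soft-mode projection per column: min x'Hx/2 - f'x s.t. x >= 0 with
# H = I + soft_lambda * S' Gamma S (bound-constrained strictly convex QP)
.project_soft_one <- function(f, H, tol = 1e-9, max_iter = 200L) {
  m <- length(f)
  active <- integer(0)
  for (it in seq_len(max_iter)) {
    free <- setdiff(seq_len(m), active)
    x <- numeric(m)
    if (length(free))
      x[free] <- drop(solve(H[free, free, drop = FALSE], f[free]))
    viol <- free[x[free] < -tol]
    if (length(viol)) {
      active <- sort(c(active, viol[which.min(x[viol])]))
      next
    }
    if (length(active)) {
      mu <- drop(H[active, , drop = FALSE] %*% x) - f[active]
      drop_i <- which(mu < -tol)
      if (length(drop_i)) {
        active <- active[-drop_i[which.min(mu[drop_i])]]
        next
      }
    }
    x[x < 0] <- 0
    return(x)
  }
  stop("soft projection failed to converge", call. = FALSE)
}

#' Project fluxes onto the flux-balance solution space
#'
#' The message-passing optimization step. In `"hard"` mode each sample's flux
#' vector is replaced by the unique closest nonnegative vector satisfying
#' exact balance (`S f' = 0`); in `"soft"` mode balance is a quadratic
#' penalty weighted by `soft_lambda` and the per-intermediate `gamma`.
#' Already-feasible columns are returned unchanged (to numerical precision);
#' the operation is idempotent.
#'
#' @param flux Nonnegative flux matrix (modules x samples).
#' @param graph A `pathway_graph` (supplies the incidence matrix and gamma).
#' @param config Settings from [flux_config()]; uses `projection_mode` and
#'   `soft_lambda`.
#' @return Projected flux matrix of the same shape and dimnames.
#' @export
mpo_project <- function(flux, graph, config = flux_config()) {
  config <- flux_config(config)
  S <- incidence_matrix(graph)
  if (nrow(flux) != ncol(S))
    stop("flux/graph shape mismatch", call. = FALSE)
  if (!is.null(rownames(flux)) && all(rownames(flux) %in% colnames(S)))
    flux <- flux[colnames(S), , drop = FALSE]
  if (any(flux < 0))
    stop("input flux must be nonnegative", call. = FALSE)
  out <- flux
  if (config$projection_mode == "hard") {
    V <- .rowspace_basis(S)
    # equality-only projection of all columns at once; only columns that go
    # negative need the active-set treatment
    X0 <- if (is.null(V)) flux else flux - V %*% crossprod(V, flux)
    needs_as <- which(apply(X0, 2, min) < -1e-9)
    out[] <- X0
    for (j in needs_as) out[, j] <- .project_hard_one(flux[, j], S)
    out[out < 0 & out > -1e-9] <- 0
  } else {
    gam <- pathway_gamma(graph)
    H <- diag(nrow(flux)) + config$soft_lambda * crossprod(S * sqrt(gam))
    # unconstrained solve for all columns; fix up the negative ones
    X0 <- solve(H, flux)
    needs_as <- which(apply(X0, 2, min) < -1e-9)
    out[] <- X0
    for (j in needs_as) out[, j] <- .project_soft_one(flux[, j], H)
    out[out < 0 & out > -1e-9] <- 0
  }
  dimnames(out) <- dimnames(flux)
  out
}
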