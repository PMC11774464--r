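# ---------------------------------------------------------------------------
# Minimal multilayer-perceptron machinery used for the per-reaction flux
# approximators: deterministic seeded initialization, vectorized forward
# pass, reverse-mode gradients w.r.t. parameters and inputs, and Adam.
#
# Layout: inputs d x n (genes x samples), L hidden tanh layers, scalar linear
# readout rectified through softplus so predicted fluxes are nonnegative.
# All of this is internal; users interact through build_flux_model() etc.
# ---------------------------------------------------------------------------

# evaluate expr with a temporary RNG state seeded by `seed`; the seed is
# forced BEFORE the current state is captured, so a lazily-drawn random seed
# argument is not rewound by the restore
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed stream; stays below 2^31 - 1
seed_stream <- function(master, key) {
  key_num <- if (is.character(key)) sum(utf8ToInt(key)) else as.numeric(key)
  as.integer((as.numeric(master) * 48271 + key_num * 16807 + 1) %% 2147483629) + 1L
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Weights are initialized NONNEGATIVE (|half-normal|, scaled by fan-in) so the
# initial map is monotone increasing in every input: the generative prior is
# that pathway-gene expression increases with reaction rate, and the
# flux-balance loss alone cannot identify the sign of the association.
# Training is unconstrained afterwards.
mlp_init <- function(d_in, hidden, seed) {
  with_seed(seed, {
    dims <- c(d_in, hidden, 1L)
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      sdl <- sqrt(1 / dims[l])
      W[[l]] <- matrix(abs(stats::rnorm(dims[l + 1L] * dims[l], sd = sdl)),
                       nrow = dims[l + 1L], ncol = dims[l])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    b[[length(b)]] <- 0.5  # keep softplus away from its dead zone at init
    list(W = W, b = b, dims = dims)
  })
}

# forward pass; X is d x n. Returns f (length n) and caches activations.
mlp_forward <- function(par, X, keep_cache = TRUE) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L))
    A[[l + 1L]] <- tanh(par$W[[l]] %*% A[[l]] + par$b[[l]])
  z_out <- drop(par$W[[L]] %*% A[[L]] + par$b[[L]])
  f <- softplus(z_out)
  out <- list(f = f, z_out = z_out)
  if (keep_cache) out$A <- A
  out
}

# gradients of sum_j df[j] * f_j w.r.t. parameters (and optionally inputs)
mlp_backward <- function(par, fwd, df, want_input_grad = FALSE) {
  L <- length(par$W)
  A <- fwd$A
  dz <- matrix(df * stats::plogis(fwd$z_out), nrow = 1L)  # softplus'
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in seq(L, 1L)) {
    gW[[l]] <- dz %*% t(A[[l]])
    gb[[l]] <- rowSums(dz)
    if (l > 1L) {
      dA <- t(par$W[[l]]) %*% dz
      dz <- dA * (1 - A[[l]]^2)
    } else if (want_input_grad) {
      dX <- t(par$W[[1L]]) %*% dz
    }
  }
  out <- list(W = gW, b = gb)
  if (want_input_grad) out$X <- dX
  out
}

# per-sample gradient of the scalar output w.r.t. each input (d x n)
mlp_input_grad <- function(par, X) {
  fwd <- mlp_forward(par, X)
  mlp_backward(par, fwd, df = rep(1, ncol(X)), want_input_grad = TRUE)$X
}

adam_init <- function(par) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(par$W), vW = zero_like(par$W),
       mb = zero_like(par$b), vb = zero_like(par$b), t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(par$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(par = par, state = state)
}
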