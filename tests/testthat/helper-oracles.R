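# Independent oracles and fixture generators used across the suite.
# These deliberately avoid the package's internal code paths.

# Exact projection onto {S x = 0, x >= 0} by exhaustive enumeration of bound
# active sets; each equality-constrained subproblem is solved through the
# Moore-Penrose pseudoinverse (MASS::ginv), a different route from the
# package's SVD active-set iteration.
oracle_project <- function(f, S, feas_tol = 1e-8) {
  m <- length(f)
  best <- NULL
  best_d <- Inf
  for (mask in 0:(2^m - 1L)) {
    act <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    C <- rbind(S, diag(m)[act, , drop = FALSE])
    x <- if (nrow(C) == 0L) f else
      drop(f - t(C) %*% (MASS::ginv(C %*% t(C)) %*% (C %*% f)))
    x[act] <- 0
    if (min(x) < -feas_tol) next
    d <- sum((x - f)^2)
    if (d < best_d - 1e-15) { best <- x; best_d <- d }
  }
  best[best < 0] <- 0
  best
}

# Local bivariate Moran's I by explicit double loops.
oracle_moran <- function(xv, yv, W, scale = TRUE) {
  n <- length(xv)
  if (scale) {
    xv <- (xv - mean(xv)) / sd(xv)
    yv <- (yv - mean(yv)) / sd(yv)
  }
  denom <- 0
  for (i in seq_len(n)) denom <- denom + xv[i]^2
  I <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + W[i, j] * yv[j]
    I[i] <- xv[i] * s / denom
  }
  I
}

# Gaussian amplification by explicit loops over in-radius neighbours.
oracle_amplify <- function(coords, values, sigma, radius, normalize = TRUE) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= radius) {
        w <- exp(-d^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
        num <- num + w * values[j]
        den <- den + w
      }
    }
    out[i] <- if (normalize) num / den else num
  }
  out
}

# Random small valid factor graphs: a chain plus extra single-edge branch
# modules attached to random intermediates.
random_test_graph <- function(seed, max_modules = 8L) {
  set.seed(seed)
  m_chain <- sample(2:5, 1)
  extra <- sample(0:min(3L, max_modules - m_chain), 1)
  mods <- paste0("r", seq_len(m_chain + extra))
  modules <- lapply(mods, function(m)
    list(id = m, name = m, genes = paste0(m, "_g1")))
  names(modules) <- mods
  cids <- paste0("c", seq_len(m_chain - 1L))
  intermediates <- lapply(cids, function(ci)
    list(id = ci, name = ci, gamma = runif(1, 0.2, 2)))
  names(intermediates) <- cids
  produce <- data.frame(module = mods[seq_len(m_chain - 1L)],
                        intermediate = cids, stringsAsFactors = FALSE)
  consume <- data.frame(intermediate = cids,
                        module = mods[1L + seq_len(m_chain - 1L)],
                        stringsAsFactors = FALSE)
  if (extra > 0) for (e in seq_len(extra)) {
    id <- mods[m_chain + e]
    ci <- sample(cids, 1)
    if (runif(1) < 0.5)
      produce <- rbind(produce, data.frame(module = id, intermediate = ci))
    else
      consume <- rbind(consume, data.frame(intermediate = ci, module = id))
  }
  g <- apflux:::new_pathway_graph(paste0("rg", seed), modules, intermediates,
                                  produce, consume)
  validate_pathway(g)
}

# Write a small pathway schema file and return its path.
write_temp_pathway <- function(lines) {
  path <- tempfile(fileext = ".pw")
  writeLines(lines, path)
  path
}

# A tiny linear chain graph R1 -> C1 -> R2 with configurable genes.
chain2_graph <- function(genes1 = "gA", genes2 = "gB") {
  path <- write_temp_pathway(c(
    "pathway chain2",
    sprintf('module r1 "first" genes=%s', paste(genes1, collapse = ",")),
    sprintf('module r2 "second" genes=%s', paste(genes2, collapse = ",")),
    'intermediate c1 "mid" gamma=1',
    "edge r1 -> c1",
    "edge c1 -> r2"))
  load_pathway(path)
}
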