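# ---------------------------------------------------------------------------
# Spatial analysis for spot-level data: Gaussian signal amplification,
# local bivariate Moran's I with permutation pseudo-p-values, and four-way
# segmentation of antigen-presentation vs T-cell dependency.
# ---------------------------------------------------------------------------

#' Construct a spatial field
#'
#' @param coordinates Numeric matrix or data.frame with two columns (x, y).
#' @param values One numeric value per spot.
#' @param spot_ids Optional spot identifiers.
#' @return An object of class `spatial_field`.
#' @export
spatial_field <- function(coordinates, values,
                          spot_ids = rownames(coordinates)) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 2L)
    stop("coordinates must have two columns", call. = FALSE)
  if (any(!is.finite(coordinates)))
    stop("coordinates must be finite", call. = FALSE)
  if (nrow(coordinates) != length(values))
    stop("one value per spot required", call. = FALSE)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(coordinates)))
  structure(list(coordinates = unname(coordinates),
                 values = as.numeric(values),
                 spot_ids = as.character(spot_ids)),
            class = "spatial_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat("Spatial field:", length(x$values), "spots; value range [",
      format(min(x$values), digits = 3), ",",
      format(max(x$values), digits = 3), "]\n")
  invisible(x)
}

# median nearest-neighbour distance, used for default bandwidths
.median_nn_dist <- function(coords) {
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  stats::median(apply(D, 1, min))
}

#' Gaussian kernel spatial weights
#'
#' `w_ij = g(d_ij)` with `g` the zero-mean Gaussian density in distance,
#' zero beyond `radius`; symmetric; the diagonal is zero unless
#' `self_weight`.
#'
#' @param coordinates Spot coordinates (n x 2).
#' @param sigma Kernel bandwidth (> 0). Default: 1.5 x median
#'   nearest-neighbour distance.
#' @param radius Neighbourhood cutoff (> 0). Default: `3 * sigma`.
#' @param self_weight Include the spot itself (weight `g(0)`)?
#' @return An object of class `kernel_weights` with elements `weights`
#'   (n x n), `sigma`, `radius`, `self_weight`.
#' @export
kernel_weights <- function(coordinates, sigma = NULL, radius = NULL,
                           self_weight = FALSE) {
  coordinates <- as.matrix(coordinates)
  if (is.null(sigma)) sigma <- 1.5 * .median_nn_dist(coordinates)
  if (is.null(radius)) radius <- 3 * sigma
  if (sigma <= 0 || radius <= 0)
    stop("sigma and radius must be > 0", call. = FALSE)
  D <- as.matrix(stats::dist(coordinates))
  W <- stats::dnorm(D, mean = 0, sd = sigma)
  W[D > radius] <- 0
  if (!self_weight) diag(W) <- 0
  structure(list(weights = W, sigma = sigma, radius = radius,
                 self_weight = self_weight),
            class = "kernel_weights")
}

#' Gaussian amplification of a spatial signal
#'
#' Smooths a low-signal spot-level field with a Gaussian kernel over the
#' neighbourhood `N_i` (spots within `radius`; the spot itself is included).
#' The default computes the kernel-weighted combination of the neighbours'
#' values, divided by the summed kernel weights when `normalize` is on (a
#' convex combination). `literal = TRUE` reproduces the unnormalized form in
#' which the centre value multiplies the summed kernel weights.
#'
#' @param field A `spatial_field`.
#' @param sigma,radius Kernel bandwidth and cutoff; defaults as in
#'   [kernel_weights()].
#' @param normalize Divide by the summed kernel weights (default TRUE).
#' @param literal Use the centre-value form `f_i * sum_j g(d_ij)`.
#' @return A `spatial_field` of amplified values.
#' @export
gaussian_amplify <- function(field, sigma = NULL, radius = NULL,
                             normalize = TRUE, literal = FALSE) {
  stopifnot(inherits(field, "spatial_field"))
  kw <- kernel_weights(field$coordinates, sigma, radius, self_weight = TRUE)
  W <- kw$weights
  totals <- rowSums(W)
  amp <- if (literal) field$values * totals else drop(W %*% field$values)
  if (normalize && !literal) amp <- amp / totals
  spatial_field(field$coordinates, amp, field$spot_ids)
}

#' Local bivariate Moran's I
#'
#' Per-spot association between one variable at the spot and the
#' kernel-weighted neighbourhood level of another:
#' `I_i = x_i * (sum_j w_ij y_j) / sum_i x_i^2`. By default both variables
#' are z-scored across spots first; `scale = FALSE` uses raw values.
#'
#' @param x,y `spatial_field`s over the same spots.
#' @param weights A `kernel_weights` over the same spots.
#' @param scale Z-score `x` and `y` first (default TRUE).
#' @return Numeric vector of per-spot `I_i`.
#' @export
local_bivariate_moran <- function(x, y, weights, scale = TRUE) {
  stopifnot(inherits(x, "spatial_field"), inherits(y, "spatial_field"),
            inherits(weights, "kernel_weights"))
  n <- length(x$values)
  if (length(y$values) != n || nrow(weights$weights) != n)
    stop("x, y and weights must cover the same spots", call. = FALSE)
  xv <- x$values; yv <- y$values
  if (scale) {
    if (stats::sd(xv) < 1e-14 || stats::sd(yv) < 1e-14)
      stop("zero variance; cannot z-score", call. = FALSE)
    xv <- (xv - mean(xv)) / stats::sd(xv)
    yv <- (yv - mean(yv)) / stats::sd(yv)
  }
  denom <- sum(xv^2)
  if (denom <= 0) stop("sum of squared x values is zero", call. = FALSE)
  as.vector(xv * (weights$weights %*% yv) / denom)
}

#' Permutation pseudo-p-values for local bivariate Moran's I
#'
#' The y values are randomly permuted across all spots; the pseudo-p at spot
#' i is the add-one-corrected proportion of permutations whose `I_i` is at
#' least as extreme as observed. `alternative = "greater"` (default) counts
#' permuted values `>=` observed; `"two.sided"` compares absolute values and
#' is appropriate when discordant (high/low) dependency must also reach
#' significance, as in [segment_regions()].
#'
#' @param x,y `spatial_field`s.
#' @param weights A `kernel_weights`.
#' @param n_permutations Number of permutations (>= 1; default 999).
#' @param seed Integer seed; results are deterministic given it.
#' @param alternative `"greater"` or `"two.sided"`.
#' @param add_one Use the add-one correction `(1 + count) /
#'   (n_permutations + 1)` so p > 0 always (default); `FALSE` gives the bare
#'   proportion.
#' @param scale Z-score the fields first (default TRUE).
#' @return An object of class `moran_result`: `local_I`, `pseudo_p`,
#'   `n_permutations`, `seed`, `alternative`.
#' @export
permutation_pvalues <- function(x, y, weights, n_permutations = 999L,
                                seed = 1L,
                                alternative = c("greater", "two.sided"),
                                add_one = TRUE, scale = TRUE) {
  alternative <- match.arg(alternative)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  obs <- local_bivariate_moran(x, y, weights, scale = scale)
  n <- length(obs)
  count <- integer(n)
  obs_cmp <- if (alternative == "two.sided") abs(obs) else obs
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      yp <- spatial_field(y$coordinates, y$values[sample.int(n)], y$spot_ids)
      Ip <- local_bivariate_moran(x, yp, weights, scale = scale)
      Icmp <- if (alternative == "two.sided") abs(Ip) else Ip
      count <- count + (Icmp >= obs_cmp)
    }
  })
  pp <- if (add_one) (1 + count) / (n_permutations + 1) else count / n_permutations
  structure(list(local_I = obs, pseudo_p = pp,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alternative = alternative),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Local bivariate Moran's I over", length(x$local_I), "spots;",
      sum(x$pseudo_p < 0.05), "spots with pseudo-p < 0.05 (",
      x$n_permutations, "permutations,", x$alternative, ")\n")
  invisible(x)
}

#' Four-way segmentation of significant spatial dependency
#'
#' Spots with `pseudo_p >= alpha` are `not_significant`; significant spots
#' are labelled by the sign pattern of the spot's z-scored x value and the
#' kernel-weighted neighbourhood average of the z-scored y values:
#' (+,+) `high_antigen_high_T`, (+,-) `high_antigen_low_T`,
#' (-,+) `low_antigen_high_T`, (-,-) `low_antigen_low_T`. A z-score of
#' exactly 0 resolves to the "low" side. Detecting the discordant patterns
#' requires a two-sided `moran_result` (see [permutation_pvalues()]).
#'
#' @param x,y `spatial_field`s (antigen-presentation level and T-cell level).
#' @param weights A `kernel_weights`.
#' @param result A `moran_result` for (x, y, weights).
#' @param alpha Significance level (default 0.05).
#' @return Factor of per-spot labels with levels `high_antigen_high_T`,
#'   `high_antigen_low_T`, `low_antigen_high_T`, `low_antigen_low_T`,
#'   `not_significant`.
#' @export
segment_regions <- function(x, y, weights, result, alpha = 0.05) {
  stopifnot(inherits(result, "moran_result"))
  n <- length(x$values)
  if (length(result$pseudo_p) != n)
    stop("result does not align with the spot set", call. = FALSE)
  if (stats::sd(x$values) < 1e-14 || stats::sd(y$values) < 1e-14)
    stop("zero variance in x or y", call. = FALSE)
  zx <- (x$values - mean(x$values)) / stats::sd(x$values)
  zy <- (y$values - mean(y$values)) / stats::sd(y$values)
  ny <- drop(weights$weights %*% zy)
  lv <- c("high_antigen_high_T", "high_antigen_low_T",
          "low_antigen_high_T", "low_antigen_low_T", "not_significant")
  lab <- rep("not_significant", n)
  sig <- result$pseudo_p < alpha
  hi_x <- zx > 0; hi_y <- ny > 0
  lab[sig & hi_x & hi_y] <- "high_antigen_high_T"
  lab[sig & hi_x & !hi_y] <- "high_antigen_low_T"
  lab[sig & !hi_x & hi_y] <- "low_antigen_high_T"
  lab[sig & !hi_x & !hi_y] <- "low_antigen_low_T"
  factor(lab, levels = lv)
}
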