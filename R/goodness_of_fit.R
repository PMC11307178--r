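# One-sample Kolmogorov asymptotic tail: P(sqrt(n) * D > lambda).
# Standard alternating series; converges in a handful of terms for the
# lambda values that matter.
.ks_asymptotic_p <- function(d, n) {
  lambda <- sqrt(n) * d
  if (lambda < 1e-10) return(1)
  j <- seq_len(100L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

# Convert DMA values to integer sixteenths (the 17-point grid index 0..16).
.dma_sixteenths <- function(v) {
  k <- as.integer(round(16 * as.numeric(v)))
  if (any(k < 0L | k > 16L)) stop("DMA values outside [0, 1]", call. = FALSE)
  k
}

#' Kolmogorov-Smirnov distance between observed and expected DMA
#'
#' The K-S distance d is the largest absolute difference between the
#' empirical CDF of a match's valid DMA values and the exact expected CDF
#' under the independent-rallies model, evaluated over the 17-point support.
#' Both CDFs are step functions that jump only at the support points, so
#' evaluating at the grid points is exact; ties in the observed values are
#' handled naturally by the grid.
#'
#' @param dma A `dma_series` (or numeric vector of DMA values on the k/16
#'   grid).
#' @param expected An [expected_dma_distribution()] built from the same
#'   match's overall winning probability.
#' @return The distance d in \[0, 1\].
#' @export
ks_distance <- function(dma, expected) {
  stopifnot(inherits(expected, "expected_dma_dist"))
  v <- as.numeric(dma)
  if (!length(v)) stop("empty DMA series", call. = FALSE)
  k <- .dma_sixteenths(v)
  ecdf_grid <- cumsum(tabulate(k + 1L, 17L)) / length(k)
  max(abs(ecdf_grid - expected_cdf(expected)))
}

# Simulate the null distribution of the K-S distance: `replicates`
# independent-rallies matches of n_rallies rallies at probability p, each
# reduced to its DMA and its distance to the expected distribution at the
# replicate's own estimated winning probability. Re-estimating p per
# replicate mirrors what is done to the observed match (whose p is also
# estimated from the data), so observed and replicate distances are
# exchangeable under the null — the parametric-bootstrap analogue of the
# Lilliefors correction. Vectorised: one outcome matrix, one multivariate
# convolution filter pass, one 17 x 128 aggregation product.
.ks_null_distances <- function(p, n_rallies, replicates) {
  x <- matrix(stats::rbinom(n_rallies * replicates, 1L, p),
              nrow = n_rallies, ncol = replicates)
  f <- stats::filter(x, .dma_kernel, method = "convolution", sides = 2)
  k <- round(unclass(f)[4:(n_rallies - 3L), , drop = FALSE])  # 16 * DMA
  m <- n_rallies - 6L
  # per-replicate exact expected CDF at the replicate's own p-hat
  seqs <- enumerate_sequences(7L)
  k_wins <- rowSums(seqs)
  dma_num <- as.integer(seqs %*% .dma_kernel)
  agg <- vapply(0:16, function(v) as.numeric(dma_num == v), numeric(128L))
  p_hat <- colMeans(x)
  prob128 <- t(outer(p_hat, k_wins, "^") * outer(1 - p_hat, 7 - k_wins, "^"))
  cdf_exp <- apply(t(agg) %*% prob128, 2L, cumsum)  # 17 x replicates
  counts <- vapply(seq_len(replicates),
                   function(j) tabulate(k[, j] + 1L, 17L), integer(17L))
  ecdf <- apply(counts, 2L, cumsum) / m
  apply(abs(ecdf - cdf_exp), 2L, max)
}

#' One-sample K-S test of a match's DMA distribution
#'
#' Tests whether the observed distribution of a match's DMA values is
#' compatible with the exact expected distribution at the match's overall
#' winning probability. Two p-value methods are available:
#'
#' * `"asymptotic"`: the standard one-sample Kolmogorov tail probability at
#'   the observed d and n. On the discrete 17-point support, and with the
#'   serial dependence of overlapping DMA windows, this p-value is
#'   conservative; it is the default because it requires no simulation.
#' * `"monte_carlo"`: simulates `mc_replicates` independent-rallies matches
#'   of the same length and winning probability, recomputes the DMA and its
#'   K-S distance for each — against the expected distribution at the
#'   replicate's own estimated winning probability, mirroring the estimation
#'   done for the observed match — and reports the fraction of replicate
#'   distances at least as large as the observed one. The replicates
#'   reproduce the discreteness of the support, the autocorrelation of
#'   overlapping DMA windows, and the effect of estimating p from the match
#'   itself, so this p-value is correctly calibrated and is recommended when
#'   runtime permits.
#'
#' @param dma A `dma_series` of the match (valid-edge policy).
#' @param expected An [expected_dma_distribution()] at the match's winning
#'   probability.
#' @param method `"asymptotic"` (default) or `"monte_carlo"`.
#' @param mc_replicates Number of Monte-Carlo replicates (>= 100).
#' @param seed Optional integer seed for the Monte-Carlo method.
#' @return A `ks_result` object: `d`, `p_value`, `method`, `n_obs`,
#'   `mc_replicates`, `seed`.
#' @export
ks_test <- function(dma, expected, method = c("asymptotic", "monte_carlo"),
                    mc_replicates = 2000L, seed = NULL) {
  method <- match.arg(method)
  d <- ks_distance(dma, expected)
  n_obs <- length(as.numeric(dma))
  if (method == "asymptotic") {
    p_value <- .ks_asymptotic_p(d, n_obs)
    mc_replicates <- NA_integer_
    seed <- NA_integer_
  } else {
    mc_replicates <- as.integer(mc_replicates)
    if (mc_replicates < 100L) {
      stop("mc_replicates must be at least 100 for a stable p-value", call. = FALSE)
    }
    n_rallies <- if (inherits(dma, "dma_series")) attr(dma, "n_rallies") else n_obs + 6L
    if (!is.null(seed)) set.seed(seed)
    d_null <- .ks_null_distances(expected$p, n_rallies, mc_replicates)
    p_value <- mean(d_null >= d)
    seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  }
  structure(list(d = d, p_value = p_value, method = method, n_obs = n_obs,
                 mc_replicates = mc_replicates, seed = seed),
            class = "ks_result")
}

#' @export
as.data.frame.ks_result <- function(x, ...) {
  data.frame(d = x$d, p_value = x$p_value, method = x$method, n_obs = x$n_obs,
             mc_replicates = x$mc_replicates, seed = x$seed)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> d = %.4f, p = %.4f (%s, n = %d)\n",
              x$d, x$p_value, x$method, x$n_obs))
  invisible(x)
}
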