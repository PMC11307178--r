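#' Generate an independent-rallies (iid Bernoulli) outcome sequence
#'
#' The null model of every test in this package: each rally is won
#' independently with the same probability p.
#'
#' @param p Winning probability in \[0, 1\].
#' @param n Number of rallies.
#' @param seed Optional integer seed for reproducibility.
#' @param perspective Passed to [rally_series()].
#' @return A [rally_series()] of n outcomes.
#' @export
generate_iid <- function(p, n, seed = NULL, perspective = "simulated") {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rally_series(stats::rbinom(n, 1L, p), perspective = perspective)
}

#' Generate an autocorrelated ("streaky") rally sequence
#'
#' A stationary two-state Markov chain with marginal winning probability p
#' and lag-1 autocorrelation rho, operationalising streakiness: a positive
#' rho makes a win more likely after a win. Transition probabilities are
#' `P(1|1) = p + rho (1 - p)` and `P(1|0) = p (1 - rho)`; rho = 0 recovers
#' the independent model exactly. The initial state is drawn from the
#' stationary law, so the marginal is p at every rally.
#'
#' Valid rho range: both transition probabilities must lie in \[0, 1\], i.e.
#' `rho > -min(p / (1 - p), (1 - p) / p)` and `rho <= 1`.
#'
#' @param p Stationary winning probability in (0, 1).
#' @param rho Lag-1 autocorrelation.
#' @param n Number of rallies.
#' @param seed Optional integer seed.
#' @param perspective Passed to [rally_series()].
#' @return A [rally_series()] of n outcomes.
#' @export
generate_markov <- function(p, rho, n, seed = NULL, perspective = "simulated") {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1, n >= 1)
  p11 <- p + rho * (1 - p)
  p10 <- p * (1 - rho)
  if (p11 < 0 || p11 > 1 || p10 < 0 || p10 > 1) {
    stop(sprintf("invalid (p, rho) = (%g, %g): transition probabilities P(1|1) = %g, P(1|0) = %g outside [0, 1]",
                 p, rho, p11, p10), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  x <- integer(n)
  x[1L] <- as.integer(u[1L] < p)
  for (i in seq_len(n - 1L)) {
    thr <- if (x[i] == 1L) p11 else p10
    x[i + 1L] <- as.integer(u[i + 1L] < thr)
  }
  rally_series(x, perspective = perspective)
}

#' Generate a regime-switching rally sequence
#'
#' Concatenates independent Bernoulli blocks with per-phase winning
#' probabilities, emulating advantageous, stalemate and disadvantageous
#' periods within a match. Used for power analysis: strong regime switching
#' flattens the DMA distribution (kurtosis below the independent-model null).
#'
#' @param phases A list of `c(p, length)` pairs (or a 2-column matrix with
#'   columns p and length): winning probability and number of rallies of each
#'   phase.
#' @param seed Optional integer seed.
#' @param perspective Passed to [rally_series()].
#' @return A [rally_series()] of `sum(lengths)` outcomes.
#' @examples
#' s <- generate_regimes(list(c(0.8, 25), c(0.2, 25), c(0.8, 25), c(0.2, 25)),
#'                       seed = 1)
#' @export
generate_regimes <- function(phases, seed = NULL, perspective = "simulated") {
  if (is.matrix(phases)) phases <- asplit(phases, 1L)
  if (!length(phases)) stop("need at least one phase", call. = FALSE)
  ps <- vapply(phases, function(ph) as.numeric(ph[[1L]]), numeric(1))
  ls <- vapply(phases, function(ph) as.integer(ph[[2L]]), integer(1))
  stopifnot(all(ps >= 0 & ps <= 1), all(ls >= 1L))
  if (!is.null(seed)) set.seed(seed)
  x <- unlist(mapply(function(p, l) stats::rbinom(l, 1L, p), ps, ls,
                     SIMPLIFY = FALSE))
  rally_series(x, perspective = perspective)
}
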