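#' Sample excess kurtosis
#'
#' Excess kurtosis measures the peakedness of a distribution relative to the
#' normal law (0 for normal data). For a DMA distribution, high kurtosis
#' means many rallies spent near the average strength (a stable match), while
#' low or negative kurtosis means a flat or multi-modal distribution, i.e.
#' large within-match fluctuations.
#'
#' Two variants are provided and must be used consistently between an
#' observed match and its simulated null:
#' * `"adjusted"` (default): the bias-adjusted sample statistic
#'   `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))`, the common default of major
#'   statistics packages;
#' * `"moment"`: the plain moment ratio `g2 = m4 / m2^2 - 3`.
#'
#' @param values Numeric vector, at least 4 values with nonzero variance.
#' @param type `"adjusted"` or `"moment"`.
#' @return Excess kurtosis (a single number).
#' @export
sample_kurtosis <- function(values, type = c("adjusted", "moment")) {
  type <- match.arg(type)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4L) stop("kurtosis needs at least 4 values", call. = FALSE)
  c_ <- x - mean(x)
  m2 <- sum(c_^2) / n
  if (m2 == 0) stop("kurtosis undefined for a constant sample", call. = FALSE)
  g2 <- sum(c_^4) / n / m2^2 - 3
  if (type == "moment") g2
  else ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Monte-Carlo null distribution of DMA kurtosis
#'
#' Builds the null distribution of the DMA kurtosis for a match with a given
#' overall point-winning probability: a long stream of `total_draws`
#' independent Bernoulli(p) rally outcomes is generated, its DMA is computed
#' once, and the valid DMA values (total_draws - 6 of them) are cut into
#' consecutive non-overlapping "Monte Carlo matches" of `segment_length`
#' values each (the trailing remainder is discarded). The excess kurtosis of
#' each segment yields the null distribution, summarised by its mean and
#' standard deviation for the z-test of [kurtosis_z_test()].
#'
#' For the observed and simulated kurtoses to be exchangeable under the null,
#' `segment_length` should equal the match's number of valid DMA values
#' (n - 6 for an n-rally match); [kurtosis_z_test()] and [analyze_matches()]
#' do this. With the conventional `total_draws = 1e6` and segments of 100 DMA
#' values this yields 9999 Monte Carlo matches.
#'
#' Segments with zero variance (possible at extreme p) are dropped and
#' counted; if more than 1% of segments are dropped the run aborts, since the
#' normal approximation for the z-test is then suspect.
#'
#' @param p Overall point-winning probability, strictly between 0 and 1.
#' @param segment_length Number of DMA values per Monte Carlo match (>= 14,
#'   i.e. a match of at least 20 rallies).
#' @param total_draws Length of the simulated rally stream (default 1e6; must
#'   be at least 100 * segment_length).
#' @param seed Optional integer seed; with a fixed seed the null is
#'   bit-reproducible.
#' @param type Kurtosis variant, see [sample_kurtosis()].
#' @return A `kurtosis_null` object: `null_mean`, `null_sd`, `n_segments`,
#'   `segment_length`, `p`, `total_draws`, `n_dropped`, `seed`, `type`.
#' @export
simulate_kurtosis_null <- function(p, segment_length, total_draws = 1e6,
                                   seed = NULL, type = c("adjusted", "moment")) {
  type <- match.arg(type)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("p must be strictly between 0 and 1 (kurtosis is undefined for a constant stream)",
         call. = FALSE)
  }
  segment_length <- as.integer(segment_length)
  if (segment_length < 14L) {
    stop("segment_length must be at least 14 DMA values (a match of >= 20 rallies)",
         call. = FALSE)
  }
  total_draws <- as.integer(total_draws)
  if (total_draws < 100L * segment_length) {
    stop("total_draws must be at least 100 * segment_length", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(stats::runif(total_draws) < p)
  f <- stats::filter(x, .dma_kernel, method = "convolution", sides = 2)
  dma <- as.numeric(f[4:(total_draws - 3L)]) / 16
  n_segments <- (total_draws - 6L) %/% segment_length
  mat <- matrix(dma[seq_len(n_segments * segment_length)], nrow = segment_length)
  # vectorised per-segment excess kurtosis
  mu <- colMeans(mat)
  ctr <- mat - rep(mu, each = segment_length)
  m2 <- colMeans(ctr^2)
  ok <- m2 > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0.01 * n_segments) {
    stop(sprintf("%d of %d simulated segments have zero variance; p = %g is too extreme for the normal z-approximation",
                 n_dropped, n_segments, p), call. = FALSE)
  }
  g2 <- colMeans(ctr^4)[ok] / m2[ok]^2 - 3
  if (type == "adjusted") {
    ns <- segment_length
    g2 <- ((ns + 1) * g2 + 6) * (ns - 1) / ((ns - 2) * (ns - 3))
  }
  structure(list(null_mean = mean(g2),
                 null_sd = stats::sd(g2),
                 n_segments = n_segments - n_dropped,
                 segment_length = segment_length,
                 p = p,
                 total_draws = total_draws,
                 n_dropped = n_dropped,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 type = type),
            class = "kurtosis_null")
}

#' @export
print.kurtosis_null <- function(x, ...) {
  cat(sprintf("<kurtosis_null> p = %.4f, %d segments of %d DMA values (%d dropped)\n  null mean %.4f, sd %.4f (%s kurtosis)\n",
              x$p, x$n_segments, x$segment_length, x$n_dropped,
              x$null_mean, x$null_sd, x$type))
  invisible(x)
}

#' z-test of a match's DMA kurtosis against its Monte-Carlo null
#'
#' Compares the observed excess kurtosis of a match's DMA values with the
#' simulated null of [simulate_kurtosis_null()]:
#' `z = (observed - null_mean) / null_sd`, with two-sided p-value
#' `2 (1 - Phi(|z|))`. A significant low kurtosis means larger-than-expected
#' within-match fluctuation; a significant high kurtosis means
#' steadier-than-expected play.
#'
#' @param dma A `dma_series` of the match. The null must have been built with
#'   `segment_length` equal to this series' number of valid values and with
#'   the match's own winning probability.
#' @param null A [simulate_kurtosis_null()] result.
#' @return A `kurtosis_test` object: `observed_kurtosis`, `z`, `p_two_sided`,
#'   `significant_at_05`, and the `null`.
#' @export
kurtosis_z_test <- function(dma, null) {
  stopifnot(inherits(null, "kurtosis_null"))
  if (null$null_sd == 0) stop("degenerate null: null_sd is zero", call. = FALSE)
  obs <- sample_kurtosis(as.numeric(dma), type = null$type)
  z <- (obs - null$null_mean) / null$null_sd
  p <- 2 * (1 - stats::pnorm(abs(z)))
  structure(list(observed_kurtosis = obs, z = z, p_two_sided = p,
                 significant_at_05 = p < 0.05, null = null),
            class = "kurtosis_test")
}

#' @export
as.data.frame.kurtosis_test <- function(x, ...) {
  data.frame(observed_kurtosis = x$observed_kurtosis,
             null_mean = x$null$null_mean, null_sd = x$null$null_sd,
             n_segments = x$null$n_segments, p = x$null$p,
             z = x$z, p_two_sided = x$p_two_sided,
             significant_at_05 = x$significant_at_05,
             seed = x$null$seed)
}

#' @export
print.kurtosis_test <- function(x, ...) {
  cat(sprintf("<kurtosis_test> observed %.4f vs null %.4f (sd %.4f): z = %.3f, p = %.4f%s\n",
              x$observed_kurtosis, x$null$null_mean, x$null$null_sd, x$z,
              x$p_two_sided, if (x$significant_at_05) " *" else ""))
  invisible(x)
}
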