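# DMA kernel for window 4: weights of the 7 rallies centred on rally i,
# divisor 16. Values are exact binary fractions (k/16), so doubles are exact.
.dma_kernel <- c(1, 2, 3, 4, 3, 2, 1)

#' Simple moving average of a rally series
#'
#' Backward-looking simple moving average: the value at rally i (for i from
#' `window` to n) is the mean of outcomes i-window+1, ..., i. This is the
#' first, forward-direction smoothing pass of the double moving average.
#'
#' @param series A [rally_series()] object (or plain 0/1 vector).
#' @param window Window length N (default 4 rallies).
#' @return A `ma_series` object: numeric vector of n - window + 1 values,
#'   each an exact multiple of 1/window, with attributes `window` and
#'   `first_valid_index` (= window).
#' @export
moving_average <- function(series, window = 4L) {
  x <- as.integer(series)
  n <- length(x)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (n < window) {
    stop(sprintf("need at least %d rallies for a window-%d moving average, got %d",
                 window, window, n), call. = FALSE)
  }
  sums <- if (window == 1L) x else as.numeric(rowSums(embed(x, window)))
  structure(sums / window,
            window = window,
            first_valid_index = window,
            class = "ma_series")
}

#' Double moving average (DMA): momentary point-winning strength
#'
#' The DMA smooths the 0/1 rally sequence twice with window-4 moving
#' averages: a forward pass (the backward-looking MA of [moving_average()])
#' followed by a backward pass, `DMA_i = (M_i + M_{i+1} + M_{i+2} + M_{i+3}) / 4`.
#' The two passes centre the statistic on rally i, so the DMA tracks the
#' momentary point-winning probability without lagging the match. Under the
#' default `"valid"` edge policy the DMA is defined exactly where all seven
#' surrounding rallies exist, i.e. for i in 4..(n-3); every value is then an
#' exact multiple of 1/16. The `"shrink"` policy instead shortens the windows
#' near the edges so a value exists at every rally; it is provided for
#' exploratory plots only.
#'
#' @param series A [rally_series()] object (or plain 0/1 vector).
#' @param window MA window (default 4; the distributional results of this
#'   package — the 17-point support and the expected distribution — are
#'   specific to window 4).
#' @param edge_policy `"valid"` (default) or `"shrink"`.
#' @return A `dma_series` object: numeric vector with attributes `window`,
#'   `edge_policy`, `first_valid_index`, `last_valid_index` and `n_rallies`.
#' @seealso [dma_weighted()] for the equivalent one-pass weighted form.
#' @examples
#' s <- rally_series(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1))
#' double_moving_average(s)
#' @export
double_moving_average <- function(series, window = 4L, edge_policy = c("valid", "shrink")) {
  edge_policy <- match.arg(edge_policy)
  x <- as.integer(series)
  n <- length(x)
  window <- as.integer(window)
  if (edge_policy == "valid") {
    if (n < 2L * window - 1L) {
      stop(sprintf("need at least %d rallies for a window-%d DMA, got %d",
                   2L * window - 1L, window, n), call. = FALSE)
    }
    m <- as.numeric(moving_average(x, window))
    # backward pass: DMA_i = mean(M_i .. M_{i+window-1}); embed() reverses
    # row order but the mean is order-free
    vals <- as.numeric(rowSums(embed(m, window))) / window
    first <- window
  } else {
    # shrink: truncate each window at the series boundary
    m <- vapply(seq_len(n), function(i) mean(x[max(1L, i - window + 1L):i]),
                numeric(1))
    vals <- vapply(seq_len(n), function(i) mean(m[i:min(n, i + window - 1L)]),
                   numeric(1))
    first <- 1L
  }
  structure(vals,
            window = window,
            edge_policy = edge_policy,
            first_valid_index = first,
            last_valid_index = first + length(vals) - 1L,
            n_rallies = n,
            class = "dma_series")
}

#' DMA as a weighted sum of seven consecutive rallies
#'
#' The window-4 DMA is algebraically a symmetric weighted sum of seven
#' consecutive rally outcomes:
#' `DMA_i = (x_{i-3} + 2 x_{i-2} + 3 x_{i-1} + 4 x_i + 3 x_{i+1} + 2 x_{i+2} + x_{i+3}) / 16`,
#' for i in 4..(n-3). This one-pass form is exactly equal to
#' [double_moving_average()] with window 4 and the `"valid"` edge policy and
#' makes the 17-value support (k/16, k = 0..16) evident.
#'
#' @inheritParams double_moving_average
#' @return A `dma_series` object, identical to
#'   `double_moving_average(series, 4)`.
#' @export
dma_weighted <- function(series) {
  x <- as.integer(series)
  n <- length(x)
  if (n < 7L) {
    stop(sprintf("need at least 7 rallies for the weighted DMA, got %d", n),
         call. = FALSE)
  }
  vals <- as.numeric(embed(x, 7L) %*% .dma_kernel) / 16
  structure(vals,
            window = 4L,
            edge_policy = "valid",
            first_valid_index = 4L,
            last_valid_index = n - 3L,
            n_rallies = n,
            class = "dma_series")
}

#' @export
print.dma_series <- function(x, ...) {
  cat(sprintf("<dma_series> %d values (window %d, rallies %d..%d of %d, %s edges)\n",
              length(x), attr(x, "window"), attr(x, "first_valid_index"),
              attr(x, "last_valid_index"), attr(x, "n_rallies"),
              attr(x, "edge_policy")))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Plot the DMA course of a match
#'
#' Line chart of momentary strength across rallies, with the overall winning
#' probability as a dashed reference line.
#'
#' @param x A `dma_series` object.
#' @param series Optional originating [rally_series()]; when given, rally
#'   outcomes are drawn as points and the overall winning probability as a
#'   dashed line.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.dma_series <- function(x, series = NULL, ...) {
  idx <- seq(attr(x, "first_valid_index"), attr(x, "last_valid_index"))
  plot(idx, as.numeric(x), type = "l", ylim = c(0, 1),
       xlab = "rally", ylab = "DMA (momentary strength)", ...)
  if (!is.null(series)) {
    graphics::points(seq_along(series), as.integer(series), pch = 3, cex = 0.4)
    graphics::abline(h = mean(as.integer(series)), lty = 2)
  }
  invisible(x)
}

#' Per-match descriptive fluctuation statistics
#'
#' Summarises the within-match fluctuation of a DMA series: mean, standard
#' deviation, interquartile range and coefficient of variation of the valid
#' DMA values, whether the series touched the boundaries 1 (a streak of at
#' least seven straight wins) or 0 (seven straight losses), and the match's
#' overall winning probability wp = wins / n.
#'
#' Quartiles use linear interpolation of the empirical distribution
#' ([stats::quantile()] type 7), the common statistics-package default; the
#' convention is fixed here so IQR values are reproducible.
#'
#' @param dma A `dma_series` computed from `series`.
#' @param series The originating [rally_series()].
#' @return A `fluct_summary` object (named list): `mean_dma`, `sd_dma`,
#'   `iqr_dma`, `cv_dma`, `touched_upper`, `touched_lower`, `n_valid`, `wp`.
#' @export
summarize_fluctuation <- function(dma, series) {
  v <- as.numeric(dma)
  x <- as.integer(series)
  m <- mean(v)
  s <- stats::sd(v)
  if (length(v) == 1L) s <- 0  # a single DMA value shows no dispersion
  structure(list(
    mean_dma = m,
    sd_dma = s,
    iqr_dma = stats::IQR(v, type = 7),
    cv_dma = if (m > 0) s / m else NA_real_,
    touched_upper = max(v) == 1,
    touched_lower = min(v) == 0,
    n_valid = length(v),
    wp = sum(x) / length(x)
  ), class = "fluct_summary")
}

#' @export
as.data.frame.fluct_summary <- function(x, ...) {
  data.frame(mean_dma = x$mean_dma, sd_dma = x$sd_dma, iqr_dma = x$iqr_dma,
             cv_dma = x$cv_dma, touched_upper = x$touched_upper,
             touched_lower = x$touched_lower, n_valid = x$n_valid, wp = x$wp)
}

#' @export
print.fluct_summary <- function(x, ...) {
  cat(sprintf(paste0("<fluct_summary> mean %.4f, sd %.4f, IQR %.4f, CV %.4f\n",
                     "  touched 1: %s, touched 0: %s, %d DMA values, wp %.4f\n"),
              x$mean_dma, x$sd_dma, x$iqr_dma, x$cv_dma,
              x$touched_upper, x$touched_lower, x$n_valid, x$wp))
  invisible(x)
}
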