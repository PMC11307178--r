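#' Enumerate all binary outcome sequences of a given length
#'
#' Exhaustive enumeration of every win/loss sequence, in lexicographic order
#' (all-zeros first, rightmost rally varying fastest). Used to derive the
#' exact DMA distribution; guarded at length 24 (2^24 rows) to keep memory
#' bounded.
#'
#' @param length Sequence length (default 7, one full DMA window).
#' @return Integer matrix with 2^length rows and `length` columns of 0/1.
#' @examples
#' nrow(enumerate_sequences(7))  # 128
#' @export
enumerate_sequences <- function(length = 7L) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be at least 1", call. = FALSE)
  if (length > 24L) {
    stop("refusing to enumerate 2^length sequences for length > 24", call. = FALSE)
  }
  g <- expand.grid(rep(list(0:1), length), KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; reverse the columns so the
  # rightmost position varies fastest, i.e. lexicographic order
  m <- as.matrix(g[, length:1, drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Exact expected DMA distribution under independent rallies
#'
#' Under the independent-rallies model every rally is a Bernoulli(p) trial,
#' so each of the 128 possible 7-rally windows has probability
#' p^k (1-p)^(7-k), where k is its number of wins. Each window maps to one of
#' the 17 attainable DMA values k/16 (k = 0..16) through the weighted kernel
#' (1,2,3,4,3,2,1)/16; accumulating the window probabilities per DMA value
#' gives the exact distribution of a single DMA value. Support points that
#' receive zero probability (possible only at p = 0 or 1) are retained so
#' every distribution lives on the same 17-point grid.
#'
#' The mean of this distribution is exactly p (the DMA is a convex
#' combination of Bernoulli(p) variables), and the distributions at p and
#' 1 - p are mirror images.
#'
#' @param p Overall point-winning probability in \[0, 1\].
#' @return An `expected_dma_dist` object: list with `support` (the 17 values
#'   0, 1/16, ..., 1), `probabilities` (summing to 1) and `p`.
#' @examples
#' d <- expected_dma_distribution(0.5)
#' d$probabilities[1]  # P(DMA = 0) = 1/128
#' @export
expected_dma_distribution <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  seqs <- enumerate_sequences(7L)
  k_wins <- rowSums(seqs)
  dma_num <- as.integer(seqs %*% .dma_kernel)  # 16 * DMA, in 0..16
  prob_seq <- p^k_wins * (1 - p)^(7 - k_wins)  # 0^0 = 1 covers p in {0, 1}
  probs <- vapply(0:16, function(k) sum(prob_seq[dma_num == k]), numeric(1))
  structure(list(support = (0:16) / 16, probabilities = probs, p = p),
            class = "expected_dma_dist")
}

#' Cumulative distribution of an expected DMA distribution
#'
#' @param dist An [expected_dma_distribution()] object.
#' @return Numeric vector of cumulative probabilities over the 17-point
#'   support (nondecreasing, last value 1).
#' @export
expected_cdf <- function(dist) {
  stopifnot(inherits(dist, "expected_dma_dist"))
  cumsum(dist$probabilities)
}

#' @export
print.expected_dma_dist <- function(x, ...) {
  cat(sprintf("<expected_dma_dist> p = %.4f, 17-point support, mean = %.4f\n",
              x$p, sum(x$support * x$probabilities)))
  print(data.frame(dma = x$support, probability = x$probabilities), ...)
  invisible(x)
}

#' @export
as.data.frame.expected_dma_dist <- function(x, ...) {
  data.frame(dma_value = x$support, probability = x$probabilities, p = x$p)
}

#' Plot an expected DMA distribution as a column diagram
#'
#' @param x An `expected_dma_dist` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.expected_dma_dist <- function(x, ...) {
  graphics::barplot(x$probabilities, names.arg = format(x$support),
                    xlab = "DMA", ylab = "probability",
                    main = sprintf("Expected DMA distribution, p = %.3f", x$p),
                    ...)
  invisible(x)
}
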