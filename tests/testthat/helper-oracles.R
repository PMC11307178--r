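# Independent brute-force oracles, written with plain loops so they share no
# code path with the package implementation.

# MA/DMA by literal two-pass composition over explicit index ranges
oracle_dma <- function(x, window = 4L) {
  n <- length(x)
  ma <- vapply(window:n, function(i) mean(x[(i - window + 1L):i]), numeric(1))
  m_at <- function(i) ma[i - window + 1L]  # ma indexed by rally
  vapply(window:(n - window + 1L), function(i) {
    mean(vapply(i:(i + window - 1L), m_at, numeric(1)))
  }, numeric(1))
}

# All length-7 binary sequences by bit extraction (most-significant bit first)
oracle_sequences7 <- function() {
  t(vapply(0:127, function(v) as.integer(intToBits(v))[7:1], integer(7)))
}

# Exact DMA distribution at p by direct enumeration, returned on the 0:16 grid
oracle_expected_probs <- function(p) {
  seqs <- oracle_sequences7()
  probs <- numeric(17)
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    k <- sum(s)
    num <- s[1] + 2 * s[2] + 3 * s[3] + 4 * s[4] + 3 * s[5] + 2 * s[6] + s[7]
    probs[num + 1L] <- probs[num + 1L] + p^k * (1 - p)^(7 - k)
  }
  probs
}

random_rally_series <- function(n, p = 0.5) {
  rally_series(as.integer(runif(n) < p))
}

# A random valid table tennis set score (winner's points, loser's points)
random_valid_set <- function() {
  if (runif(1) < 0.7) c(11L, sample(0:9, 1L)) else {
    w <- sample(12:20, 1L); c(w, w - 2L)
  }
}

make_sets <- function(scores, won) {
  lapply(seq_along(scores), function(i) {
    ss <- set_score(scores[[i]][1], scores[[i]][2])
    attr(ss, "won_by_focal") <- won[i]
    ss
  })
}
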