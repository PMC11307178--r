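test_that("enumeration is exhaustive, distinct and lexicographic", {
  m1 <- enumerate_sequences(1)
  expect_equal(dim(m1), c(2L, 1L))
  expect_equal(m1[, 1], 0:1)

  m3 <- enumerate_sequences(3)
  expect_equal(nrow(m3), 8L)
  # lexicographic: rows read as binary numbers are 0..7
  expect_equal(as.integer(m3 %*% c(4, 2, 1)), 0:7)

  m7 <- enumerate_sequences(7)
  expect_equal(nrow(m7), 128L)
  expect_equal(nrow(unique(m7)), 128L)

  expect_error(enumerate_sequences(0), "at least 1")
  expect_error(enumerate_sequences(25), "length > 24")
})

test_that("degenerate probabilities give point masses at the boundaries", {
  d1 <- expected_dma_distribution(1)
  expect_equal(d1$probabilities, c(rep(0, 16), 1))
  d0 <- expected_dma_distribution(0)
  expect_equal(d0$probabilities, c(1, rep(0, 16)))
  expect_error(expected_dma_distribution(1.2), "in \\[0, 1\\]")
  expect_error(expected_dma_distribution(-0.1), "in \\[0, 1\\]")
})

test_that("the p = 0.5 distribution is symmetric with P(DMA = 0) = 1/128", {
  d <- expected_dma_distribution(0.5)
  expect_equal(d$probabilities[1], 1 / 128)
  expect_equal(d$probabilities[17], 1 / 128)
  expect_equal(d$probabilities, rev(d$probabilities))
  expect_equal(sum(d$support * d$probabilities), 0.5)
})

test_that("enumeration distribution matches the independent bit-loop oracle", {
  for (p in c(0.3, 0.5, 0.7, 0.577)) {
    d <- expected_dma_distribution(p)
    expect_equal(d$probabilities, oracle_expected_probs(p), tolerance = 1e-14)
  }
  # p = 0.7 is right-shifted: more mass above 0.5 than below
  d7 <- expected_dma_distribution(0.7)
  expect_gt(sum(d7$probabilities[d7$support > 0.5]),
            sum(d7$probabilities[d7$support < 0.5]))
})

test_that("normalization and mean identity hold across random p", {
  set.seed(33)
  for (p in runif(100)) {
    d <- expected_dma_distribution(p)
    expect_lt(abs(sum(d$probabilities) - 1), 1e-12)
    expect_lt(abs(sum(d$support * d$probabilities) - p), 1e-12)
    expect_true(all(d$probabilities >= 0))
  }
})

test_that("distributions at p and 1 - p are mirror images", {
  set.seed(34)
  for (p in runif(20)) {
    a <- expected_dma_distribution(p)$probabilities
    b <- expected_dma_distribution(1 - p)$probabilities
    expect_equal(a, rev(b), tolerance = 1e-14)
  }
})

test_that("support is exactly the 17 sixteenths and is always retained", {
  d <- expected_dma_distribution(0.42)
  expect_length(d$support, 17L)
  expect_identical(d$support, (0:16) / 16)
  expect_length(expected_dma_distribution(1)$probabilities, 17L)
})

test_that("expected CDF is a proper nondecreasing CDF with known values", {
  d <- expected_dma_distribution(0.5)
  cdf <- expected_cdf(d)
  expect_true(all(diff(cdf) >= 0))
  expect_lt(abs(cdf[17] - 1), 1e-12)
  # by symmetry at p = 0.5: P(DMA <= 0.5) = (1 + P(DMA = 0.5)) / 2
  expect_equal(cdf[9], (1 + d$probabilities[9]) / 2, tolerance = 1e-14)
  # oracle value: count sequences with weighted sum <= 8 over 128
  seqs <- oracle_sequences7()
  nums <- as.integer(seqs %*% c(1, 2, 3, 4, 3, 2, 1))
  expect_equal(cdf[9], sum(nums <= 8) / 128, tolerance = 1e-14)

  cdf1 <- expected_cdf(expected_dma_distribution(1))
  expect_equal(cdf1, c(rep(0, 16), 1))
})

test_that("a long simulated iid stream reproduces the exact distribution", {
  p <- 0.577
  n <- 1e6
  s <- generate_iid(p, n, seed = 404)
  k <- round(16 * as.numeric(dma_weighted(s)))
  emp <- tabulate(k + 1L, 17L) / length(k)
  exact <- expected_dma_distribution(p)$probabilities
  # overlapping DMA windows are serially dependent, which inflates the
  # variance of the empirical frequencies relative to iid sampling; the
  # binomial SE is used as the scale with a dependence-aware factor
  se <- sqrt(exact * (1 - exact) / length(k))
  expect_true(all(abs(emp - exact) <= 3 * pmax(se, 1e-6) * sqrt(7)))
})
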