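test_that("moving average matches hand-computed means and refuses short input", {
  expect_equal(as.numeric(moving_average(rally_series(rep(1, 7)))), rep(1, 4))
  expect_equal(as.numeric(moving_average(rally_series(c(1, 0, 1, 0, 1)))),
               c(0.5, 0.5))
  ma <- moving_average(rally_series(c(1, 1, 0, 0, 0)))
  expect_equal(as.numeric(ma), c(0.5, 0.25))
  expect_identical(attr(ma, "first_valid_index"), 4L)
  expect_error(moving_average(rally_series(c(1, 0))), "at least 4")
})

test_that("DMA at rally 4 equals the 7-term weighted kernel for all 128 windows", {
  seqs <- oracle_sequences7()
  for (r in seq_len(nrow(seqs))) {
    x <- seqs[r, ]
    got <- double_moving_average(rally_series(x))
    want <- (x[1] + 2 * x[2] + 3 * x[3] + 4 * x[4] + 3 * x[5] + 2 * x[6] + x[7]) / 16
    expect_length(got, 1L)
    expect_identical(as.numeric(got), want)
  }
})

test_that("DMA series carries the valid index range and handles short series", {
  s <- rally_series(rep(1, 7))
  d <- double_moving_average(s)
  expect_identical(as.numeric(d), 1)
  expect_identical(attr(d, "first_valid_index"), 4L)
  expect_identical(attr(d, "last_valid_index"), 4L)
  expect_error(double_moving_average(rally_series(rep(1, 6))), "at least 7")
  expect_error(dma_weighted(rally_series(rep(0, 6))), "at least 7")

  d12 <- double_moving_average(rally_series(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1)))
  expect_length(d12, 6L)
  expect_equal(as.numeric(d12), oracle_dma(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1)))
})

test_that("weighted form, two-pass composition and brute-force oracle agree exactly", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(7:200, 1L)
    x <- as.integer(runif(n) < runif(1))
    a <- double_moving_average(rally_series(x))
    b <- dma_weighted(rally_series(x))
    # exact rational equality: all values are multiples of 1/16, so the
    # doubles must be bit-identical
    expect_identical(as.numeric(a), as.numeric(b))
    if (i <= 50) expect_identical(as.numeric(a), oracle_dma(x))
  }
})

test_that("every DMA value lies on the k/16 grid", {
  set.seed(5)
  for (i in 1:50) {
    x <- random_rally_series(sample(7:150, 1L), runif(1))
    k <- 16 * as.numeric(double_moving_average(x))
    expect_identical(k, round(k))
    expect_true(all(k >= 0 & k <= 16))
  }
})

test_that("complementing the outcomes mirrors the DMA about 0.5", {
  set.seed(17)
  for (i in 1:25) {
    x <- as.integer(runif(sample(7:100, 1L)) < 0.6)
    d <- as.numeric(double_moving_average(rally_series(x)))
    dc <- as.numeric(double_moving_average(rally_series(1L - x)))
    expect_identical(dc, 1 - d)
  }
})

test_that("mean DMA of a long iid series converges to p", {
  p <- 0.577
  n <- 1e5
  s <- generate_iid(p, n, seed = 202)
  m <- mean(as.numeric(double_moving_average(s)))
  expect_lt(abs(m - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("fluctuation summary reports dispersion, boundary touches and wp", {
  s <- rally_series(rep(1, 10))
  d <- double_moving_average(s)
  sm <- summarize_fluctuation(d, s)
  expect_identical(sm$sd_dma, 0)
  expect_identical(sm$iqr_dma, 0)
  expect_identical(sm$cv_dma, 0)
  expect_true(sm$touched_upper)
  expect_false(sm$touched_lower)
  expect_identical(sm$wp, 1)
  expect_identical(sm$n_valid, 4L)

  # IQR under type-7 linear interpolation: quartiles 0.4375 and 0.8125
  fake <- structure(c(0.25, 0.5, 0.75, 1.0), class = "dma_series",
                    n_rallies = 10L)
  sm2 <- summarize_fluctuation(fake, s)
  expect_equal(sm2$iqr_dma, 0.375)
})

test_that("shrink edge policy covers every rally and agrees in the interior", {
  x <- c(1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 1, 0)
  full <- double_moving_average(rally_series(x), edge_policy = "shrink")
  valid <- double_moving_average(rally_series(x))
  expect_length(full, length(x))
  expect_equal(as.numeric(full)[4:(length(x) - 3)], as.numeric(valid))
  expect_identical(as.numeric(full)[1], mean(c(x[1], mean(x[1:2]), mean(x[1:3]),
                                               mean(x[1:4]))))
})
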