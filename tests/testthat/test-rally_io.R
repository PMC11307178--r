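test_that("rally CSV round-trips exactly, including interleaved matches", {
  set.seed(11)
  r1 <- match_record("m1", random_rally_series(25))
  r2 <- match_record("m2", random_rally_series(40))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rally_csv(list(r1, r2), path)
  back <- read_rally_csv(path)
  expect_identical(as.integer(back$m1$rally_series), as.integer(r1$rally_series))
  expect_identical(as.integer(back$m2$rally_series), as.integer(r2$rally_series))

  # interleave the rows of the two matches; per-match order must be recovered
  df <- utils::read.csv(path)
  df <- df[order(df$rally_index, df$match_id), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- read_rally_csv(path2)
  expect_length(back2, 2L)
  expect_identical(as.integer(back2$m2$rally_series), as.integer(r2$rally_series))
})

test_that("reader rejects malformed rally data with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("match_id,rally_index,outcome", "m1,1,1", "m1,2,2"), path)
  expect_error(read_rally_csv(path), "non-binary outcome '2' at data row 2")

  writeLines(c("match_id,rally_index,outcome", "m1,1,1", "m1,1,0"), path)
  expect_error(read_rally_csv(path), "no gaps or duplicates")

  writeLines(c("match_id,rally_index,outcome", "m1,1,1", "m1,3,0"), path)
  expect_error(read_rally_csv(path), "no gaps or duplicates")

  writeLines("match_id,rally_index,outcome", path)
  expect_error(read_rally_csv(path), "no rally rows")
})

test_that("rally_series and match_record enforce their invariants", {
  expect_error(rally_series(integer(0)), "at least one rally")
  expect_error(rally_series(c(1, 0, 2)), "must be 0 or 1")
  s <- rally_series(rep(c(1, 0), 11))  # 22 rallies
  sets <- parse_scoreline("11:9")      # 20 points: mismatch
  expect_error(match_record("m", s, set_scores = sets), "22 rallies")
})

test_that("parse_scoreline handles the in-paper 4-3 scoreline and separators", {
  sets <- parse_scoreline("12:10,7:11,7:11,5:11,13:11,11:4,11:8")
  expect_length(sets, 7L)
  won <- vapply(sets, attr, logical(1), "won_by_focal")
  expect_identical(which(won), c(1L, 5L, 6L, 7L))
  expect_identical(sets[[1]]$points_winner, 12L)
  expect_identical(sets[[5]]$points_loser, 11L)

  # dash separators and whitespace are equivalent
  sets2 <- parse_scoreline(" 12-10, 7–11 ")
  expect_identical(sets2[[1]]$points_winner, 12L)
  expect_false(attr(sets2[[2]], "won_by_focal"))

  expect_length(parse_scoreline("11:0"), 1L)
})

test_that("scoreline validation accepts exactly the valid set scores", {
  expect_error(parse_scoreline("11:10"), "set 1")
  expect_error(parse_scoreline("10:8"), "set 1")
  expect_error(parse_scoreline("11:0,12:9"), "set 2")
  expect_error(parse_scoreline("9:9"), "tied")

  set.seed(42)
  for (i in 1:50) {
    ws <- random_valid_set()
    txt <- sprintf("%d:%d", ws[1], ws[2])
    expect_length(parse_scoreline(txt), 1L)
    # corrupt it: shift the loser's points up past validity
    bad_l <- if (ws[1] == 11L) 10L else ws[2] + 1L
    expect_error(parse_scoreline(sprintf("%d:%d", ws[1], bad_l)))
  }
})

test_that("results tables round-trip and reject mixed types", {
  set.seed(7)
  summaries <- lapply(1:2, function(i) {
    s <- random_rally_series(30)
    summarize_fluctuation(double_moving_average(s), s)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(summaries, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$sd_dma, vapply(summaries, `[[`, numeric(1), "sd_dma"))

  jpath <- withr::local_tempfile(fileext = ".json")
  write_results_table(summaries, jpath, format = "json")
  jback <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(jback$wp, vapply(summaries, `[[`, numeric(1), "wp"))

  write_results_table(list(), path)
  expect_lte(length(readLines(path)), 1L)  # no data rows

  mixed <- c(summaries[1], list(structure(list(), class = "other_thing")))
  expect_error(write_results_table(mixed, path), "same class")
})
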