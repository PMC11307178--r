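#' Construct a rally outcome series
#'
#' The raw input of every analysis in this package: the ordered sequence of
#' rally outcomes of one match, coded 1 when the focal player wins the rally
#' and 0 when they lose it.
#'
#' @param outcomes Integer or numeric vector of 0/1 rally outcomes, in rally
#'   order (rally indices are 1-based).
#' @param perspective Free-text label of the focal player whose wins are coded
#'   as 1 (for example the match winner's name).
#' @return An object of class `rally_series`: the 0/1 integer vector with
#'   attributes `n` (number of rallies) and `perspective`.
#' @examples
#' s <- rally_series(c(1, 0, 1, 1, 0, 1, 1), perspective = "winner")
#' length(s)
#' @export
rally_series <- function(outcomes, perspective = "") {
  if (length(outcomes) < 1L) {
    stop("a rally series needs at least one rally", call. = FALSE)
  }
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1))) {
    bad <- which(is.na(outcomes) | !(outcomes %in% c(0, 1)))[1L]
    stop(sprintf("rally outcomes must be 0 or 1; offending rally %d has value '%s'",
                 bad, as.character(outcomes[bad])), call. = FALSE)
  }
  structure(as.integer(outcomes),
            n = length(outcomes),
            perspective = as.character(perspective)[1L],
            class = "rally_series")
}

#' @export
print.rally_series <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("<rally_series> %d rallies, %d won (wp = %.3f)",
              n, sum(x), sum(x) / n))
  if (nzchar(attr(x, "perspective"))) {
    cat(sprintf(", perspective: %s", attr(x, "perspective")))
  }
  cat("\n")
  invisible(x)
}

#' Construct a validated set score
#'
#' A table tennis set is won at 11 points with the loser at 0 to 9, or beyond
#' 11 ("deuce") with a winning margin of exactly two points.
#'
#' @param points_winner Points scored by the set winner.
#' @param points_loser Points scored by the set loser.
#' @return A `set_score` object (named list with `points_winner`,
#'   `points_loser`).
#' @examples
#' set_score(11, 9)
#' set_score(13, 11)
#' @export
set_score <- function(points_winner, points_loser) {
  w <- as.integer(points_winner)
  l <- as.integer(points_loser)
  if (is.na(w) || is.na(l) || w < 11L) {
    stop(sprintf("invalid set score %s:%s (winner must reach at least 11)",
                 points_winner, points_loser), call. = FALSE)
  }
  if (w == 11L && !(l >= 0L && l <= 9L)) {
    stop(sprintf("invalid set score 11:%d (a set won 11-x requires x in 0..9)", l),
         call. = FALSE)
  }
  if (w > 11L && w - l != 2L) {
    stop(sprintf("invalid set score %d:%d (a deuce set is won by exactly two points)",
                 w, l), call. = FALSE)
  }
  structure(list(points_winner = w, points_loser = l), class = "set_score")
}

#' Construct a match record
#'
#' Bundles a rally series with optional set scores and free-form metadata.
#' When both rallies and set scores are present, their total point counts must
#' agree.
#'
#' @param match_id Free-text match identifier.
#' @param rally_series A [rally_series()] object.
#' @param set_scores Optional list as returned by [parse_scoreline()]: each
#'   element a `set_score` with a `won_by_focal` attribute.
#' @param metadata Optional named list (players, gender, rankings, ...).
#' @return A `match_record` object.
#' @export
match_record <- function(match_id, rally_series, set_scores = NULL,
                         metadata = list()) {
  stopifnot(inherits(rally_series, "rally_series"))
  if (!is.null(set_scores)) {
    pts <- sum(vapply(set_scores, function(s) s$points_winner + s$points_loser,
                      numeric(1)))
    if (pts != attr(rally_series, "n")) {
      stop(sprintf(paste0("set scores account for %d points but the rally series ",
                          "has %d rallies (match '%s')"),
                   pts, attr(rally_series, "n"), match_id), call. = FALSE)
    }
  }
  structure(list(match_id = as.character(match_id)[1L],
                 rally_series = rally_series,
                 set_scores = set_scores,
                 metadata = metadata),
            class = "match_record")
}

#' Read rally sequences from CSV
#'
#' Reads a rally-by-rally CSV (one row per rally) into a list of
#' [match_record()] objects, one per distinct match identifier. The default
#' column names are `match_id`, `rally_index`, `outcome`; third-party exports
#' can be ingested by remapping them through `columns`. Rally indices must be
#' exactly 1..n within each match (no gaps, no duplicates) and outcomes must
#' be 0 or 1.
#'
#' @param path Path to a CSV file with a header row.
#' @param columns Named list mapping the roles `match_id`, `rally_index` and
#'   `outcome` to column names in the file.
#' @return Named list of `match_record` objects, keyed and ordered by first
#'   appearance of each match id in the file.
#' @seealso [write_rally_csv()] for the inverse operation.
#' @export
read_rally_csv <- function(path,
                           columns = list(match_id = "match_id",
                                          rally_index = "rally_index",
                                          outcome = "outcome")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(columns[c("match_id", "rally_index", "outcome")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  mid <- as.character(df[[columns$match_id]])
  idx <- df[[columns$rally_index]]
  out <- df[[columns$outcome]]
  bad <- which(is.na(out) | !(out %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("non-binary outcome '%s' at data row %d of %s",
                 as.character(df[[columns$outcome]][bad[1L]]), bad[1L], path),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("no rally rows in %s", path), call. = FALSE)
  ids <- unique(mid)
  records <- lapply(ids, function(id) {
    sel <- mid == id
    i <- as.integer(idx[sel])
    if (anyNA(i) || anyDuplicated(i) || !setequal(i, seq_along(i))) {
      stop(sprintf("match '%s': rally indices must be exactly 1..%d with no gaps or duplicates",
                   id, sum(sel)), call. = FALSE)
    }
    o <- out[sel][order(i)]
    match_record(id, rally_series(o))
  })
  names(records) <- ids
  records
}

#' Write rally sequences to CSV
#'
#' Inverse of [read_rally_csv()]: writes one row per rally with columns
#' `match_id`, `rally_index` (1-based), `outcome`.
#'
#' @param records List of [match_record()] objects.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_rally_csv <- function(records, path) {
  stopifnot(length(records) >= 1L)
  rows <- lapply(records, function(r) {
    s <- r$rally_series
    data.frame(match_id = r$match_id,
               rally_index = seq_len(attr(s, "n")),
               outcome = as.integer(s),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a set scoreline string
#'
#' Parses a comma-separated scoreline such as
#' `"12:10,7:11,7:11,5:11,13:11,11:4,11:8"` from the focal player's
#' perspective (first number of each pair = focal player's points). Both `:`
#' and hyphen/en-dash separators are accepted and whitespace is ignored. Each
#' set must be a valid table tennis score: won at 11 with the loser on 0-9,
#' or won beyond 11 by exactly two points.
#'
#' @param text Scoreline string.
#' @return List of `set_score` objects, each carrying attribute
#'   `won_by_focal` (logical).
#' @examples
#' sets <- parse_scoreline("12:10,7:11,7:11,5:11,13:11,11:4,11:8")
#' sum(vapply(sets, attr, logical(1), "won_by_focal"))  # focal wins 4 sets
#' @export
parse_scoreline <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pairs <- strsplit(gsub("[[:space:]]", "", text), ",", fixed = TRUE)[[1L]]
  if (!length(pairs)) stop("empty scoreline", call. = FALSE)
  lapply(seq_along(pairs), function(i) {
    nums <- strsplit(pairs[i], "[:–—-]")[[1L]]
    if (length(nums) != 2L || anyNA(suppressWarnings(as.integer(nums)))) {
      stop(sprintf("set %d: cannot parse '%s' as a score pair", i, pairs[i]),
           call. = FALSE)
    }
    a <- as.integer(nums[1L]); b <- as.integer(nums[2L])
    if (a == b) stop(sprintf("set %d: tied score %d:%d is impossible", i, a, b),
                     call. = FALSE)
    ss <- tryCatch(set_score(max(a, b), min(a, b)),
                   error = function(e) stop(sprintf("set %d: %s", i,
                                                    conditionMessage(e)),
                                            call. = FALSE))
    attr(ss, "won_by_focal") <- a > b
    ss
  })
}

#' Write a homogeneous list of results to CSV or JSON
#'
#' Flattens a list of result objects of one type (fluctuation summaries, K-S
#' results, kurtosis test results, CP results, ...) into a table, one row per
#' result, with a stable column order and full floating precision, and writes
#' it to `path`.
#'
#' @param results List of result objects, all of the same class. Each class
#'   must have an `as.data.frame` method (all result classes in this package
#'   do). An empty list writes a file with no data rows.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (length(results) == 0L) {
    df <- data.frame()
  } else {
    classes <- vapply(results, function(r) class(r)[1L], character(1))
    if (length(unique(classes)) != 1L) {
      stop(sprintf("results must all have the same class; got: %s",
                   paste(unique(classes), collapse = ", ")), call. = FALSE)
    }
    rows <- lapply(results, as.data.frame)
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
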