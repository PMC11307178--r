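#' Per-set competition performance (SCP)
#'
#' Scores the dominance of one set on a 0-22 scale, symmetric between the two
#' players about 11. The set winner's value S is
#' * `S = 22 - points_loser` when the set is won at 11 (11-0 gives 22, 11-9
#'   gives 13), and
#' * a deuce decay for sets won beyond 11 with winner score w:
#'   * exponential variant (default): `S = 11 + 2 * 1.25^-(w - 11)`,
#'   * linear variant: `S = max(11, 13 - 1.25 * (w - 11))`.
#'
#' The focal player receives S if they won the set and 22 - S otherwise, so
#' the two players' values always sum to 22. Unlike the traditional
#' equal-margin score (see [set_cp_traditional()]), which rates 11-9, 12-10
#' and 13-11 identically, the deuce decay makes dominance strictly
#' decreasing over that sequence: 13 > 12.6 > 12.28 (exponential).
#'
#' @param set_score A [set_score()] object.
#' @param won_by_focal Did the focal player win this set?
#' @param variant `"exponential"` (default) or `"linear"`.
#' @return The focal player's per-set value in \[0, 22\].
#' @export
set_cp <- function(set_score, won_by_focal, variant = c("exponential", "linear")) {
  variant <- match.arg(variant)
  stopifnot(inherits(set_score, "set_score"), is.logical(won_by_focal))
  w <- set_score$points_winner
  s_winner <- if (w == 11L) {
    22 - set_score$points_loser
  } else if (variant == "exponential") {
    11 + 2 * 1.25^-(w - 11L)
  } else {
    max(11, 13 - 1.25 * (w - 11L))
  }
  if (won_by_focal) s_winner else 22 - s_winner
}

#' Traditional equal-margin per-set competition performance
#'
#' The baseline the improved score corrects: the focal player's value is
#' 11 plus the signed point margin of the set, so all two-point sets (11-9,
#' 12-10, 13-11, ...) score identically.
#'
#' @inheritParams set_cp
#' @return The focal player's per-set value in \[0, 22\].
#' @export
set_cp_traditional <- function(set_score, won_by_focal) {
  stopifnot(inherits(set_score, "set_score"))
  margin <- set_score$points_winner - set_score$points_loser
  11 + if (won_by_focal) margin else -margin
}

#' Match-level competition performance (CP)
#'
#' The focal player's CP is the arithmetic mean of their per-set values
#' ([set_cp()]); the opponent's CP is 22 minus it. CP ranges from 0 (every
#' set lost 0-11) to 22 (every set won 11-0), with 11 marking a perfectly
#' balanced match.
#'
#' @param sets List of [set_score()] objects each carrying a `won_by_focal`
#'   attribute, as produced by [parse_scoreline()].
#' @param variant `"exponential"` (default), `"linear"`, or `"traditional"`
#'   for the equal-margin baseline.
#' @return A `cp_result` object: `scp_per_set` (focal player's per-set
#'   values), `cp_focal`, `cp_opponent`, `n_sets`, `formula_variant`.
#' @examples
#' sets <- parse_scoreline("12:10,7:11,7:11,5:11,13:11,11:4,11:8")
#' match_cp(sets)
#' @export
match_cp <- function(sets, variant = c("exponential", "linear", "traditional")) {
  variant <- match.arg(variant)
  if (!length(sets)) stop("need at least one set", call. = FALSE)
  scp <- vapply(sets, function(s) {
    won <- attr(s, "won_by_focal")
    if (is.null(won)) stop("each set needs a 'won_by_focal' attribute", call. = FALSE)
    if (variant == "traditional") set_cp_traditional(s, won)
    else set_cp(s, won, variant)
  }, numeric(1))
  cp <- mean(scp)
  structure(list(scp_per_set = scp,
                 cp_focal = cp,
                 cp_opponent = 22 - cp,
                 n_sets = length(sets),
                 formula_variant = variant),
            class = "cp_result")
}

#' @export
as.data.frame.cp_result <- function(x, ...) {
  data.frame(cp_focal = x$cp_focal, cp_opponent = x$cp_opponent,
             n_sets = x$n_sets, formula_variant = x$formula_variant)
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf("<cp_result> CP focal %.3f / opponent %.3f over %d sets (%s variant)\n",
              x$cp_focal, x$cp_opponent, x$n_sets, x$formula_variant))
  cat("  per-set:", paste(sprintf("%.3f", x$scp_per_set), collapse = ", "), "\n")
  invisible(x)
}
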