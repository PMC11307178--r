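#' Analyse a batch of matches
#'
#' Runs the full per-match pipeline over a list of [match_record()]s: DMA and
#' fluctuation summary, exact expected distribution at the match's own
#' overall winning probability, K-S test of the observed against the expected
#' DMA distribution, and (where the match is long enough and not one-sided)
#' the Monte-Carlo kurtosis z-test with the null built at the match's own
#' winning probability and valid DMA count. Matches shorter than 7 rallies
#' are skipped with a warning. Per-match seeds are derived deterministically
#' from the master seed, so a report is fully reproducible.
#'
#' The kurtosis columns are `NA` for matches whose winning probability is 0
#' or 1 (the null is degenerate) or with fewer than 14 valid DMA values
#' (under 20 rallies). No multiple-testing correction is applied to the
#' per-match flags; the report instead carries the expected number of false
#' positives at the chosen alpha so tournament-level proportions can be read
#' against it.
#'
#' @param records List of [match_record()] objects.
#' @param config Named list overriding any of: `seed` (master seed, default
#'   1), `ks_method` (`"asymptotic"` or `"monte_carlo"`), `mc_replicates`
#'   (default 2000), `kurtosis_total_draws` (default 1e6),
#'   `kurtosis_type` (`"adjusted"` or `"moment"`), `alpha` (default 0.05).
#' @return A `batch_report` object: `per_match` data frame (one row per
#'   analysed match), `n_matches`, `n_skipped`, `prop_ks_significant`,
#'   `prop_kurtosis_significant`, `expected_false_positives`, `config`.
#' @export
analyze_matches <- function(records, config = list()) {
  cfg <- utils::modifyList(list(seed = 1L,
                                ks_method = "asymptotic",
                                mc_replicates = 2000L,
                                kurtosis_total_draws = 1e6,
                                kurtosis_type = "adjusted",
                                alpha = 0.05),
                           config)
  ok <- vapply(records, function(r) attr(r$rally_series, "n") >= 7L, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(sprintf("skipping %d match(es) with fewer than 7 rallies: %s",
                    n_skipped,
                    paste(vapply(records[!ok], `[[`, character(1), "match_id"),
                          collapse = ", ")), call. = FALSE)
  }
  records <- records[ok]
  if (!length(records)) stop("no analyzable matches (all shorter than 7 rallies)",
                             call. = FALSE)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    seed_i <- as.integer((as.numeric(cfg$seed) + 7919 * i) %% (2^31 - 1))
    s <- r$rally_series
    dma <- double_moving_average(s)
    summ <- summarize_fluctuation(dma, s)
    expd <- expected_dma_distribution(summ$wp)
    ks <- ks_test(dma, expd, method = cfg$ks_method,
                  mc_replicates = cfg$mc_replicates, seed = seed_i)
    kt <- NULL
    if (summ$wp > 0 && summ$wp < 1 && summ$n_valid >= 14L) {
      null <- simulate_kurtosis_null(summ$wp, segment_length = summ$n_valid,
                                     total_draws = cfg$kurtosis_total_draws,
                                     seed = seed_i, type = cfg$kurtosis_type)
      kt <- tryCatch(kurtosis_z_test(dma, null), error = function(e) NULL)
    }
    cbind(data.frame(match_id = r$match_id, n = attr(s, "n")),
          as.data.frame(summ),
          data.frame(ks_d = ks$d, ks_p = ks$p_value, ks_method = ks$method,
                     ks_significant = ks$p_value < cfg$alpha),
          if (is.null(kt)) {
            data.frame(observed_kurtosis = NA_real_, null_mean = NA_real_,
                       null_sd = NA_real_, z = NA_real_,
                       p_two_sided = NA_real_, kurtosis_significant = NA)
          } else {
            data.frame(observed_kurtosis = kt$observed_kurtosis,
                       null_mean = kt$null$null_mean, null_sd = kt$null$null_sd,
                       z = kt$z, p_two_sided = kt$p_two_sided,
                       kurtosis_significant = kt$p_two_sided < cfg$alpha)
          },
          data.frame(seed = seed_i))
  })
  per_match <- do.call(rbind, rows)
  rownames(per_match) <- NULL
  n_matches <- nrow(per_match)
  structure(list(
    per_match = per_match,
    n_matches = n_matches,
    n_skipped = n_skipped,
    prop_ks_significant = sum(per_match$ks_significant, na.rm = TRUE) / n_matches,
    prop_kurtosis_significant =
      sum(per_match$kurtosis_significant, na.rm = TRUE) / n_matches,
    expected_false_positives = cfg$alpha * n_matches,
    config = cfg
  ), class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf(paste0("<batch_report> %d matches analysed (%d skipped)\n",
                     "  K-S significant: %.1f%%  kurtosis significant: %.1f%%",
                     "  (expected false positives at alpha %.2f: %.1f)\n"),
              x$n_matches, x$n_skipped, 100 * x$prop_ks_significant,
              100 * x$prop_kurtosis_significant, x$config$alpha,
              x$expected_false_positives))
  invisible(x)
}
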