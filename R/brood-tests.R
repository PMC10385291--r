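#' Exact two-sided binomial test
#'
#' Exact two-tailed binomial test of `k` successes in `n` trials against a
#' null success probability, computed by doubling the smaller tail and capping
#' at 1. For the symmetric null `p_null = 0.5` used throughout the brood and
#' sequence analyses this coincides with the minimum-likelihood two-sided
#' rule, so the result matches [stats::binom.test()].
#'
#' @param k Number of successes.
#' @param n Number of trials (`n >= 1`).
#' @param p_null Null success probability (default 0.5).
#' @return Object of class `binom_test_result`: list with `k`, `n`, `p_null`
#'   and `p_two_sided`.
#' @examples
#' binom_two_sided(27, 39)$p_two_sided # 0.0237
#' @export
binom_two_sided <- function(k, n, p_null = 0.5) {
  stopifnot(n >= 1)
  if (k < 0 || k > n) stop("`k` must lie in [0, n]", call. = FALSE)
  lower <- stats::pbinom(k, n, p_null)
  upper <- stats::pbinom(k - 1, n, p_null, lower.tail = FALSE)
  structure(
    list(k = k, n = n, p_null = p_null,
         p_two_sided = min(1, 2 * min(lower, upper))),
    class = "binom_test_result"
  )
}

#' @export
print.binom_test_result <- function(x, ...) {
  cat(sprintf("Exact binomial test: %d / %d vs p = %g, two-sided p = %.4f\n",
              x$k, x$n, x$p_null, x$p_two_sided))
  invisible(x)
}

#' Pair up double broods into ordered sex combinations
#'
#' Collects, for each territory-year with a two-nestling brood, the sexes of
#' the first- and second-hatched nestlings. Broods missing a nestling, a sex
#' or the hatching order are excluded and counted rather than guessed.
#'
#' @param records Data frame of validated nestling records.
#' @return List with `pairs` (data frame: `territory_id`, `year`, `first_sex`,
#'   `second_sex`, `combo` in `mm/ff/mf/fm`), `n_excluded` and `n_double_broods`
#'   (distinct territory-years holding any `brood_size == 2` record).
#' @export
pair_double_broods <- function(records) {
  doubles <- records[!is.na(records$brood_size) & records$brood_size == 2, ,
                     drop = FALSE]
  key <- paste(doubles$territory_id, doubles$year, sep = "\r")
  broods <- split(doubles, key)
  pairs <- list()
  excluded <- 0L
  for (b in broods) {
    firsts <- b[!is.na(b$hatching_order) & b$hatching_order == "first", ]
    seconds <- b[!is.na(b$hatching_order) & b$hatching_order == "second", ]
    if (nrow(firsts) > 1 || nrow(seconds) > 1) {
      stop("duplicate hatching order in territory ", b$territory_id[1],
           ", year ", b$year[1], call. = FALSE)
    }
    if (nrow(firsts) == 1 && nrow(seconds) == 1 &&
        firsts$sex %in% SEX_LEVELS && seconds$sex %in% SEX_LEVELS) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        territory_id = b$territory_id[1], year = b$year[1],
        first_sex = firsts$sex, second_sex = seconds$sex,
        stringsAsFactors = FALSE
      )
    } else {
      excluded <- excluded + 1L
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(territory_id = character(0), year = integer(0),
               first_sex = character(0), second_sex = character(0),
               stringsAsFactors = FALSE)
  pairs$combo <- tolower(paste0(pairs$first_sex, pairs$second_sex))
  rownames(pairs) <- NULL
  list(pairs = pairs, n_excluded = excluded,
       n_double_broods = length(broods))
}

# run the three Table-style tests on one row of combination counts
combination_row_tests <- function(mm, ff, mf, fm) {
  test_p <- function(k, n) {
    if (is.na(k) || is.na(n) || n == 0) NA_real_
    else binom_two_sided(k, n)$p_two_sided
  }
  single <- if (is.na(mm) && is.na(ff)) NA_integer_ else
    sum(c(mm, ff), na.rm = TRUE)
  mixed <- if (is.na(mf) && is.na(fm)) NA_integer_ else
    sum(c(mf, fm), na.rm = TRUE)
  c(p_mm_ff = test_p(mm, mm + ff),
    p_mf_fm = test_p(mf, mf + fm),
    p_single_mixed = test_p(single, single + mixed))
}

#' Binomial test battery on double-brood sex combinations
#'
#' For each stratum of a combination-count table, tests (i) two-male vs
#' two-female broods, (ii) mixed broods with the male first vs the female
#' first, and (iii) single-sex vs mixed-sex broods, each with
#' [binom_two_sided()] against 0.5. Cells without trials (e.g. strata with no
#' hatching-order data) are reported as `NA`.
#'
#' @param counts Data frame with columns `region`, `mm`, `ff`, `mf`, `fm` —
#'   e.g. [brood_combination_counts()].
#' @return Data frame of class `brood_combination_table` adding columns
#'   `single`, `mixed`, `p_mm_ff`, `p_mf_fm`, `p_single_mixed`.
#' @examples
#' combination_tests(brood_combination_counts())
#' @export
combination_tests <- function(counts) {
  stopifnot(all(c("region", "mm", "ff", "mf", "fm") %in% names(counts)))
  ps <- t(vapply(seq_len(nrow(counts)), function(i) {
    combination_row_tests(counts$mm[i], counts$ff[i], counts$mf[i],
                          counts$fm[i])
  }, numeric(3)))
  counts$single <- ifelse(is.na(counts$mm) & is.na(counts$ff), NA,
                          rowSums(counts[, c("mm", "ff")], na.rm = TRUE))
  counts$mixed <- ifelse(is.na(counts$mf) & is.na(counts$fm), NA,
                         rowSums(counts[, c("mf", "fm")], na.rm = TRUE))
  out <- cbind(counts, as.data.frame(ps))
  class(out) <- c("brood_combination_table", "data.frame")
  out
}

#' Combination table built from nestling records
#'
#' Classifies every complete double brood with [pair_double_broods()], counts
#' the `mm/ff/mf/fm` combinations per stratum and runs the binomial battery of
#' [combination_tests()]. Pooled strata (`Peninsular`, `Islands`, `All`) are
#' sums over the region strata.
#'
#' @param records Data frame of validated nestling records.
#' @param by Grouping column (default `"region"`).
#' @param pooled Append pooled mainland/island/all strata (default `TRUE`).
#' @return A `brood_combination_table`; see [combination_tests()].
#' @export
combination_table <- function(records, by = "region", pooled = TRUE) {
  paired <- pair_double_broods(records)
  pairs <- paired$pairs
  strata <- records[[by]][match(
    paste(pairs$territory_id, pairs$year, sep = "\r"),
    paste(records$territory_id, records$year, sep = "\r"))]
  levels_seen <- unique(strata)
  counts <- do.call(rbind, lapply(levels_seen, function(g) {
    combos <- pairs$combo[strata == g]
    data.frame(region = g,
               mm = sum(combos == "mm"), ff = sum(combos == "ff"),
               mf = sum(combos == "mf"), fm = sum(combos == "fm"),
               stringsAsFactors = FALSE)
  }))
  if (pooled && by == "region") {
    mainland <- counts$region %in% MAINLAND_REGIONS
    pool_row <- function(name, idx) {
      data.frame(region = name, mm = sum(counts$mm[idx]),
                 ff = sum(counts$ff[idx]), mf = sum(counts$mf[idx]),
                 fm = sum(counts$fm[idx]), stringsAsFactors = FALSE)
    }
    counts <- rbind(counts,
                    pool_row("Peninsular", mainland),
                    pool_row("Islands", !mainland),
                    pool_row("All", rep(TRUE, nrow(counts))))
  }
  combination_tests(counts)
}

#' @export
print.brood_combination_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("p_mm_ff", "p_mf_fm", "p_single_mixed")) {
    y[[col]] <- round(y[[col]], 4)
  }
  print(y)
  invisible(x)
}
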