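#' Monte Carlo parity test for a sex-ratio sample
#'
#' Tests whether an observed proportion of males deviates from parity while
#' controlling for sample size, by repeatedly drawing `n` individuals
#' *without replacement* from a theoretical pool of `pool_size` nestlings with
#' a balanced (1:1) sex ratio and comparing the observed ratio with the
#' empirical distribution of simulated ratios. Tail probabilities count the
#' randomisations whose ratio is equal to or greater (lower) than the observed
#' one, divided by `n_sims`; the 95% interval is the 2.5% / 97.5% pair of
#' order statistics of the sorted simulated ratios (the 25th and 976th of
#' 1000). A sample is flagged significant when the observed ratio falls
#' outside that interval.
#'
#' @param n Sample size (number of sexed nestlings).
#' @param k_males Number of males observed.
#' @param pool_size Size of the balanced theoretical pool (even; default 3000).
#' @param n_sims Number of randomisations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `parity_test`: a list with `n`, `k_males`,
#'   `observed_ratio`, `q025`, `q975`, `p_ge`, `p_le`, `p_two` (doubled
#'   smaller tail, capped at 1), `n_sims`, `pool_size` and `significant`.
#' @seealso [exact_parity_interval()] for the deterministic hypergeometric
#'   oracle, [parity_table()] for a per-region summary.
#' @examples
#' mc_parity_test(499, 275, seed = 1)
#' @export
mc_parity_test <- function(n, k_males, pool_size = 3000, n_sims = 1000,
                           seed = NULL) {
  if (pool_size %% 2 != 0) stop("`pool_size` must be even", call. = FALSE)
  if (n > pool_size) stop("`n` cannot exceed `pool_size`", call. = FALSE)
  stopifnot(k_males >= 0, k_males <= n, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  half <- pool_size / 2
  # drawing n without replacement from half males / half females:
  # the male count per draw is hypergeometric
  sims <- stats::rhyper(n_sims, half, half, n) / n
  observed <- k_males / n
  sorted <- sort(sims)
  k_lo <- max(1L, floor(0.025 * n_sims))
  k_hi <- min(n_sims, ceiling(0.975 * n_sims) + 1L)
  q025 <- sorted[k_lo]
  q975 <- sorted[k_hi]
  structure(
    list(
      n = n, k_males = k_males, observed_ratio = observed,
      q025 = q025, q975 = q975,
      p_ge = mean(sims >= observed), p_le = mean(sims <= observed),
      p_two = min(1, 2 * min(mean(sims >= observed), mean(sims <= observed))),
      n_sims = n_sims, pool_size = pool_size,
      significant = observed < q025 || observed > q975
    ),
    class = "parity_test"
  )
}

#' Exact hypergeometric 95% parity interval
#'
#' Deterministic oracle for [mc_parity_test()]: the central interval of the
#' distribution of the male proportion when `n` individuals are drawn without
#' replacement from a balanced pool. Returns `k_lo / n` and `k_hi / n` where
#' `k_lo` is the largest male count whose lower tail `P(X < k_lo)` is at most
#' `alpha/2` and `k_hi` the smallest whose upper tail `P(X > k_hi)` is at most
#' `alpha/2`, so the interval holds at least `1 - alpha` probability mass.
#'
#' @param n Sample size.
#' @param pool_size Size of the balanced pool (even; default 3000).
#' @param alpha Total tail probability (default 0.05).
#' @return Named numeric vector `c(lo, hi)` of proportions.
#' @examples
#' round(exact_parity_interval(1661), 2) # 0.48 0.52
#' @export
exact_parity_interval <- function(n, pool_size = 3000, alpha = 0.05) {
  if (pool_size %% 2 != 0) stop("`pool_size` must be even", call. = FALSE)
  if (n > pool_size) stop("`n` cannot exceed `pool_size`", call. = FALSE)
  half <- pool_size / 2
  ks <- 0:n
  lower_tail <- stats::phyper(ks - 1, half, half, n)  # P(X < k)
  upper_tail <- stats::phyper(ks, half, half, n, lower.tail = FALSE)  # P(X > k)
  k_lo <- max(ks[lower_tail <= alpha / 2])
  k_hi <- min(ks[upper_tail <= alpha / 2])
  c(lo = k_lo / n, hi = k_hi / n)
}

#' Per-stratum parity summary table
#'
#' Runs [mc_parity_test()] on each row of a counts table (such as
#' [region_sex_counts()]) or on counts aggregated from nestling records,
#' producing one row per stratum with the observed ratio, the simulated 95%
#' interval and the significance flag.
#'
#' @param x Either a data frame of counts with columns `region`, `males`,
#'   `females`, or a data frame of nestling records (with `region` and `sex`
#'   columns) to be aggregated.
#' @param pool_size,n_sims Passed to [mc_parity_test()].
#' @param seed Integer seed; each stratum uses an offset of it so the table is
#'   reproducible as a whole.
#' @return Data frame of class `parity_table` with columns `region`, `n`,
#'   `males`, `females`, `ratio`, `lo`, `hi`, `significant`.
#' @export
parity_table <- function(x, pool_size = 3000, n_sims = 1000, seed = NULL) {
  counts <- if (all(c("males", "females") %in% names(x))) {
    x
  } else {
    stopifnot(all(c("region", "sex") %in% names(x)))
    tab <- table(x$region, x$sex)
    data.frame(region = rownames(tab),
               males = as.integer(tab[, "M"]),
               females = as.integer(tab[, "F"]),
               stringsAsFactors = FALSE)
  }
  counts$n <- counts$males + counts$females
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    res <- mc_parity_test(counts$n[i], counts$males[i],
                          pool_size = pool_size, n_sims = n_sims,
                          seed = if (is.null(seed)) NULL else seed + i)
    data.frame(region = counts$region[i], n = res$n, males = counts$males[i],
               females = counts$females[i], ratio = res$observed_ratio,
               lo = res$q025, hi = res$q975, significant = res$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("parity_table", "data.frame")
  out
}

#' @export
print.parity_test <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Monte Carlo parity test: %d males of %d (ratio %.2f)\n", x$k_males, x$n,
    x$observed_ratio))
  cat(sprintf("  simulated 95%% interval: %.2f-%.2f (%d draws, pool %d)\n",
              x$q025, x$q975, x$n_sims, x$pool_size))
  cat(sprintf("  p(>= observed) = %.3f, p(<= observed) = %.3f, doubled = %.3f\n",
              x$p_ge, x$p_le, x$p_two))
  cat("  significant (outside interval):", x$significant, "\n")
  invisible(x)
}

#' @export
print.parity_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$ratio <- round(y$ratio, digits)
  y$lo <- round(y$lo, digits)
  y$hi <- round(y$hi, digits)
  print(y)
  invisible(x)
}
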