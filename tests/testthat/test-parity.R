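test_that("a male-biased island-sized sample is flagged, a balanced one is not", {
  res <- mc_parity_test(499, 275, seed = 1)
  expect_equal(res$observed_ratio, 275 / 499)
  expect_true(res$significant)
  expect_lt(res$p_ge, 0.025)

  bal <- mc_parity_test(100, 50, seed = 2)
  expect_false(bal$significant)
  expect_equal(bal$p_ge, 0.5, tolerance = 0.2)
  expect_equal(bal$p_le, 0.5, tolerance = 0.2)
  # both tails include ties, so together they exceed 1 by the tie mass
  expect_gte(bal$p_ge + bal$p_le, 1)
})

test_that("parity test results satisfy their structural invariants", {
  for (seed in 1:5) {
    n <- c(50, 200, 499, 1661)[(seed %% 4) + 1]
    k <- rbinom(1, n, 0.5)
    r <- mc_parity_test(n, k, seed = seed)
    expect_gte(r$observed_ratio, 0)
    expect_lte(r$observed_ratio, 1)
    expect_lte(r$q025, r$q975)
    expect_true(all(c(r$p_ge, r$p_le) >= 0 & c(r$p_ge, r$p_le) <= 1))
    expect_identical(r$significant,
                     r$observed_ratio < r$q025 || r$observed_ratio > r$q975)
  }
  expect_error(mc_parity_test(10, 5, pool_size = 3001), "even")
  expect_error(mc_parity_test(4000, 100), "exceed")
})

test_that("the exact interval matches the hypergeometric CDF and degenerates correctly", {
  # exhaustive draw: the ratio is deterministic
  expect_equal(unname(exact_parity_interval(3000)), c(0.5, 0.5))
  # large-sample rows at 2 dp
  expect_equal(unname(round(exact_parity_interval(1661), 2)), c(0.48, 0.52))
  expect_equal(unname(round(exact_parity_interval(499), 2)), c(0.46, 0.54))
  # tail definition: at least 95% mass inside, each outer tail <= 2.5%
  for (n in c(50, 182, 499, 1661)) {
    iv <- exact_parity_interval(n)
    k_lo <- iv[["lo"]] * n
    k_hi <- iv[["hi"]] * n
    expect_lte(phyper(k_lo - 1, 1500, 1500, n), 0.025)
    expect_lte(phyper(k_hi, 1500, 1500, n, lower.tail = FALSE), 0.025)
    expect_gte(phyper(k_hi, 1500, 1500, n) - phyper(k_lo - 1, 1500, 1500, n),
               0.95)
  }
})

test_that("the Monte Carlo interval concentrates on the exact oracle interval", {
  # sample sizes whose 2-dp bounds sit clear of a rounding boundary; at
  # sizes like 425 the exact bound is near .455 and the rounded MC order
  # statistic legitimately alternates
  for (n in c(499, 1112, 1661)) {
    iv <- exact_parity_interval(n)
    hits_lo <- 0
    hits_hi <- 0
    for (seed in 1:20) {
      r <- mc_parity_test(n, round(n / 2), seed = 100 + seed)
      hits_lo <- hits_lo + (round(r$q025, 2) == round(iv[["lo"]], 2))
      hits_hi <- hits_hi + (round(r$q975, 2) == round(iv[["hi"]], 2))
    }
    expect_gte(hits_lo, 15)
    expect_gte(hits_hi, 15)
  }
  # at every size the raw MC order statistics bracket the exact bounds closely
  for (n in c(182, 425, 1661)) {
    iv <- exact_parity_interval(n)
    r <- mc_parity_test(n, round(n / 2), seed = 77)
    expect_lt(abs(r$q025 - iv[["lo"]]), 2 / sqrt(n))
    expect_lt(abs(r$q975 - iv[["hi"]]), 2 / sqrt(n))
  }
})

test_that("the finite-pool null converges to the binomial null as the pool grows", {
  n <- 100
  r <- mc_parity_test(n, 50, pool_size = 1e6, n_sims = 4000, seed = 3)
  expect_lt(abs(r$q975 - qbinom(0.975, n, 0.5) / n), 1 / n + 1e-9)
  expect_lt(abs(r$q025 - qbinom(0.025, n, 0.5) / n), 1 / n + 1e-9)
})

test_that("the randomisation p-value is super-uniform under the finite-pool null", {
  set.seed(17)
  n <- 200
  n_rep <- 400
  k_null <- rhyper(n_rep, 1500, 1500, n)
  p <- vapply(seq_len(n_rep), function(i) {
    mc_parity_test(n, k_null[i], n_sims = 500, seed = 1000 + i)$p_ge
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    # allow the resolution of the randomisation (1/n_sims) plus MC error
    mc_slack <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(p <= alpha), alpha + 1 / 500 + mc_slack)
  }
})

test_that("parity_table aggregates records and counts identically", {
  st <- simulate_study(seed = 4)
  from_records <- parity_table(st, seed = 50)
  counts <- region_sex_counts(pooled = FALSE)
  counts <- counts[order(counts$region), ]
  from_records <- from_records[order(from_records$region), ]
  # simulate_study draws sexes, so compare structure and n, not male counts
  expect_identical(from_records$n, counts$n)
  expect_identical(from_records$region, counts$region)
  expect_equal(from_records$ratio,
               from_records$males / from_records$n)
})
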