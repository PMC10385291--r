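test_that("sequences are ordered by year then hatching order", {
  rec <- data.frame(
    nestling_id = c("x", "y", "z"),
    region = "Canary", insularity = "island",
    territory_id = "t1", year = c(2001L, 2001L, 2002L),
    hatching_date = NA_integer_, brood_size = c(2L, 2L, 1L),
    hatching_order = c("second", "first", "single"),
    sex = c("F", "M", "M"), breeding_unit = "pair",
    mother_id = "f1", father_id = "m1",
    stringsAsFactors = FALSE
  )
  sq <- build_sequences(rec, "female", min_offspring = 2)
  expect_equal(sq$sexes, "MFM")
  expect_equal(sq$max_run_M, 1)
  expect_equal(sq$max_run_F, 1)
  expect_false(sq$all_same_sex)
})

test_that("run detection agrees with a brute-force scan over all short strings", {
  for (len in 1:12) {
    combos <- expand.grid(rep(list(c("M", "F")), len),
                          stringsAsFactors = FALSE)
    strings <- lapply(seq_len(nrow(combos)), function(i) {
      unlist(combos[i, ], use.names = FALSE)
    })
    got_m <- vapply(strings, broodskew:::max_run, 0L, "M")
    got_f <- vapply(strings, broodskew:::max_run, 0L, "F")
    ref_m <- vapply(strings, brute_max_run, 0L, "M")
    ref_f <- vapply(strings, brute_max_run, 0L, "F")
    expect_identical(got_m, ref_m)
    expect_identical(got_f, ref_f)
  }
})

test_that("run-bias counts and test match the published battery", {
  seqs <- data.frame(
    unit_id = sprintf("u%02d", 1:20), unit_kind = "female",
    n = 6, sexes = c(rep("MMMMFF", 11), rep("FFFFMM", 3), rep("MFMFMF", 6)),
    stringsAsFactors = FALSE
  )
  seqs$max_run_M <- vapply(strsplit(seqs$sexes, ""), brute_max_run, 0L, "M")
  seqs$max_run_F <- vapply(strsplit(seqs$sexes, ""), brute_max_run, 0L, "F")
  rb <- run_bias_test(seqs, run_length = 4)
  expect_equal(rb$units_male_run, 11)
  expect_equal(rb$units_female_run, 3)
  expect_equal(round(rb$test$p_two_sided, 4), 0.0574)

  balanced <- seqs[1:10, ]
  balanced$max_run_M <- rep(c(4L, 0L), 5)
  balanced$max_run_F <- rep(c(0L, 4L), 5)
  expect_equal(run_bias_test(balanced)$test$p_two_sided, 1)

  # a unit with both runs contributes to both tallies
  both <- data.frame(unit_id = "u", unit_kind = "female", n = 8,
                     sexes = "MMMMFFFF", max_run_M = 4L, max_run_F = 4L,
                     stringsAsFactors = FALSE)
  rb2 <- run_bias_test(both)
  expect_equal(rb2$units_male_run, 1)
  expect_equal(rb2$units_female_run, 1)

  none <- data.frame(unit_id = "u", unit_kind = "female", n = 3,
                     sexes = "MFM", max_run_M = 1L, max_run_F = 1L,
                     stringsAsFactors = FALSE)
  expect_true(run_bias_test(none)$no_test)
})

test_that("single-unit parity tests match their closed forms", {
  nine <- data.frame(sexes = "MMMMMMMMM")
  expect_equal(round(all_same_sex_test(nine[1, , drop = FALSE])$p_two_sided, 4),
               0.0039)
  one <- data.frame(sexes = "M")
  expect_equal(all_same_sex_test(one[1, , drop = FALSE])$p_two_sided, 1)
  eight <- data.frame(sexes = "MMMMMMMM")
  expect_equal(all_same_sex_test(eight[1, , drop = FALSE])$p_two_sided,
               2 * 0.5^8)
})

test_that("sequence building honours identity, minimum length and relabelling", {
  sim <- simulate_records(sim_config(), seed = 13)
  sq <- build_sequences(sim$records, "female", min_offspring = 2)
  expect_true(all(sq$n >= 2))
  expect_true(all(sq$max_run_M <= nchar(sq$sexes)))
  # all_same_sex iff one run spans the sequence
  expect_identical(sq$all_same_sex,
                   pmax(sq$max_run_M, sq$max_run_F) == sq$n)
  # relabelling units leaves the run-bias test unchanged
  rb <- run_bias_test(sq)
  shuffled <- sq[sample(nrow(sq)), ]
  shuffled$unit_id <- paste0("relabel_", seq_len(nrow(shuffled)))
  rb2 <- run_bias_test(shuffled)
  expect_equal(rb$units_male_run, rb2$units_male_run)
  expect_equal(rb$units_female_run, rb2$units_female_run)
  if (!rb$no_test) expect_equal(rb$test$p_two_sided, rb2$test$p_two_sided)
  # single-offspring units are excluded
  sq1 <- build_sequences(sim$records, "female", min_offspring = 5)
  expect_true(all(sq1$n >= 5))
  expect_lt(nrow(sq1), nrow(sq))
})

test_that("the run-bias p-value is super-uniform under a null generator", {
  set.seed(99)
  n_rep <- 300
  p <- rep(NA_real_, n_rep)
  for (i in seq_len(n_rep)) {
    lens <- sample(4:10, 40, replace = TRUE)
    seqs <- data.frame(
      unit_id = sprintf("u%02d", seq_along(lens)), unit_kind = "female",
      n = lens,
      sexes = vapply(lens, function(L) {
        paste(sample(c("M", "F"), L, replace = TRUE), collapse = "")
      }, ""),
      stringsAsFactors = FALSE
    )
    seqs$max_run_M <- vapply(strsplit(seqs$sexes, ""), brute_max_run, 0L, "M")
    seqs$max_run_F <- vapply(strsplit(seqs$sexes, ""), brute_max_run, 0L, "F")
    rb <- run_bias_test(seqs)
    p[i] <- if (rb$no_test) 1 else rb$test$p_two_sided
  }
  for (alpha in c(0.05, 0.1)) {
    mc_slack <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(p <= alpha), alpha + mc_slack)
  }
})
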