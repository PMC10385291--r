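test_that("AICc follows its formula and limits", {
  expect_equal(aicc(-100, 3, 1000), 206.0241, tolerance = 1e-4)
  # n -> infinity recovers AIC
  expect_equal(aicc(-100, 3, 1e9), -2 * -100 + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "n > k")
  # ordering invariant to a constant shift of all log-likelihoods
  ll <- c(-100, -98.5, -103)
  a1 <- vapply(ll, aicc, numeric(1), k = 3, n = 500)
  a2 <- vapply(ll + 17, aicc, numeric(1), k = 3, n = 500)
  expect_identical(order(a1), order(a2))
})

test_that("Akaike weights normalise and match hand arithmetic", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(w[1] / w[2], exp(1), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    x <- runif(sample(2:8, 1), 200, 2000)
    expect_equal(sum(akaike_weights(x)), 1, tolerance = 1e-12)
  }
  # removing a model preserves weight ratios after renormalisation
  x <- c(300, 301.2, 302.5)
  w3 <- akaike_weights(x)
  w2 <- akaike_weights(x[1:2])
  expect_equal(w2[1] / w2[2], w3[1] / w3[2], tolerance = 1e-12)
})

test_that("candidate enumeration matches the per-scale variable pools", {
  bal <- enumerate_candidates("balearic")
  expect_length(bal, 4)
  expect_identical(bal[[1]], character(0))
  can <- enumerate_candidates("canary")
  expect_true(any(vapply(can, function(s) "unit" %in% s, logical(1))))
  all_sets <- enumerate_candidates("all")
  has <- function(sets, s) any(vapply(sets, setequal, logical(1), s))
  expect_true(has(all_sets, c("insularity", "brood_size")))
  # aliased pairs never co-occur
  expect_false(any(vapply(all_sets, function(s) {
    all(c("region", "insularity") %in% s) || all(c("brood_size", "order") %in% s)
  }, logical(1))))
  age <- enumerate_candidates("parental_age", age_coding = "cat2")
  expect_identical(age, list(character(0), "age_cat2"))
  expect_error(enumerate_candidates("europe"))
})

test_that("mixed-model fits reduce to plain GLM / OLS without random variation", {
  set.seed(50)
  n <- 1500
  d <- data.frame(
    sex = NA, year = rep(2000:2014, each = n / 15),
    territory_id = rep(sprintf("t%02d", 1:50), length.out = n),
    insularity = sample(c("mainland", "island"), n, replace = TRUE),
    brood_size = sample(1:2, n, replace = TRUE)
  )
  eta <- -0.1 + 0.4 * (d$insularity == "island")
  d$sex <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "M", "F")
  fmix <- fit_glmm(d, c("insularity", "brood_size"))
  # with this draw both variance estimates sit on the 0 boundary, so the
  # mixed model must collapse to the plain GLM
  expect_equal(unname(lme4::getME(fmix$model, "theta")), c(0, 0),
               tolerance = 1e-6)
  ref <- glm(I(sex == "M") ~ insularity + factor(brood_size),
             data = transform(d, insularity = factor(insularity,
                                                     c("mainland", "island"))),
             family = binomial)
  expect_equal(fmix$coefficients$estimate, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fmix$k, 5)  # intercept + 2 fixed + 2 variances
  # gaussian family without random terms is ordinary least squares
  d$resp <- rnorm(n)
  fg <- fit_glmm(d, "brood_size", random_terms = character(0),
                 family = "gaussian", response = "resp")
  ols <- lm(resp ~ factor(brood_size), data = d)
  expect_equal(fg$coefficients$estimate, unname(coef(ols)), tolerance = 1e-10)
})

test_that("model selection ranks candidates and flags the alternative set", {
  sim <- simulate_records(
    sim_config(beta_island = 0.8, sigma_year = 0.05, sigma_territory = 0.05),
    seed = 19)
  ms <- model_selection(sim$records, candidates = list(
    character(0), "insularity", "brood_size", c("insularity", "brood_size")))
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(ms$table$delta), 0)
  expect_true("null" %in% ms$table$model)
  expect_identical(ms$table$alternative, ms$table$delta < 2)
  # strong generating effect: an insularity model leads the ranking
  expect_match(ms$table$model[1], "insularity")
  # every fit used the same rows
  expect_length(unique(vapply(ms$fits, `[[`, numeric(1), "n")), 1)
})

test_that("model averaging matches hand arithmetic and degenerates correctly", {
  fake_fit <- function(label, terms, est) {
    structure(list(label = label, terms = terms,
                   coefficients = data.frame(
                     term = names(est), estimate = unname(est),
                     se = rep(0.1, length(est)), stringsAsFactors = FALSE)),
              class = "glmm_fit")
  }
  fits <- list(
    fake_fit("a", "x", c("(Intercept)" = 0.5, x = 1)),
    fake_fit("null", character(0), c("(Intercept)" = 0.5))
  )
  mset <- structure(list(
    table = data.frame(model = c("a", "null"), df = c(2, 1),
                       AICc = c(100, 100), delta = c(0, 0),
                       weight = c(0.5, 0.5), alternative = c(TRUE, TRUE)),
    fits = fits, n = 100, n_dropped = 0), class = "model_set")
  avg <- model_average(mset)
  # zero substitution halves the effect present in one of two equal models
  expect_equal(avg$estimate[avg$term == "x"], 0.5)
  cond <- model_average(mset, method = "conditional")
  expect_equal(cond$estimate[cond$term == "x"], 1)
  # single-model alternative set: averaging returns that model's estimates
  mset1 <- mset
  mset1$table$alternative <- c(TRUE, FALSE)
  mset1$table$weight <- c(0.9, 0.1)
  avg1 <- model_average(mset1)
  expect_equal(avg1$estimate[avg1$term == "x"], 1)
  expect_equal(avg1$se[avg1$term == "x"], 0.1)
})

test_that("support labels operationalise CI overlap with zero", {
  fake_set <- function(est, se) {
    fit <- structure(list(label = "m", terms = "x",
                          coefficients = data.frame(
                            term = "x", estimate = est, se = se,
                            stringsAsFactors = FALSE)),
                     class = "glmm_fit")
    structure(list(table = data.frame(model = "m", df = 2, AICc = 1,
                                      delta = 0, weight = 1,
                                      alternative = TRUE),
                   fits = list(fit), n = 10, n_dropped = 0),
              class = "model_set")
  }
  expect_equal(model_average(fake_set(1, 0.2))$support, "strong")
  expect_equal(model_average(fake_set(0.3, 0.2))$support, "weak")
  expect_equal(model_average(fake_set(0.05, 0.2))$support, "none")
})

test_that("Bonferroni contrasts scale with the number of level pairs", {
  sim <- simulate_records(sim_config(beta_post = 0.5), seed = 23)
  f2 <- fit_glmm(sim$records, c("insularity", "madcow"))
  con3 <- posthoc_bonferroni(f2, "madcow")
  expect_equal(nrow(con3), 3)  # 3-level factor: 3 pairs, p x 3
  raw_p <- 2 * pnorm(-abs(con3$z))
  expect_equal(con3$p_adjusted, pmin(1, raw_p * 3))
  con1 <- posthoc_bonferroni(f2, "insularity")
  expect_equal(nrow(con1), 1)  # 2-level factor: single unadjusted contrast
  expect_equal(con1$p_adjusted, min(1, 2 * pnorm(-abs(con1$z))))
  expect_error(posthoc_bonferroni(f2, "unit"), "not in the model")
})

test_that("variance inflation factors match their closed forms", {
  set.seed(6)
  n <- 10000
  d <- data.frame(x1 = rnorm(n), x3 = rnorm(n))
  d$x2 <- 0.9 * d$x1 + sqrt(1 - 0.81) * rnorm(n)
  v <- vif_terms(d, c("x1", "x2", "x3"))
  expect_equal(unname(v["x3"]), 1, tolerance = 0.02)
  expect_equal(unname(v["x2"]), 1 / (1 - 0.81), tolerance = 0.35)
  d$x4 <- d$x1
  expect_true(is.infinite(vif_terms(d, c("x1", "x4"))["x1"]))
})

test_that("annual-ratio models detect a density effect and define lags correctly", {
  set.seed(14)
  ann <- data.frame(year = 1998:2021)
  ann$pairs <- round(30 + cumsum(rnorm(24, 1.5, 2)))
  lagged <- add_trend_lags(ann, 1:7)
  for (k in c(1, 4, 7)) {
    expect_equal(lagged[[paste0("trend_lag_", k)]][24],
                 ann$pairs[24] - ann$pairs[24 - k])
    expect_true(all(is.na(lagged[[paste0("trend_lag_", k)]][seq_len(k)])))
  }
  # constant annual ratio: the null stays within 2 AICc of everything
  flat <- ann
  flat$ratio <- 0.5 + rnorm(24, 0, 0.002)
  res_flat <- annual_ratio_glm(flat, predictors = "density")
  expect_true(res_flat$table$supported[res_flat$table$model == "null"])
  # strong density signal at low noise: density beats the null by > 2
  sig <- ann
  sig$ratio <- 0.3 + 0.002 * sig$pairs + rnorm(24, 0, 0.002)
  res_sig <- annual_ratio_glm(sig, predictors = "density")
  tab <- res_sig$table
  expect_equal(tab$model[1], "density")
  expect_gt(tab$delta[tab$model == "null"], 2)
  flat$ratio <- 0.5
  expect_error(annual_ratio_glm(transform(flat, pairs = 30),
                                predictors = "density"), "constant")
})
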