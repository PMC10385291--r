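# Independent oracles used across tests.

# two-sided binomial p by explicit enumeration of the probability mass
enum_binom_p <- function(k, n, p = 0.5) {
  mass <- vapply(0:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
                 numeric(1))
  lower <- sum(mass[0:k + 1])
  upper <- sum(mass[k:n + 1])
  min(1, 2 * min(lower, upper))
}

# longest run of `value` by a brute-force scan
brute_max_run <- function(sexes, value) {
  best <- 0L
  run <- 0L
  for (s in sexes) {
    run <- if (s == value) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

# small well-formed record data.frame for data-model tests
tiny_records <- function() {
  data.frame(
    nestling_id = c("a", "b", "c"),
    region = c("Navarra", "Canary", "Canary"),
    territory_id = c("t1", "t2", "t2"),
    year = c(2000L, 2015L, 2015L),
    hatching_date = c(100L, 120L, 125L),
    brood_size = c(1L, 2L, 2L),
    hatching_order = c("single", "first", "second"),
    sex = c("M", "F", "M"),
    breeding_unit = c("pair", "pair", "pair"),
    mother_id = c("f1", "f2", "f2"),
    father_id = c("m1", "m2", "m2"),
    stringsAsFactors = FALSE
  )
}

# marginal log-likelihood of the intercept-only logistic random-intercept
# model by adaptive quadrature (integrate) per group
adaptive_loglik <- function(mu, sigma, k_by_group, n_by_group) {
  sum(mapply(function(k, n) {
    f <- function(u) {
      p <- plogis(mu + u)
      p^k * (1 - p)^(n - k) * dnorm(u, 0, sigma)
    }
    log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }, k_by_group, n_by_group))
}
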