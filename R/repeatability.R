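# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Marginal log-likelihood of the intercept-only logistic model with one
# Gaussian random intercept, by fixed-order Gauss-Hermite quadrature.
# Integral per group: int prod_j p(u)^y (1-p(u))^(1-y) dN(u; 0, sigma^2)
# with the substitution u = sqrt(2) * sigma * x, weight exp(-x^2).
binary_intercept_loglik <- function(mu, sigma, k_by_group, n_by_group, gh) {
  u <- sqrt(2) * sigma * gh$x
  eta <- outer(rep(1, length(k_by_group)), u) + mu
  log_p <- stats::plogis(eta, log.p = TRUE)
  log_q <- stats::plogis(eta, log.p = TRUE, lower.tail = FALSE)
  log_int <- k_by_group * log_p + (n_by_group - k_by_group) * log_q
  lw <- log(gh$w) - 0.5 * log(pi)
  sum(apply(sweep(log_int, 2, lw, "+"), 1, log_sum_exp))
}

#' Fit an intercept-only logistic model with a group random intercept
#'
#' Maximum-likelihood fit of `y_ij ~ Bernoulli(plogis(mu + u_i))` with
#' `u_i ~ N(0, sigma^2)`, the variance-components model underlying the
#' repeatability of a binary trait. The per-group marginal likelihood is
#' integrated by fixed-order Gauss--Hermite quadrature and the two parameters
#' are maximised on `(mu, log sigma)` with sigma floored at 1e-10, so the
#' variance estimate is constrained non-negative.
#'
#' @param outcomes Binary vector (0/1, logical, or `"M"`/`"F"` with `"M"` as
#'   success).
#' @param group_ids Grouping identifiers, same length as `outcomes`; at least
#'   two groups.
#' @param nodes Quadrature order (default 20, minimum 15).
#' @return Object of class `binary_intercept_fit`: list with `mu`,
#'   `sigma2_group`, `logLik`, `converged`, `separation` (all outcomes
#'   identical), `n_groups`, `n_obs`, and the per-group sufficient statistics.
#' @seealso [repeatability_latent()], [rpt_binary()]
#' @export
fit_binary_intercept_model <- function(outcomes, group_ids, nodes = 20) {
  y <- coerce_binary(outcomes)
  stopifnot(length(y) == length(group_ids), nodes >= 15)
  groups <- factor(group_ids)
  if (nlevels(groups) < 2) {
    stop("at least two groups are required", call. = FALSE)
  }
  k_by_group <- as.vector(tapply(y, groups, sum))
  n_by_group <- as.vector(tapply(y, groups, length))
  gh <- pracma::gaussHermite(nodes)
  separation <- all(y == 1) || all(y == 0)
  nll <- function(par) {
    -binary_intercept_loglik(par[1], exp(par[2]), k_by_group, n_by_group, gh)
  }
  start_mu <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  opt <- stats::optim(
    c(start_mu, log(0.5)), nll, method = "L-BFGS-B",
    lower = c(-30, log(1e-10)), upper = c(30, log(50)),
    control = list(factr = 1e7, maxit = 500)
  )
  structure(
    list(
      mu = opt$par[1], sigma2_group = exp(opt$par[2])^2,
      logLik = -opt$value, converged = opt$convergence == 0,
      separation = separation,
      n_groups = nlevels(groups), n_obs = length(y),
      k_by_group = as.integer(k_by_group),
      n_by_group = as.integer(n_by_group),
      nodes = nodes
    ),
    class = "binary_intercept_fit"
  )
}

coerce_binary <- function(outcomes) {
  if (is.character(outcomes) || is.factor(outcomes)) {
    outcomes <- as.character(outcomes)
    stopifnot(all(outcomes %in% SEX_LEVELS))
    as.integer(outcomes == "M")
  } else {
    y <- as.integer(outcomes)
    stopifnot(all(y %in% 0:1))
    y
  }
}

#' Latent-scale repeatability of a binary trait
#'
#' Proportion of latent (logit-link) variance attributable to among-group
#' differences: `r = sigma2 / (sigma2 + pi^2 / 3)`, where `pi^2 / 3` is the
#' residual variance of the standard logistic distribution.
#'
#' @param fit A `binary_intercept_fit`, or a non-negative variance.
#' @return Repeatability in `[0, 1]`.
#' @examples
#' repeatability_latent(pi^2 / 3) # 0.5
#' @export
repeatability_latent <- function(fit) {
  sigma2 <- if (inherits(fit, "binary_intercept_fit")) fit$sigma2_group else fit
  stopifnot(sigma2 >= 0)
  sigma2 / (sigma2 + pi^2 / 3)
}

#' Repeatability of a binary trait with a parametric bootstrap
#'
#' Fits the intercept-only logistic mixed model, computes the latent-scale
#' repeatability, and obtains its uncertainty by a parametric bootstrap:
#' `n_boot` datasets are simulated from the fitted model on the observed group
#' structure, the model is refit on each and the repeatability recomputed.
#' The bootstrap standard deviation is reported as the SE and the 2.5% /
#' 97.5% percentiles as the 95% CI (truncated at the 0 boundary by
#' construction, since the variance is constrained non-negative).
#'
#' @inheritParams fit_binary_intercept_model
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `repeatability_result`: list with `r`, `se`,
#'   `ci_lo`, `ci_hi`, `sigma2_group`, `n_groups`, `n_obs`, `n_boot`,
#'   `n_failed` and the underlying `fit`.
#' @export
rpt_binary <- function(outcomes, group_ids, n_boot = 1000, seed = NULL,
                       nodes = 20) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_binary_intercept_model(outcomes, group_ids, nodes = nodes)
  r_hat <- repeatability_latent(fit)
  sigma <- sqrt(fit$sigma2_group)
  boots <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    u <- stats::rnorm(fit$n_groups, 0, sigma)
    k_sim <- stats::rbinom(fit$n_groups, fit$n_by_group,
                           stats::plogis(fit$mu + u))
    y_sim <- rep(rep(c(1L, 0L), fit$n_groups),
                 times = as.vector(rbind(k_sim, fit$n_by_group - k_sim)))
    g_sim <- rep(seq_len(fit$n_groups), fit$n_by_group)
    boots[b] <- tryCatch(
      repeatability_latent(
        fit_binary_intercept_model(y_sim, g_sim, nodes = nodes)),
      error = function(e) NA_real_
    )
  }
  n_failed <- sum(is.na(boots))
  if (n_failed > 0.1 * n_boot) {
    stop("more than 10% of bootstrap refits failed (", n_failed, " of ",
         n_boot, ")", call. = FALSE)
  }
  ok <- boots[!is.na(boots)]
  structure(
    list(
      r = r_hat, se = stats::sd(ok),
      ci_lo = unname(stats::quantile(ok, 0.025)),
      ci_hi = unname(stats::quantile(ok, 0.975)),
      sigma2_group = fit$sigma2_group,
      n_groups = fit$n_groups, n_obs = fit$n_obs,
      n_boot = n_boot, n_failed = n_failed, fit = fit
    ),
    class = "repeatability_result"
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "Latent-scale repeatability: r = %.2f +/- %.2f (95%% CI %.2f-%.2f)\n",
    x$r, x$se, x$ci_lo, x$ci_hi))
  cat(sprintf("  %d groups, %d observations, %d bootstrap replicates\n",
              x$n_groups, x$n_obs, x$n_boot))
  invisible(x)
}

#' @export
print.binary_intercept_fit <- function(x, ...) {
  cat(sprintf(
    "Binary random-intercept fit: mu = %.3f, sigma2 = %.4f, logLik = %.3f\n",
    x$mu, x$sigma2_group, x$logLik))
  if (x$separation) cat("  warning: all outcomes identical (separation)\n")
  invisible(x)
}
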