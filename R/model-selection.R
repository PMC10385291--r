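#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; the correction vanishes as
#' `n` grows, recovering AIC.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of estimated parameters (intercept + fixed effects +
#'   variance components).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc score.
#' @examples
#' aicc(-100, 3, 1000) # 206.0241
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights of a model set
#'
#' Normalised evidence weights `w_i = exp(-delta_i / 2) / sum_j
#' exp(-delta_j / 2)` computed from the AICc differences to the best model,
#' which keeps the exponentials in range.
#'
#' @param aicc_values Numeric vector of AICc scores.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' round(akaike_weights(c(100, 102)), 3) # 0.731 0.269
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

# registry of model terms: formula fragment and record columns each one needs
TERM_REGISTRY <- list(
  insularity = list(expr = "insularity", cols = "insularity"),
  region = list(expr = "region", cols = "region"),
  madcow = list(expr = "madcow_period", cols = "madcow_period"),
  hatching_date = list(expr = "hatching_date_sc", cols = "hatching_date"),
  brood_size = list(expr = "factor(brood_size)", cols = "brood_size"),
  order = list(expr = "hatching_order", cols = "hatching_order"),
  unit = list(expr = "breeding_unit", cols = "breeding_unit"),
  age = list(expr = "age", cols = "age"),
  age_cat3 = list(expr = "age_cat3", cols = "age"),
  age_cat2 = list(expr = "age_cat2", cols = "age")
)

# variable pools per scale of analysis
SCALE_VARIABLES <- list(
  all = c("insularity", "region", "madcow", "brood_size", "order",
          "hatching_date"),
  peninsular = c("region", "madcow", "brood_size", "order", "hatching_date"),
  canary = c("madcow", "brood_size", "order", "hatching_date", "unit"),
  balearic = c("brood_size", "madcow")
)

#' Enumerate additive candidate models for a scale of analysis
#'
#' All additive subsets (no interactions) of the explanatory variables
#' available at a given scale, always including the empty (null) model.
#' Subsets that would give a rank-deficient design are excluded: `region`
#' together with `insularity` (insularity is a function of region) and
#' `brood_size` together with `order` (a two-nestling brood is exactly a
#' first- or second-hatched nestling). The parental-age scales hold a single
#' age variable under the requested coding.
#'
#' @param scale One of `"all"`, `"peninsular"`, `"canary"`, `"balearic"`,
#'   `"parental_age"`.
#' @param age_coding For `scale = "parental_age"`: `"raw"` (age in years),
#'   `"cat3"` (`<6`, `6-15`, `>15`) or `"cat2"` (`<=7`, `>=8`).
#' @return List of character vectors of term names; the first element is
#'   `character(0)`, the null model.
#' @export
enumerate_candidates <- function(scale = c("all", "peninsular", "canary",
                                           "balearic", "parental_age"),
                                 age_coding = c("raw", "cat3", "cat2")) {
  scale <- match.arg(scale)
  if (scale == "parental_age") {
    age_coding <- match.arg(age_coding)
    term <- switch(age_coding, raw = "age", cat3 = "age_cat3",
                   cat2 = "age_cat2")
    return(list(character(0), term))
  }
  vars <- SCALE_VARIABLES[[scale]]
  subsets <- list(character(0))
  for (v in vars) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, v)))
  }
  keep <- vapply(subsets, function(s) {
    !(all(c("region", "insularity") %in% s)) &&
      !(all(c("brood_size", "order") %in% s))
  }, logical(1))
  subsets[keep]
}

# prepare the analysis data for a set of terms: listwise deletion on every
# column the terms need, factor coding, scaled hatching date, binary response
prepare_model_data <- function(records, terms, response = "male") {
  cols_needed <- unique(c("sex", unlist(lapply(TERM_REGISTRY[terms],
                                               `[[`, "cols"))))
  cols_needed <- intersect(cols_needed, names(records))
  keep <- stats::complete.cases(records[, cols_needed, drop = FALSE])
  d <- records[keep, , drop = FALSE]
  d$male <- as.integer(d$sex == "M")
  if ("insularity" %in% names(d)) {
    d$insularity <- factor(d$insularity, levels = c("mainland", "island"))
  }
  if ("region" %in% names(d)) d$region <- factor(d$region)
  if ("madcow_period" %in% names(d)) {
    d$madcow_period <- factor(d$madcow_period, levels = PERIOD_LEVELS)
  }
  if ("hatching_order" %in% names(d)) {
    d$hatching_order <- factor(d$hatching_order, levels = ORDER_LEVELS)
  }
  if ("breeding_unit" %in% names(d)) {
    d$breeding_unit <- factor(d$breeding_unit, levels = UNIT_LEVELS)
  }
  if ("hatching_date" %in% names(d)) {
    centre <- mean(d$hatching_date, na.rm = TRUE)
    scl <- stats::sd(d$hatching_date, na.rm = TRUE)
    if (is.na(scl) || scl == 0) scl <- 1
    d$hatching_date_sc <- (d$hatching_date - centre) / scl
    attr(d, "hatching_date_scale") <- c(centre = centre, sd = scl)
  }
  if ("age" %in% names(d)) {
    d$age_cat3 <- cut(d$age, breaks = c(-Inf, 5, 15, Inf),
                      labels = c("subadult", "adult", "old"))
    d$age_cat2 <- cut(d$age, breaks = c(-Inf, 7, Inf),
                      labels = c("young", "old"))
  }
  d
}

#' Fit one candidate (generalised) linear mixed model
#'
#' Fits an additive model for the probability that a nestling is male
#' (binomial family, logit link) or for a Gaussian response, with crossed
#' Gaussian random intercepts estimated by maximum likelihood (Laplace
#' approximation, via \pkg{lme4}). With no random terms the model reduces to
#' an ordinary GLM / linear model. Hatching date is centred and scaled before
#' fitting; its coefficient is also reported back-transformed to the original
#' day scale.
#'
#' @param records Data frame of nestling records (or any data frame holding
#'   the response and term columns).
#' @param fixed_terms Character vector of term names from the registry
#'   (`insularity`, `region`, `madcow`, `hatching_date`, `brood_size`,
#'   `order`, `unit`, `age`, `age_cat3`, `age_cat2`); `character(0)` fits the
#'   null model.
#' @param random_terms Character vector of grouping columns for random
#'   intercepts (default `c("year", "territory_id")`); may be empty.
#' @param family `"binomial"` (logit) or `"gaussian"` (identity).
#' @param response Response column; the default `"male"` is derived from
#'   `sex` when absent.
#' @param data_prepared Set to `TRUE` when `records` already went through the
#'   internal preparation step (used by [model_selection()] so every candidate
#'   sees the same rows).
#' @return Object of class `glmm_fit`: list with the fitted `model`, `terms`,
#'   `label`, `logLik`, `k`, `n`, `aicc`, `converged` and a `coefficients`
#'   data frame (estimate, SE, Wald 95% CI).
#' @export
fit_glmm <- function(records, fixed_terms = character(0),
                     random_terms = c("year", "territory_id"),
                     family = c("binomial", "gaussian"),
                     response = "male", data_prepared = FALSE) {
  family <- match.arg(family)
  bad <- setdiff(fixed_terms, names(TERM_REGISTRY))
  if (length(bad)) {
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- if (data_prepared) records else
    prepare_model_data(records, fixed_terms, response)
  rhs <- if (length(fixed_terms) == 0) "1" else
    paste(vapply(TERM_REGISTRY[fixed_terms], `[[`, "", "expr"),
          collapse = " + ")
  ran <- if (length(random_terms)) {
    paste(sprintf("(1 | %s)", random_terms), collapse = " + ")
  } else {
    NULL
  }
  fml <- stats::as.formula(paste(response, "~", paste(c(rhs, ran),
                                                      collapse = " + ")))
  converged <- TRUE
  model <- withCallingHandlers(
    {
      if (length(random_terms) == 0) {
        if (family == "binomial") {
          stats::glm(fml, data = d, family = stats::binomial())
        } else {
          stats::lm(fml, data = d)
        }
      } else if (family == "binomial") {
        lme4::glmer(fml, data = d, family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = TRUE))
      } else {
        lme4::lmer(fml, data = d, REML = FALSE)
      }
    },
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w),
                ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    },
    message = function(m) {
      # boundary (singular) fits are valid: variances estimated at 0
      if (grepl("boundary \\(singular\\)", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    }
  )
  if (isS4(model)) {
    msgs <- unlist(model@optinfo$conv$lme4)
    if (!is.null(model@optinfo$conv$opt) && model@optinfo$conv$opt != 0) {
      converged <- FALSE
    }
    if (length(msgs) &&
        any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
      converged <- FALSE
    }
  }
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- nrow(d)
  est <- if (isS4(model)) lme4::fixef(model) else stats::coef(model)
  vc <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(vc))
  coefs <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
    stringsAsFactors = FALSE
  )
  hds <- attr(d, "hatching_date_scale")
  if (!is.null(hds) && "hatching_date_sc" %in% coefs$term) {
    i <- coefs$term == "hatching_date_sc"
    coefs$estimate_per_day <- NA_real_
    coefs$estimate_per_day[i] <- coefs$estimate[i] / hds[["sd"]]
  }
  structure(
    list(model = model, terms = fixed_terms, random_terms = random_terms,
         label = if (length(fixed_terms)) paste(fixed_terms, collapse = " + ")
                 else "null",
         family = family, logLik = as.numeric(ll), k = k, n = n,
         aicc = aicc(as.numeric(ll), k, n), converged = converged,
         coefficients = coefs, vcov = vc),
    class = "glmm_fit"
  )
}

#' AICc model selection over a candidate set
#'
#' Fits every candidate model of a scale (or an explicit candidate list) on a
#' common dataset (listwise deletion over the union of the scale's variables,
#' so all AICc values are comparable), drops non-converged fits, and ranks the
#' rest by AICc with differences and Akaike weights. Models within 2 AICc
#' units of the best are flagged as the alternative set.
#'
#' @param records Data frame of nestling records.
#' @param scale Scale of analysis passed to [enumerate_candidates()], or
#'   `NULL` when `candidates` is given.
#' @param candidates Optional list of character vectors of term names.
#' @param random_terms,family,response Passed to [fit_glmm()].
#' @param age_coding Passed to [enumerate_candidates()] for the parental-age
#'   scale.
#' @return Object of class `model_set`: list with `table` (model, df, AICc,
#'   delta, weight, alternative), `fits`, `n` and `n_dropped` (non-converged).
#' @seealso [model_average()]
#' @export
model_selection <- function(records, scale = NULL, candidates = NULL,
                            random_terms = c("year", "territory_id"),
                            family = "binomial", response = "male",
                            age_coding = "raw") {
  if (is.null(candidates)) {
    if (is.null(scale)) stop("give either `scale` or `candidates`",
                             call. = FALSE)
    candidates <- enumerate_candidates(scale, age_coding = age_coding)
  }
  all_terms <- unique(unlist(candidates))
  d <- prepare_model_data(records, all_terms, response)
  fits <- lapply(candidates, function(terms) {
    fit_glmm(d, terms, random_terms = random_terms, family = family,
             response = response, data_prepared = TRUE)
  })
  converged <- vapply(fits, `[[`, logical(1), "converged")
  n_dropped <- sum(!converged)
  fits <- fits[converged]
  if (!length(fits)) stop("no candidate model converged", call. = FALSE)
  scores <- vapply(fits, `[[`, numeric(1), "aicc")
  ord <- order(scores)
  fits <- fits[ord]
  scores <- scores[ord]
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "label"),
    df = vapply(fits, `[[`, numeric(1), "k"),
    AICc = scores,
    delta = scores - min(scores),
    weight = akaike_weights(scores),
    stringsAsFactors = FALSE
  )
  tab$alternative <- tab$delta < 2
  structure(
    list(table = tab, fits = fits, n = fits[[1]]$n, n_dropped = n_dropped),
    class = "model_set"
  )
}

#' Model-averaged effects over the alternative set
#'
#' Averages coefficients over the models within 2 AICc units of the best,
#' with their Akaike weights renormalised inside that set. The default
#' `"full"` (zero-substitution) average treats a coefficient as 0 with SE 0 in
#' models that omit it; `"conditional"` averages only over the models that
#' contain it. The unconditional SE combines within-model sampling variance
#' and between-model spread,
#' `SE = sum_i w_i * sqrt(se_i^2 + (b_i - b_bar)^2)`. Each averaged effect is
#' labelled `strong` when its 95% CI excludes zero, `weak` when the CI covers
#' zero but the estimate exceeds its SE in magnitude, and `none` otherwise.
#'
#' @param model_set A `model_set` from [model_selection()].
#' @param method `"full"` (default) or `"conditional"`.
#' @return Data frame of class `averaged_effects`: `term`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `support`.
#' @export
model_average <- function(model_set, method = c("full", "conditional")) {
  method <- match.arg(method)
  alt <- model_set$fits[model_set$table$alternative]
  if (!length(alt)) stop("no alternative models (delta < 2)", call. = FALSE)
  w <- model_set$table$weight[model_set$table$alternative]
  w <- w / sum(w)
  coef_names <- unique(unlist(lapply(alt, function(f) f$coefficients$term)))
  rows <- lapply(coef_names, function(nm) {
    b <- vapply(alt, function(f) {
      i <- match(nm, f$coefficients$term)
      if (is.na(i)) 0 else f$coefficients$estimate[i]
    }, numeric(1))
    s <- vapply(alt, function(f) {
      i <- match(nm, f$coefficients$term)
      if (is.na(i)) 0 else f$coefficients$se[i]
    }, numeric(1))
    present <- vapply(alt, function(f) nm %in% f$coefficients$term, logical(1))
    if (method == "conditional") {
      wc <- w[present] / sum(w[present])
      b <- b[present]; s <- s[present]
    } else {
      wc <- w
    }
    bbar <- sum(wc * b)
    se <- sum(wc * sqrt(s^2 + (b - bbar)^2))
    ci_lo <- bbar - 1.96 * se
    ci_hi <- bbar + 1.96 * se
    support <- if (ci_lo > 0 || ci_hi < 0) "strong"
      else if (abs(bbar) > se) "weak" else "none"
    data.frame(term = nm, estimate = bbar, se = se, ci_lo = ci_lo,
               ci_hi = ci_hi, support = support, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("averaged_effects", "data.frame")
  out
}

#' Bonferroni-adjusted pairwise contrasts of a factor
#'
#' Wald contrasts between all level pairs of a fixed factor in a fitted
#' model, with p-values multiplied by the number of comparisons (capped at 1).
#'
#' @param fit A `glmm_fit` containing the factor.
#' @param factor_term Term name as used in [fit_glmm()] (e.g. `"madcow"`).
#' @return Data frame with `contrast`, `estimate`, `se`, `z`, `p_adjusted`.
#' @export
posthoc_bonferroni <- function(fit, factor_term) {
  if (!factor_term %in% fit$terms) {
    stop("term '", factor_term, "' is not in the model", call. = FALSE)
  }
  expr <- TERM_REGISTRY[[factor_term]]$expr
  cn <- fit$coefficients$term
  idx <- grep(paste0("^", gsub("([()])", "\\\\\\1", expr)), cn)
  if (!length(idx)) stop("'", factor_term, "' has no factor coefficients",
                         call. = FALSE)
  levels_all <- c("(reference)", cn[idx])
  m <- length(idx) + 1
  combs <- utils::combn(m, 2)
  n_comp <- ncol(combs)
  vc <- fit$vcov
  est_of <- function(i) if (i == 1) 0 else fit$coefficients$estimate[idx[i - 1]]
  var_of <- function(i, j) {
    v <- 0
    if (i > 1) v <- v + vc[idx[i - 1], idx[i - 1]]
    if (j > 1) v <- v + vc[idx[j - 1], idx[j - 1]]
    if (i > 1 && j > 1) v <- v - 2 * vc[idx[i - 1], idx[j - 1]]
    v
  }
  rows <- lapply(seq_len(n_comp), function(c_) {
    i <- combs[1, c_]; j <- combs[2, c_]
    est <- est_of(j) - est_of(i)
    se <- sqrt(var_of(i, j))
    z <- est / se
    data.frame(
      contrast = paste(levels_all[j], "-", levels_all[i]),
      estimate = est, se = se, z = z,
      p_adjusted = min(1, 2 * stats::pnorm(-abs(z)) * n_comp),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Variance inflation factors of continuous covariates
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing covariate `j`
#' on the remaining covariates; perfect collinearity is reported as `Inf`.
#'
#' @param data Data frame holding the covariates.
#' @param terms Character vector of at least two column names.
#' @return Named numeric vector of VIFs.
#' @export
vif_terms <- function(data, terms) {
  stopifnot(length(terms) >= 2, all(terms %in% names(data)))
  d <- data[stats::complete.cases(data[, terms, drop = FALSE]), terms,
            drop = FALSE]
  vapply(terms, function(t_) {
    fml <- stats::as.formula(
      paste(t_, "~", paste(setdiff(terms, t_), collapse = " + ")))
    # a perfect fit is legitimate input here (it signals aliasing), so the
    # "essentially perfect fit" warning is noise
    r2 <- suppressWarnings(summary(stats::lm(fml, data = d))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' @export
print.model_set <- function(x, digits = 2, ...) {
  cat("AICc model selection (", nrow(x$table), " converged models, n = ",
      x$n, ")\n", sep = "")
  if (x$n_dropped) cat("  dropped", x$n_dropped, "non-converged model(s)\n")
  tab <- x$table
  tab$AICc <- round(tab$AICc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(utils::head(tab, 10))
  if (nrow(tab) > 10) cat("  ... and", nrow(tab) - 10, "more models\n")
  invisible(x)
}

#' @export
print.glmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Model [%s], %s family, n = %d\n", x$label, x$family, x$n))
  cat(sprintf("  logLik = %.3f, k = %d, AICc = %.2f, converged = %s\n",
              x$logLik, x$k, x$aicc, x$converged))
  coefs <- x$coefficients
  coefs[-1] <- lapply(coefs[-1], round, digits)
  print(coefs)
  invisible(x)
}
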