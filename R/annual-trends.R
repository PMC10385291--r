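#' Annual sex ratios from nestling records
#'
#' @param records Data frame of validated nestling records.
#' @return Data frame with `year`, `n`, `males` and `ratio` (proportion male).
#' @export
annual_sex_ratio <- function(records) {
  years <- sort(unique(records$year))
  out <- data.frame(year = years)
  out$n <- vapply(years, function(y) sum(records$year == y), integer(1))
  out$males <- vapply(years, function(y) {
    sum(records$year == y & records$sex == "M")
  }, integer(1))
  out$ratio <- out$males / out$n
  out
}

#' Add lagged population-trend covariates to annual counts
#'
#' For each lag `k`, `trend_lag_k = pairs(t) - pairs(t - k)`: the change in
#' the number of breeding pairs relative to `k` years earlier. Years whose
#' lagged count is outside the series are `NA`.
#'
#' @param annual Data frame with columns `year` and `pairs` (annual number of
#'   breeding pairs).
#' @param lags Integer vector of lags (default `1:7`, spanning the typical age
#'   at first reproduction).
#' @return `annual` with one `trend_lag_<k>` column per lag.
#' @export
add_trend_lags <- function(annual, lags = 1:7) {
  stopifnot(all(c("year", "pairs") %in% names(annual)))
  for (k in lags) {
    annual[[paste0("trend_lag_", k)]] <-
      annual$pairs - annual$pairs[match(annual$year - k, annual$year)]
  }
  annual
}

#' Density and population-trend models for the annual sex ratio
#'
#' Fits one Gaussian GLM (identity link) of the annual offspring sex ratio on
#' each requested predictor — conspecific density (`pairs`) and/or the lagged
#' population-trend variables — plus the null model, on the common set of
#' years where every predictor is available, and compares them by AICc. A
#' predictor is labelled unsupported when its model sits more than 2 AICc
#' units above the best model of the set.
#'
#' @param annual Data frame with columns `year`, `ratio`, `pairs` (and any
#'   `trend_lag_*` columns; missing ones are derived via [add_trend_lags()]).
#' @param predictors Character vector out of `"density"` and
#'   `"trend_lag_1"` ... `"trend_lag_7"`.
#' @return Object of class `annual_ratio_models`: list with `table` (model,
#'   df, AICc, delta, weight, supported), `fits` (the `lm` objects) and `n`.
#' @export
annual_ratio_glm <- function(annual,
                             predictors = c("density",
                                            paste0("trend_lag_", 1:7))) {
  stopifnot(all(c("year", "ratio", "pairs") %in% names(annual)))
  lags_needed <- grep("^trend_lag_", predictors, value = TRUE)
  missing_lags <- setdiff(lags_needed, names(annual))
  if (length(missing_lags)) {
    annual <- add_trend_lags(annual,
                             as.integer(sub("trend_lag_", "", missing_lags)))
  }
  cols <- ifelse(predictors == "density", "pairs", predictors)
  d <- annual[stats::complete.cases(annual[, c("ratio", cols), drop = FALSE]),
              , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 years of complete data",
                        call. = FALSE)
  for (col in unique(cols)) {
    if (stats::sd(d[[col]]) == 0) {
      stop("predictor '", col, "' is constant over the analysis years",
           call. = FALSE)
    }
  }
  fits <- c(list(null = stats::lm(ratio ~ 1, data = d)),
            stats::setNames(lapply(cols, function(col) {
              stats::lm(stats::as.formula(paste("ratio ~", col)), data = d)
            }), predictors))
  scores <- vapply(fits, function(m) {
    ll <- stats::logLik(m)
    aicc(as.numeric(ll), attr(ll, "df"), nrow(d))
  }, numeric(1))
  ord <- order(scores)
  tab <- data.frame(
    model = names(fits)[ord],
    df = vapply(fits[ord], function(m) attr(stats::logLik(m), "df"),
                numeric(1)),
    AICc = scores[ord],
    delta = scores[ord] - min(scores),
    weight = akaike_weights(scores[ord]),
    stringsAsFactors = FALSE
  )
  tab$supported <- tab$delta <= 2
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], n = nrow(d)),
            class = "annual_ratio_models")
}

#' @export
print.annual_ratio_models <- function(x, digits = 2, ...) {
  cat("Annual sex-ratio models (Gaussian, identity link), n =", x$n, "years\n")
  tab <- x$table
  tab$AICc <- round(tab$AICc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(tab)
  invisible(x)
}
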