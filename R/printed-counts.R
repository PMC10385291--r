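#' Regional counts of sexed Egyptian vulture nestlings
#'
#' Numbers of male and female nestlings sexed per breeding region by the
#' long-term Spanish monitoring programmes (1995--2021), as published for the
#' mainland (Andalusia, Aragon, Navarra, Segovia) and island (Canary,
#' Balearic) populations. These counts are the inputs for the region-level
#' parity tests; pooled strata can be added with `pooled = TRUE`.
#'
#' @param pooled If `TRUE` (default), append the pooled "Peninsular",
#'   "Islands" and "All" strata obtained by summing the region rows.
#' @return Data frame with columns `region`, `n`, `males`, `females`.
#' @seealso [parity_table()], [brood_combination_counts()]
#' @export
region_sex_counts <- function(pooled = TRUE) {
  base <- data.frame(
    region = c("Andalusia", "Aragon", "Navarra", "Segovia",
               "Canary", "Balearic"),
    males = c(123L, 113L, 208L, 84L, 275L, 26L),
    females = c(145L, 124L, 217L, 98L, 224L, 24L),
    stringsAsFactors = FALSE
  )
  if (pooled) {
    mainland <- base$region %in% MAINLAND_REGIONS
    pool_row <- function(name, idx) {
      data.frame(region = name,
                 males = sum(base$males[idx]),
                 females = sum(base$females[idx]),
                 stringsAsFactors = FALSE)
    }
    base <- rbind(
      pool_row("Peninsular", mainland),
      base[mainland, ],
      pool_row("Islands", !mainland),
      base[!mainland, ],
      pool_row("All", rep(TRUE, nrow(base)))
    )
  }
  base$n <- base$males + base$females
  rownames(base) <- NULL
  base[, c("region", "n", "males", "females")]
}

#' Published sex combinations of double broods by region
#'
#' Counts of two-nestling broods per region classified by sex combination in
#' hatching order: `mm` (two males), `ff` (two females), `mf` (male first,
#' female second) and `fm` (female first, male second). Order information was
#' unavailable for the Balearic Islands, so its mixed-brood cells are `NA`.
#'
#' @param pooled If `TRUE` (default), append pooled "Peninsular", "Islands"
#'   and "All" strata (sums of the region rows; `NA` cells propagate only when
#'   every summand is `NA`).
#' @return Data frame with columns `region`, `mm`, `ff`, `mf`, `fm`.
#' @seealso [combination_tests()]
#' @export
brood_combination_counts <- function(pooled = TRUE) {
  base <- data.frame(
    region = c("Andalusia", "Aragon", "Navarra", "Segovia",
               "Canary", "Balearic"),
    mm = c(12L, 14L, 38L, 13L, 27L, 4L),
    ff = c(15L, 22L, 34L, 13L, 12L, 1L),
    mf = c(11L, 15L, 31L, 14L, 20L, NA),
    fm = c(21L, 22L, 24L, 16L, 12L, NA),
    stringsAsFactors = FALSE
  )
  if (pooled) {
    mainland <- base$region %in% MAINLAND_REGIONS
    pool_row <- function(name, idx) {
      sums <- lapply(base[idx, c("mm", "ff", "mf", "fm")], function(v) {
        if (all(is.na(v))) NA_integer_ else sum(v, na.rm = TRUE)
      })
      cbind(data.frame(region = name, stringsAsFactors = FALSE),
            as.data.frame(sums))
    }
    base <- rbind(
      pool_row("Peninsular", mainland),
      base[mainland, ],
      pool_row("Islands", !mainland),
      base[!mainland, ],
      pool_row("All", rep(TRUE, nrow(base)))
    )
  }
  rownames(base) <- NULL
  base
}
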