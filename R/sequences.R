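#' Longest run of a given sex in a sequence
#'
#' @param sexes Character vector of `"M"` / `"F"`.
#' @param value The sex whose longest consecutive run is wanted.
#' @return Integer run length (0 when the sex is absent).
#' @keywords internal
max_run <- function(sexes, value) {
  r <- rle(sexes)
  hit <- r$values == value
  if (!any(hit)) 0L else max(r$lengths[hit])
}

# identity of the breeding unit a record belongs to, per unit kind
unit_identity <- function(records, unit_kind) {
  switch(unit_kind,
    female = records$mother_id,
    pair = ifelse(is.na(records$mother_id) | is.na(records$father_id) |
                    is.na(records$breeding_unit) |
                    records$breeding_unit != "pair",
                  NA, paste(records$mother_id, records$father_id, sep = "+")),
    trio = ifelse(is.na(records$mother_id) | is.na(records$father_id) |
                    is.na(records$breeding_unit) |
                    records$breeding_unit != "trio",
                  NA, paste(records$mother_id, records$father_id, sep = "+"))
  )
}

#' Build chronological offspring sex sequences per breeding unit
#'
#' Orders each unit's sexed offspring by year and, within a year, by hatching
#' order (singles and first-hatched before second-hatched), and summarises the
#' same-sex runs. Gap years do not break a run: the offspring sequence, not
#' the calendar, is treated as consecutive. Units with fewer than
#' `min_offspring` sexed nestlings are dropped, as are records without an
#' identity for the chosen unit kind.
#'
#' @param records Data frame of validated nestling records.
#' @param unit_kind `"female"` (identity = mother), `"pair"` or `"trio"`
#'   (identity = parent pair restricted to that breeding-unit type).
#' @param min_offspring Minimum sequence length to keep a unit (default 2).
#' @return Data frame of class `unit_sequences`: one row per unit with
#'   `unit_id`, `unit_kind`, `n`, `sexes` (collapsed string, e.g. `"MFM"`),
#'   `max_run_M`, `max_run_F`, `all_same_sex`.
#' @export
build_sequences <- function(records, unit_kind = c("female", "pair", "trio"),
                            min_offspring = 2) {
  unit_kind <- match.arg(unit_kind)
  ids <- unit_identity(records, unit_kind)
  keep <- !is.na(ids) & records$sex %in% SEX_LEVELS
  recs <- records[keep, , drop = FALSE]
  ids <- ids[keep]
  order_rank <- match(recs$hatching_order, ORDER_LEVELS)
  order_rank[is.na(order_rank)] <- 1.5  # unknown order keeps input position
  rows <- lapply(split(seq_len(nrow(recs)), ids), function(idx) {
    idx <- idx[order(recs$year[idx], order_rank[idx])]
    sexes <- recs$sex[idx]
    if (length(sexes) < min_offspring) return(NULL)
    rm_ <- max_run(sexes, "M")
    rf_ <- max_run(sexes, "F")
    data.frame(
      unit_id = ids[idx[1]], unit_kind = unit_kind, n = length(sexes),
      sexes = paste(sexes, collapse = ""),
      max_run_M = rm_, max_run_F = rf_,
      all_same_sex = max(rm_, rf_) == length(sexes),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(unit_id = character(0), unit_kind = character(0),
                      n = integer(0), sexes = character(0),
                      max_run_M = integer(0), max_run_F = integer(0),
                      all_same_sex = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("unit_sequences", "data.frame")
  out
}

#' Test for a bias in long same-sex runs across breeding units
#'
#' Counts the units whose longest male run reaches `run_length` and those
#' whose longest female run does, and compares the two tallies with an exact
#' two-sided binomial test against 0.5. A unit with both a qualifying male
#' and a qualifying female run contributes to both tallies.
#'
#' @param sequences A `unit_sequences` data frame from [build_sequences()].
#' @param run_length Minimum run length that qualifies (default 4).
#' @return List of class `run_bias_test`: `units_male_run`,
#'   `units_female_run`, `run_length`, and `test` (a `binom_test_result`, or
#'   `NULL` with `no_test = TRUE` when neither tally is positive).
#' @examples
#' # eleven male-run units vs three female-run units
#' binom_two_sided(11, 14)$p_two_sided # 0.0574
#' @export
run_bias_test <- function(sequences, run_length = 4) {
  stopifnot(nrow(sequences) > 0)
  m <- sum(sequences$max_run_M >= run_length)
  f <- sum(sequences$max_run_F >= run_length)
  res <- list(units_male_run = m, units_female_run = f,
              run_length = run_length)
  if (m + f == 0) {
    res$test <- NULL
    res$no_test <- TRUE
  } else {
    res$test <- binom_two_sided(m, m + f)
    res$no_test <- FALSE
  }
  structure(res, class = "run_bias_test")
}

#' Parity test of a single unit's offspring sequence
#'
#' Exact two-sided binomial test of whether one breeding unit's offspring sex
#' ratio deviates from 0.5, with the majority sex as the success count. Used
#' for striking sequences such as a trio raising only males.
#'
#' @param sequence One row of a `unit_sequences` data frame (or any list with
#'   `sexes` as a collapsed string).
#' @return A `binom_test_result`.
#' @examples
#' seqs <- data.frame(sexes = "MMMMMMMMM")
#' all_same_sex_test(seqs[1, ])$p_two_sided # 0.0039
#' @export
all_same_sex_test <- function(sequence) {
  sexes <- strsplit(sequence$sexes, "")[[1]]
  stopifnot(length(sexes) >= 1)
  k <- max(sum(sexes == "M"), sum(sexes == "F"))
  binom_two_sided(k, length(sexes))
}

#' @export
print.run_bias_test <- function(x, ...) {
  cat(sprintf("Same-sex run bias (runs >= %d): %d male-run vs %d female-run units\n",
              x$run_length, x$units_male_run, x$units_female_run))
  if (isTRUE(x$no_test)) {
    cat("  no qualifying runs; no test performed\n")
  } else {
    cat(sprintf("  two-sided binomial p = %.4f\n", x$test$p_two_sided))
  }
  invisible(x)
}
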