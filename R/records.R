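#' @keywords internal
"_PACKAGE"

#' Region and factor level constants
#'
#' The six breeding nuclei covered by the monitoring programmes, split into
#' mainland (peninsular Spain) and island groups, plus the levels used for
#' sexes, hatching order, breeding units and the food-availability periods
#' defined by the EU carcass-disposal regulations ("mad-cow" crisis).
#'
#' @name region_levels
#' @keywords internal
NULL

MAINLAND_REGIONS <- c("Andalusia", "Aragon", "Navarra", "Segovia")
ISLAND_REGIONS <- c("Canary", "Balearic")
ALL_REGIONS <- c(MAINLAND_REGIONS, ISLAND_REGIONS)
SEX_LEVELS <- c("M", "F")
ORDER_LEVELS <- c("single", "first", "second")
UNIT_LEVELS <- c("pair", "trio")
PERIOD_LEVELS <- c("pre", "restrictive", "post")

RECORD_COLUMNS <- c(
  "nestling_id", "region", "insularity", "territory_id", "year",
  "hatching_date", "brood_size", "hatching_order", "sex", "breeding_unit",
  "mother_id", "father_id", "mother_age", "father_age", "madcow_period"
)

#' Assign the food-availability period of a year
#'
#' Maps calendar years to the three stages of the mad-cow crisis used as a
#' food-availability proxy: the pre-restrictive period (1990--2001) with
#' abundant livestock carcasses, the restrictive period (2002--2011) when
#' carcass abandonment was curtailed by sanitary regulation, and the
#' post-restrictive period (2012 onwards) when availability recovered.
#'
#' @param year Integer vector of calendar years, all `>= 1990`.
#' @return Character vector with values `"pre"`, `"restrictive"` or `"post"`.
#' @examples
#' assign_madcow_period(c(2001, 2002, 2012))
#' @export
assign_madcow_period <- function(year) {
  year <- as.integer(year)
  if (anyNA(year)) stop("`year` contains missing values", call. = FALSE)
  if (any(year < 1990)) {
    stop("`year` must be >= 1990 (periods are defined from 1990 onwards)",
         call. = FALSE)
  }
  out <- ifelse(year <= 2001, "pre", ifelse(year <= 2011, "restrictive", "post"))
  out
}

#' Age calibration for back-calculating hatching dates
#'
#' Container for the linear regression relating the length of the seventh
#' primary feather to nestling age (age in days = intercept + slope * length),
#' plus the hatching lag assumed for second-hatched nestlings of double broods.
#' The regression coefficients come from an external growth study and are
#' therefore user supplied, not hard-coded.
#'
#' @param intercept Intercept of the age regression, in days.
#' @param slope Slope of the age regression, in days per mm of seventh-primary
#'   length.
#' @param sibling_lag Days by which a second-hatched nestling is assumed to
#'   hatch after its older sibling. Default 5.
#' @return An object of class `age_calibration`.
#' @export
age_calibration <- function(intercept, slope, sibling_lag = 5) {
  stopifnot(is.finite(intercept), is.finite(slope))
  if (sibling_lag < 0) stop("`sibling_lag` must be >= 0", call. = FALSE)
  structure(
    list(intercept = intercept, slope = slope, sibling_lag = sibling_lag),
    class = "age_calibration"
  )
}

#' Back-calculate a hatching date from banding data
#'
#' Estimates age at banding from wing (seventh primary) length through an
#' [age_calibration()] and subtracts it from the banding date, on the Julian
#' scale (day 1 = January 1). Second-hatched nestlings are dated relative to
#' their older sibling instead, using the calibration's `sibling_lag`.
#'
#' @param banding_julian Julian day of banding.
#' @param wing_length Seventh-primary length in mm (ignored for
#'   `order = "second"`).
#' @param calibration An [age_calibration()] object.
#' @param order `"single"` or `"first"` to use the wing regression, `"second"`
#'   to date relative to `sibling_hatch`.
#' @param sibling_hatch Estimated Julian hatching day of the older sibling
#'   (required when `order = "second"`).
#' @return Integer Julian hatching day.
#' @examples
#' cal <- age_calibration(intercept = 0, slope = 1)
#' backcalc_hatching_date(200, 60, cal)                  # 140
#' backcalc_hatching_date(NA, NA, cal, order = "second", sibling_hatch = 140)
#' @export
backcalc_hatching_date <- function(banding_julian, wing_length, calibration,
                                   order = c("single", "first", "second"),
                                   sibling_hatch = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(calibration, "age_calibration"))
  if (order == "second") {
    if (is.null(sibling_hatch)) {
      stop("`sibling_hatch` is required for second-hatched nestlings",
           call. = FALSE)
    }
    return(as.integer(round(sibling_hatch + calibration$sibling_lag)))
  }
  if (wing_length <= 0) stop("`wing_length` must be > 0", call. = FALSE)
  age <- calibration$intercept + calibration$slope * wing_length
  if (age <= 0) {
    stop("calibration yields non-positive age (", round(age, 2), " days)",
         call. = FALSE)
  }
  as.integer(banding_julian - round(age))
}

# Row-level invariant checks shared by load_records() and the generator.
# Returns a character vector of messages, zero-length when the row set is clean.
check_record_invariants <- function(df) {
  msgs <- character(0)
  bad <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      sprintf("rows %s: %s", paste(which(idx), collapse = ","), what)
    } else {
      character(0)
    }
  }
  msgs <- c(msgs, bad(!(df$sex %in% SEX_LEVELS), "sex must be 'M' or 'F'"))
  msgs <- c(msgs, bad(!(df$region %in% ALL_REGIONS),
                      paste("unknown region; expected one of",
                            paste(ALL_REGIONS, collapse = ", "))))
  if ("insularity" %in% names(df)) {
    expected <- ifelse(df$region %in% ISLAND_REGIONS, "island", "mainland")
    msgs <- c(msgs, bad(!is.na(df$insularity) & df$region %in% ALL_REGIONS &
                          df$insularity != expected,
                        "insularity inconsistent with region"))
  }
  if ("brood_size" %in% names(df)) {
    msgs <- c(msgs, bad(!is.na(df$brood_size) & !(df$brood_size %in% 1:2),
                        "brood_size must be 1 or 2"))
    if ("hatching_order" %in% names(df)) {
      ord <- df$hatching_order
      msgs <- c(msgs, bad(!is.na(ord) & !(ord %in% ORDER_LEVELS),
                          "unknown hatching_order"))
      msgs <- c(msgs, bad(!is.na(ord) & !is.na(df$brood_size) &
                            df$brood_size == 1 & ord != "single",
                          "brood_size 1 requires hatching_order 'single'"))
      msgs <- c(msgs, bad(!is.na(ord) & !is.na(df$brood_size) &
                            df$brood_size == 2 & !(ord %in% c("first", "second")),
                          "brood_size 2 requires hatching_order 'first' or 'second'"))
    }
  }
  if ("hatching_date" %in% names(df)) {
    hd <- df$hatching_date
    msgs <- c(msgs, bad(!is.na(hd) & (hd < 1 | hd > 366),
                        "hatching_date must be a Julian day in [1, 366]"))
  }
  if ("breeding_unit" %in% names(df)) {
    msgs <- c(msgs, bad(!is.na(df$breeding_unit) &
                          !(df$breeding_unit %in% UNIT_LEVELS),
                        "breeding_unit must be 'pair' or 'trio'"))
  }
  msgs <- c(msgs, bad(is.na(df$year) | df$year < 1990, "year missing or < 1990"))
  msgs
}

# Per-row validity mask used to split loaded rows into accepted/rejected.
record_row_valid <- function(df) {
  ok <- df$sex %in% SEX_LEVELS &
    df$region %in% ALL_REGIONS &
    !is.na(df$year) & df$year >= 1990
  if ("brood_size" %in% names(df)) {
    ok <- ok & (is.na(df$brood_size) | df$brood_size %in% 1:2)
    if ("hatching_order" %in% names(df)) {
      ord <- df$hatching_order
      ok <- ok & (is.na(ord) | ord %in% ORDER_LEVELS)
      both <- !is.na(ord) & !is.na(df$brood_size)
      ok <- ok & (!both | (df$brood_size == 1) == (ord == "single"))
    }
  }
  if ("hatching_date" %in% names(df)) {
    hd <- df$hatching_date
    ok <- ok & (is.na(hd) | (hd >= 1 & hd <= 366))
  }
  if ("breeding_unit" %in% names(df)) {
    bu <- df$breeding_unit
    ok <- ok & (is.na(bu) | bu %in% UNIT_LEVELS)
  }
  if ("insularity" %in% names(df)) {
    expected <- ifelse(df$region %in% ISLAND_REGIONS, "island", "mainland")
    ok <- ok & (is.na(df$insularity) | df$insularity == expected)
  }
  ok
}

# Normalise a raw data.frame into the canonical record layout: add derived
# columns (insularity, madcow_period), coerce types, blank -> NA.
normalise_records <- function(df) {
  for (col in setdiff(RECORD_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[RECORD_COLUMNS]
  chr <- c("nestling_id", "region", "insularity", "territory_id",
           "hatching_order", "sex", "breeding_unit", "mother_id", "father_id",
           "madcow_period")
  for (col in chr) {
    v <- as.character(df[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA
    df[[col]] <- trimws(v)
  }
  num <- c("year", "hatching_date", "brood_size", "mother_age", "father_age")
  for (col in num) df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  derive <- is.na(df$insularity) & df$region %in% ALL_REGIONS
  df$insularity[derive] <-
    ifelse(df$region[derive] %in% ISLAND_REGIONS, "island", "mainland")[seq_len(sum(derive))]
  ok_year <- !is.na(df$year) & df$year >= 1990
  df$madcow_period[ok_year] <- assign_madcow_period(df$year[ok_year])
  rownames(df) <- NULL
  df
}

#' Load nestling monitoring records from CSV
#'
#' Reads one row per sexed nestling, applies an optional column mapping,
#' derives `insularity` and `madcow_period`, validates the record invariants
#' and splits the rows into accepted records and rejected rows with
#' row-level diagnostics.
#'
#' @param path Path to a CSV file with a header row. Columns `region`,
#'   `territory_id`, `year` and `sex` are required.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(territory_id = "terr", sex = "sexo")`.
#' @return A list of class `record_set` with elements `records` (validated
#'   data.frame in the canonical layout), `rejected` (offending rows with a
#'   `reason` column) and `n_loaded` / `n_rejected` counts.
#' @seealso [write_records()], [assign_madcow_period()]
#' @export
load_records <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop("schema maps '", canon, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("region", "territory_id", "year", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- normalise_records(df)
  ok <- record_row_valid(df)
  rejected <- df[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    reasons <- vapply(seq_len(nrow(rejected)), function(i) {
      paste(check_record_invariants(rejected[i, , drop = FALSE]),
            collapse = "; ")
    }, character(1))
    rejected$reason <- reasons
  }
  out <- structure(
    list(records = df[ok, , drop = FALSE],
         rejected = rejected,
         n_loaded = sum(ok), n_rejected = sum(!ok)),
    class = "record_set"
  )
  rownames(out$records) <- NULL
  out
}

#' Write nestling records to CSV
#'
#' Inverse of [load_records()]: writes the canonical record layout with empty
#' cells for missing values so that a write/read round-trip is lossless.
#'
#' @param records Data frame of records (canonical layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.record_set <- function(x, ...) {
  cat("Nestling record set:", x$n_loaded, "accepted,",
      x$n_rejected, "rejected\n")
  if (x$n_rejected > 0) {
    cat("First rejection:", x$rejected$reason[1], "\n")
  }
  invisible(x)
}
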