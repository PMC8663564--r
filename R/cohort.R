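#' Default column mapping for long-format test-record files
#'
#' Column names expected in the input CSV. Public exports differ in their
#' header spelling, so every entry can be overridden; pass a modified copy to
#' \code{\link{load_cohort}}. Entries \code{metric}, \code{sdmt_baseline} and
#' \code{age} are optional columns: if the named column is absent from the
#' file it is silently skipped (for \code{metric}, all rows are then assumed
#' to carry the primary metric already).
#'
#' @return Named list of column names.
#' @export
default_column_map <- function() {
  list(
    participant_id = "participant_id",
    test           = "test_name",
    hand           = "hand",
    timestamp      = "test_date",
    metric         = "metric_name",
    value          = "metric_value",
    sdmt_baseline  = "sdmt_baseline",
    age            = "age_years"
  )
}

#' Default primary-metric names per test
#'
#' Used to select rows when the input file is a long table with one row per
#' (test, metric) pair. Override any entry to match the export at hand.
#'
#' @return Named character vector, names are test names.
#' @export
default_metric_map <- function() {
  c("e-SDMT"         = "correct_responses",
    "FingerPinching" = "successful_pinches",
    "DrawAShape"     = "shapes_correct",
    "TwoMinuteWalk"  = "steps",
    "UTurn"          = "turn_speed",
    "StaticBalance"  = "sway_path")
}

# ISO-8601 parsing; date-only stamps imputed at 12:00 so that day-resolution
# data never flips across midnight when converted to weeks.
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  x[date_only] <- paste(x[date_only], "12:00:00")
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  out
}

#' Construct a cohort from a table of test records
#'
#' Groups records into analysis units (participant, or participant-by-hand
#' for dexterity tests, per \code{\link{floodlight_tests}}), orders each unit
#' chronologically (ties kept in input row order), and assigns the gap-free
#' 1-based \code{repetition_index}, the model time \code{t_rep} =
#' repetition_index - 1, and \code{t_weeks} = weeks since the unit's first
#' test.
#'
#' @param records Data frame with columns \code{participant_id}, \code{test},
#'   \code{hand} (\code{"left"}, \code{"right"} or \code{"none"}),
#'   \code{timestamp} (POSIXct) and \code{value}; optionally
#'   \code{sdmt_baseline}.
#' @param participants Data frame with columns \code{participant_id} and
#'   \code{age_years} (may be \code{NA}); defaults to all-missing ages.
#' @param provenance Character notes on origin and filters applied.
#' @return An object of class \code{"cohort"}: a list with elements
#'   \code{records} (indexed data frame), \code{participants},
#'   \code{provenance} and \code{dropped} (named counts of discarded rows).
#' @export
as_cohort <- function(records, participants = NULL, provenance = character()) {
  req <- c("participant_id", "test", "hand", "timestamp", "value")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$participant_id <- as.character(records$participant_id)
  records$test <- as.character(records$test)
  records$hand <- tolower(as.character(records$hand))
  dropped <- c(unknown_test = 0L, bad_hand = 0L, bad_value = 0L,
               bad_timestamp = 0L)

  specs <- floodlight_tests()
  known <- records$test %in% specs$name
  dropped["unknown_test"] <- sum(!known)
  records <- records[known, , drop = FALSE]

  grouping <- specs$grouping[match(records$test, specs$name)]
  # hand label normalization: hand-grouped tests need left/right; others none
  is_hand <- grouping == "hand"
  bad_hand <- is_hand & !(records$hand %in% c("left", "right"))
  if (any(bad_hand)) {
    warning(sum(bad_hand), " record(s) on hand-grouped tests with ",
            "unrecognized hand label dropped", call. = FALSE)
  }
  dropped["bad_hand"] <- sum(bad_hand)
  records$hand[!is_hand] <- "none"
  records <- records[!bad_hand, , drop = FALSE]

  bad_val <- !is.finite(records$value)
  dropped["bad_value"] <- sum(bad_val)
  records <- records[!bad_val, , drop = FALSE]
  bad_ts <- is.na(records$timestamp)
  dropped["bad_timestamp"] <- sum(bad_ts)
  records <- records[!bad_ts, , drop = FALSE]

  records$unit_id <- ifelse(records$hand == "none",
                            records$participant_id,
                            paste(records$participant_id, records$hand,
                                  sep = ":"))

  # stable chronological order within unit x test; radix order is stable so
  # same-timestamp rows keep their input order
  key <- paste(records$test, records$unit_id, sep = "\r")
  ord <- order(key, as.numeric(records$timestamp), method = "radix")
  records <- records[ord, , drop = FALSE]
  grp <- paste(records$test, records$unit_id, sep = "\r")
  records$repetition_index <- stats::ave(seq_len(nrow(records)), grp,
                                         FUN = seq_along)
  records$t_rep <- records$repetition_index - 1
  t0 <- stats::ave(as.numeric(records$timestamp), grp, FUN = function(z) z[1])
  records$t_weeks <- (as.numeric(records$timestamp) - t0) / (7 * 86400)
  rownames(records) <- NULL

  if (is.null(participants)) {
    participants <- data.frame(
      participant_id = unique(records$participant_id),
      age_years = NA_real_, stringsAsFactors = FALSE)
  }
  participants$participant_id <- as.character(participants$participant_id)
  orphan <- setdiff(records$participant_id, participants$participant_id)
  if (length(orphan) > 0) {
    participants <- rbind(participants,
                          data.frame(participant_id = orphan,
                                     age_years = NA_real_,
                                     stringsAsFactors = FALSE))
  }

  structure(list(records = records, participants = participants,
                 provenance = provenance, dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  r <- x$records
  cat("Cohort:", nrow(r), "records,",
      length(unique(paste(r$test, r$unit_id))), "analysis unit(s),",
      length(unique(r$participant_id)), "participant(s)\n")
  for (tt in unique(r$test)) {
    n <- sum(r$test == tt)
    u <- length(unique(r$unit_id[r$test == tt]))
    cat(sprintf("  %-15s %6d records in %4d unit(s)\n", tt, n, u))
  }
  if (length(x$provenance) > 0) {
    cat("Provenance:", paste(x$provenance, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Load a long-format test-record file into a cohort
#'
#' Reads a delimited long-format export (one row per performed test, or per
#' test-metric pair), keeps rows whose metric matches the configured primary
#' metric of their test, applies the cutoff date, and groups records into
#' analysis units. Malformed rows (unknown test, bad hand label on a
#' hand-grouped test, non-finite value, unparseable timestamp) are counted in
#' the returned cohort's \code{dropped} field, not fatal.
#'
#' @param path Path to a CSV file.
#' @param column_map Named list as \code{\link{default_column_map}}.
#' @param metric_map Named character vector as
#'   \code{\link{default_metric_map}}; only used when the metric column is
#'   present.
#' @param cutoff_date Optional \code{"YYYY-MM-DD"}; rows after this date
#'   (inclusive cutoff) are dropped.
#' @return A \code{\link{as_cohort}} object.
#' @export
load_cohort <- function(path, column_map = default_column_map(),
                        metric_map = default_metric_map(),
                        cutoff_date = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("participant_id", "test", "hand", "timestamp", "value")
  for (k in needed) {
    if (is.null(column_map[[k]]) || !(column_map[[k]] %in% names(raw))) {
      stop("configuration error: mandatory column '", k, "' (mapped to '",
           column_map[[k]], "') not found in ", path, call. = FALSE)
    }
  }
  df <- data.frame(
    participant_id = as.character(raw[[column_map$participant_id]]),
    test = as.character(raw[[column_map$test]]),
    hand = as.character(raw[[column_map$hand]]),
    timestamp = parse_timestamp(raw[[column_map$timestamp]]),
    value = suppressWarnings(as.numeric(raw[[column_map$value]])),
    stringsAsFactors = FALSE
  )
  if (!is.null(column_map$sdmt_baseline) &&
      column_map$sdmt_baseline %in% names(raw)) {
    df$sdmt_baseline <- suppressWarnings(
      as.numeric(raw[[column_map$sdmt_baseline]]))
  }
  filters <- character()
  if (!is.null(column_map$metric) && column_map$metric %in% names(raw)) {
    want <- metric_map[df$test]
    keep <- is.na(want) | raw[[column_map$metric]] == want
    df <- df[keep, , drop = FALSE]
    filters <- c(filters, "primary-metric rows only")
  }
  if (!is.null(cutoff_date)) {
    cut <- as.POSIXct(paste(cutoff_date, "23:59:59"), tz = "UTC")
    df <- df[!is.na(df$timestamp) & df$timestamp <= cut, , drop = FALSE]
    filters <- c(filters, paste0("cutoff_date<=", cutoff_date))
  }
  if (nrow(df) == 0 || all(is.na(df$value))) {
    stop("input error: no parseable rows in ", path, call. = FALSE)
  }
  participants <- NULL
  if (!is.null(column_map$age) && column_map$age %in% names(raw)) {
    ages <- suppressWarnings(as.numeric(raw[[column_map$age]]))
    participants <- unique(data.frame(
      participant_id = as.character(raw[[column_map$participant_id]]),
      age_years = ages, stringsAsFactors = FALSE))
    # one age per participant: take the first non-missing
    participants <- participants[order(participants$participant_id,
                                       is.na(participants$age_years)), ]
    participants <- participants[!duplicated(participants$participant_id), ]
  }
  df$value[is.na(df$value)] <- NaN  # counted as bad_value by as_cohort
  as_cohort(df, participants,
            provenance = c(paste0("file=", path), filters))
}

#' Write a cohort to the normalized long format
#'
#' One row per record with full-precision values; the file re-loads into an
#' identical cohort via \code{\link{load_cohort}} with
#' \code{normalized_column_map()}.
#'
#' @param cohort A cohort.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  r <- cohort$records
  age <- cohort$participants$age_years[
    match(r$participant_id, cohort$participants$participant_id)]
  out <- data.frame(
    unit_id = r$unit_id,
    participant_id = r$participant_id,
    test = r$test,
    hand = r$hand,
    timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC"),
    repetition_index = r$repetition_index,
    t_weeks = sprintf("%.17g", r$t_weeks),
    value = sprintf("%.17g", r$value),
    age_years = age,
    stringsAsFactors = FALSE
  )
  if (!is.null(r$sdmt_baseline)) out$sdmt_baseline <- r$sdmt_baseline
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Column map matching \code{\link{write_cohort}} output
#' @return Named list usable as \code{column_map} in \code{\link{load_cohort}}.
#' @export
normalized_column_map <- function() {
  m <- default_column_map()
  m$test <- "test"
  m$hand <- "hand"
  m$timestamp <- "timestamp"
  m$value <- "value"
  m$metric <- NULL
  m$sdmt_baseline <- "sdmt_baseline"
  m
}

#' Correct symbol-digit scores for dexterity and reaction speed
#'
#' The electronic symbol-digit test includes a 15-second second step showing
#' digits instead of symbols ("baseline" tapping). Dividing the main-test
#' correct responses by the baseline correct responses removes the motor
#' component, leaving information processing speed. Records with a missing or
#' zero baseline are dropped (counted in \code{dropped["sdmt_baseline"]}).
#'
#' The transform refuses to run twice: raw scores are integer counts, and a
#' cohort whose symbol-digit values are no longer integers is rejected.
#'
#' @param cohort A cohort containing \code{"e-SDMT"} records with an
#'   \code{sdmt_baseline} column.
#' @return A new cohort with corrected symbol-digit values (re-indexed).
#' @export
correct_sdmt <- function(cohort) {
  r <- cohort$records
  is_sdmt <- r$test == "e-SDMT"
  if (!any(is_sdmt)) {
    stop("usage error: cohort contains no e-SDMT records", call. = FALSE)
  }
  if (is.null(r$sdmt_baseline)) {
    stop("usage error: e-SDMT records carry no sdmt_baseline column",
         call. = FALSE)
  }
  v <- r$value[is_sdmt]
  if (any(abs(v - round(v)) > 1e-8)) {
    stop("usage error: e-SDMT values are not integer counts; ",
         "was correct_sdmt() already applied?", call. = FALSE)
  }
  bad <- is_sdmt & (is.na(r$sdmt_baseline) | r$sdmt_baseline == 0)
  n_bad <- sum(bad)
  r$value[is_sdmt] <- r$value[is_sdmt] / r$sdmt_baseline[is_sdmt]
  r <- r[!bad, , drop = FALSE]
  r$sdmt_baseline[r$test == "e-SDMT"] <- NA_real_
  out <- as_cohort(r[, c("participant_id", "test", "hand", "timestamp",
                         "value", "sdmt_baseline")],
                   cohort$participants,
                   provenance = c(cohort$provenance, "sdmt_corrected"))
  out$dropped["sdmt_baseline"] <- n_bad
  out
}

# records of one test as a data frame, preserving the index columns
test_records <- function(cohort, test) {
  r <- cohort$records[cohort$records$test == test, , drop = FALSE]
  rownames(r) <- NULL
  r
}

# unique unit ids for one test
test_units <- function(cohort, test) unique(test_records(cohort, test)$unit_id)
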