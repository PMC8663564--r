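#' Metadata for the six smartphone tests
#'
#' Returns the per-test metadata used throughout the pipeline: the primary
#' metric and its units, whether higher or lower values indicate better
#' performance, the grouping level of an analysis unit (participant, or
#' participant-by-hand for the dexterity tests), and the app-enforced minimum
#' intertest interval in days (7 for the symbol-digit test, 2 per hand for
#' the dexterity tests, 1 for the mobility tests).
#'
#' Static Balance (sway path, m/s^2) is the only test where lower values are
#' better; Finger Pinching and Draw a Shape are the only hand-grouped tests.
#'
#' @return A data frame with one row per test and columns \code{name},
#'   \code{metric_units}, \code{direction} (\code{"higher_better"} or
#'   \code{"lower_better"}), \code{grouping} (\code{"participant"} or
#'   \code{"hand"}) and \code{min_interval_days}.
#' @examples
#' floodlight_tests()
#' @export
floodlight_tests <- function() {
  data.frame(
    name = c("e-SDMT", "FingerPinching", "DrawAShape",
             "TwoMinuteWalk", "UTurn", "StaticBalance"),
    metric_units = c("correct responses", "successful pinches",
                     "shapes drawn correctly", "steps", "rad/s", "m/s^2"),
    direction = c("higher_better", "higher_better", "higher_better",
                  "higher_better", "higher_better", "lower_better"),
    grouping = c("participant", "hand", "hand",
                 "participant", "participant", "participant"),
    min_interval_days = c(7, 2, 2, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Look up the metadata row for one test
#'
#' @param test Test name; one of the names in \code{floodlight_tests()}.
#' @return A one-row data frame (see \code{\link{floodlight_tests}}).
#' @examples
#' test_spec("StaticBalance")$direction
#' @export
test_spec <- function(test) {
  specs <- floodlight_tests()
  i <- match(test, specs$name)
  if (is.na(i)) {
    stop("unknown test '", test, "'; known tests: ",
         paste(specs$name, collapse = ", "), call. = FALSE)
  }
  specs[i, , drop = FALSE]
}
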