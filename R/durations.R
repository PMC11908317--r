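#' Parse an ISO-8601 duration into days
#'
#' Supports the date part of ISO-8601 periods (`P3Y6M`, `P22D`, `P2Y`,
#' `P10W`), with decimal fractions permitted in any component. Conversion
#' uses 1 year = 365.25 days and 1 month = 30.44 days. Time-of-day parts
#' are not supported (clinical onset ages are day-resolved).
#'
#' @param x character vector of ISO-8601 period strings.
#' @return numeric vector of days; `NA` where the input is not parseable.
#' @export
parseIsoDuration <- function(x) {
  pat <- "^P(?:([0-9]+(?:\\.[0-9]+)?)Y)?(?:([0-9]+(?:\\.[0-9]+)?)M)?(?:([0-9]+(?:\\.[0-9]+)?)W)?(?:([0-9]+(?:\\.[0-9]+)?)D)?$"
  m <- regmatches(x, regexec(pat, x))
  vapply(seq_along(x), function(i) {
    g <- m[[i]]
    if (length(g) == 0L || !nzchar(g[1]) || all(!nzchar(g[-1])))
      return(NA_real_)
    num <- suppressWarnings(as.numeric(g[-1]))
    num[is.na(num)] <- 0
    num[1] * DAYS_PER_YEAR + num[2] * DAYS_PER_MONTH + num[3] * 7 + num[4]
  }, numeric(1))
}

#' Format days as an ISO-8601 duration
#'
#' Canonical day-denominated form `P<n>D`; the inverse of
#' [parseIsoDuration()] up to the day representation, so ages round-trip
#' exactly through the JSON dump.
#'
#' @param days numeric vector of days.
#' @return character vector; `NA` maps to `NA`.
#' @export
formatIsoDuration <- function(days) {
  ifelse(is.na(days), NA_character_,
         paste0("P", format(days, digits = 15, trim = TRUE,
                            scientific = FALSE), "D"))
}

#' @rdname parseIsoDuration
#' @param days numeric vector of days.
#' @export
daysToYears <- function(days) days / DAYS_PER_YEAR
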