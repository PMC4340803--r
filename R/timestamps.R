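# Timestamps are ISO-8601 strings with timezone on the wire and numeric
# seconds since the UNIX epoch (UTC) internally, so comparisons are absolute
# instants and durations are plain Reals in seconds.

#' Parse ISO-8601 timestamps to epoch seconds
#'
#' Accepts `"2012-01-05T10:30:00Z"` or an explicit numeric offset such as
#' `"+02:00"`/`"+0200"`. Returns numeric seconds since 1970-01-01T00:00:00Z.
#'
#' @param x character vector of ISO-8601 timestamps.
#' @return numeric vector of epoch seconds; `NA` elements stay `NA`.
#' @keywords internal
parse_time <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  y <- x[ok]
  y <- sub("Z$", "+0000", y)
  y <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", y)
  t <- as.POSIXct(y, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  bad <- is.na(t)
  if (any(bad)) {
    abort_structural(sprintf("unparseable ISO-8601 timestamp: %s",
                             paste(unique(x[ok][bad]), collapse = ", ")))
  }
  out[ok] <- as.numeric(t)
  out
}

#' Format epoch seconds as ISO-8601 UTC strings
#'
#' @param t numeric epoch seconds.
#' @return character vector, `NA` for missing end times.
#' @keywords internal
format_time <- function(t) {
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t)
  if (any(ok)) {
    out[ok] <- format(as.POSIXct(t[ok], origin = "1970-01-01", tz = "UTC"),
                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  out
}
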