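#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# stop() with call.=FALSE and sprintf-style formatting
stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x)

# Day-of-week factor with Monday as the reference level (RR estimates are
# invariant to this choice; Monday is fixed so coefficients are comparable
# across fits).
dow_factor <- function(dates) {
  lev <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  idx <- (as.integer(as.Date(dates)) + 3L) %% 7L  # 1970-01-01 was a Thursday
  factor(lev[idx + 1L], levels = lev)
}

assert_daily_dates <- function(dates, what = "dates") {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop2("%s contain unparseable values", what)
  d <- diff(as.integer(dates))
  if (length(d) && any(d != 1L))
    stop2("%s must be contiguous at daily resolution", what)
  dates
}
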