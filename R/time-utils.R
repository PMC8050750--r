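# Instant arithmetic helpers. All instants are numeric seconds since the Unix
# epoch, UTC; date-only strings are anchored at midnight UTC so interval
# arithmetic is deterministic regardless of locale or session timezone.

SECONDS_PER_DAY <- 86400

#' Parse an ISO 8601 timestamp to an epoch instant
#'
#' Accepts date-only strings (`"2017-03-02"`, read as midnight UTC),
#' date-times with or without a timezone designator (`Z` or `+hh:mm`;
#' missing designators are read as UTC), and fractional seconds (truncated).
#'
#' @param x Character vector of ISO 8601 strings (`NA` passes through).
#' @return Numeric vector of seconds since the Unix epoch (UTC).
#' @examples
#' parse_instant("2017-03-02T08:00:00Z")
#' parse_instant("2017-03-02")
#' @export
parse_instant <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  xs <- x[ok]

  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", xs)
  full <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?$",
    xs
  )
  bad <- !date_only & !full
  if (any(bad)) {
    stop_fhirprep(
      sprintf("malformed ISO 8601 timestamp: %s", xs[bad][1L]),
      class = "fhirprep_time_error"
    )
  }

  res <- rep(NA_real_, length(xs))
  if (any(date_only)) {
    res[date_only] <- as.numeric(as.POSIXct(xs[date_only],
      format = "%Y-%m-%d", tz = "UTC"
    ))
  }
  if (any(full)) {
    f <- xs[full]
    # timezone offset (seconds to subtract), then strip designator + fraction
    off <- rep(0, length(f))
    m <- regmatches(f, regexpr("[+-]\\d{2}:?\\d{2}$", f))
    has_off <- grepl("[+-]\\d{2}:?\\d{2}$", f)
    if (any(has_off)) {
      mm <- gsub(":", "", m)
      sgn <- ifelse(substr(mm, 1, 1) == "-", -1, 1)
      hh <- as.numeric(substr(mm, 2, 3))
      mi <- as.numeric(substr(mm, 4, 5))
      off[has_off] <- sgn * (hh * 3600 + mi * 60)
    }
    core <- sub("(Z|[+-]\\d{2}:?\\d{2})$", "", f)
    core <- sub("\\.\\d+$", "", core)
    core <- ifelse(grepl(":\\d{2}:", core) | grepl("T\\d{2}:\\d{2}:\\d{2}$", core),
      core, paste0(core, ":00")
    )
    res[full] <- as.numeric(as.POSIXct(core,
      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
    )) - off[full]
  }
  out[ok] <- res
  out
}

# non-stopping variant: returns parsed values plus a flag for malformed
# entries (used by the bulk loader, which skips rather than aborts)
try_parse_instant <- function(x) {
  present <- !is.na(x) & nzchar(x)
  valid <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x) |
    grepl(
      "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?$",
      x
    )
  bad <- present & !valid
  vals <- rep(NA_real_, length(x))
  good <- present & valid
  if (any(good)) vals[good] <- parse_instant(x[good])
  list(values = vals, bad = bad)
}

#' Format an epoch instant as an ISO 8601 UTC string
#'
#' @param t Numeric vector of epoch seconds.
#' @return Character vector `"YYYY-MM-DDThh:mm:ssZ"` (`NA` passes through).
#' @export
format_instant <- function(t) {
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t)
  out[ok] <- format(as.POSIXct(t[ok], origin = "1970-01-01", tz = "UTC"),
    "%Y-%m-%dT%H:%M:%SZ",
    tz = "UTC"
  )
  out
}

instant_to_date <- function(t) {
  as.Date(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
}

#' Completed age in years at a time point
#'
#' Floor of the number of whole years between `birth_date` and the calendar
#' date of `t`. A February-29 birthday counts as completed on March 1 in
#' non-leap years.
#'
#' @param birth_date A `Date` vector (or string coercible to one).
#' @param t Numeric epoch instants (see [parse_instant()]).
#' @return Integer vector of completed years; `NA` where either input is `NA`.
#' @examples
#' patient_age_at(as.Date("1980-06-15"), parse_instant("2017-06-15"))
#' @export
patient_age_at <- function(birth_date, t) {
  birth_date <- as.Date(birth_date)
  d <- instant_to_date(t)
  n <- max(length(birth_date), length(d))
  birth_date <- rep_len(birth_date, n)
  d <- rep_len(d, n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(birth_date) & !is.na(d)
  if (!any(ok)) return(out)
  bl <- as.POSIXlt(birth_date[ok])
  dl <- as.POSIXlt(d[ok])
  yrs <- dl$year - bl$year
  before_birthday <- (dl$mon < bl$mon) | (dl$mon == bl$mon & dl$mday < bl$mday)
  out[ok] <- as.integer(yrs - as.integer(before_birthday))
  out
}

# half-up decimal rounding (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic 32-bit string hash (FNV-1a), for per-patient RNG streams
str_hash32 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- bitwXor(as.integer(h %% 2^31), b)
      h <- (h * 16777619) %% 2^31
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

stop_fhirprep <- function(msg, class = "fhirprep_error", ...) {
  rlang::abort(msg, class = c(class, "fhirprep_error"), ...)
}
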