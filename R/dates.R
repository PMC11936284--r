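#' Parse FAERS-dialect date strings
#'
#' FAERS encodes dates as `YYYYMMDD` strings; partially known dates are
#' truncated to `YYYYMM` or `YYYY` and unknown dates are blank. This parser
#' classifies each string and converts fully specified, calendar-valid dates
#' to [Date]. Impossible calendar dates (e.g. `"20230230"`) are classified
#' as missing.
#'
#' @param x character (or numeric) vector of raw date strings.
#' @return A `data.table` with one row per input: `raw`, `status`
#'   (`"full"`, `"partial"` or `"missing"`), `date` (`Date`, `NA` unless
#'   full) and `year` (integer, `NA` when missing).
#' @examples
#' parse_faers_date(c("20230228", "202302", "2023", "20230230", ""))
#' @export
parse_faers_date <- function(x) {
  raw <- trimws(as.character(x))
  raw[is.na(raw)] <- ""
  n <- length(raw)
  status <- rep("missing", n)
  date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  year <- rep(NA_integer_, n)

  full <- grepl("^[0-9]{8}$", raw)
  if (any(full)) {
    d <- as.Date(raw[full], format = "%Y%m%d")
    ok <- !is.na(d)
    idx <- which(full)[ok]
    status[idx] <- "full"
    date[idx] <- d[ok]
    year[idx] <- as.integer(substr(raw[idx], 1, 4))
  }
  ym <- grepl("^[0-9]{6}$", raw)
  if (any(ym)) {
    mo <- as.integer(substr(raw[ym], 5, 6))
    ok <- mo >= 1 & mo <= 12
    idx <- which(ym)[ok]
    status[idx] <- "partial"
    year[idx] <- as.integer(substr(raw[idx], 1, 4))
  }
  yy <- grepl("^[0-9]{4}$", raw)
  if (any(yy)) {
    status[yy] <- "partial"
    year[yy] <- as.integer(raw[yy])
  }
  data.table::data.table(raw = raw, status = status, date = date, year = year)
}

# integer YYYYMMDD (or NA) used for ordering in deduplication
date_sort_key <- function(x) {
  raw <- trimws(as.character(x))
  suppressWarnings(key <- as.integer(raw))
  key[!grepl("^[0-9]{8}$", raw)] <- NA_integer_
  key
}

format_faers_date <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}
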