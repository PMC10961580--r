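#' Month-key utilities
#'
#' Calendar months are represented throughout the package as `"YYYY-MM"`
#' character keys. `month_key()` converts dates to keys, `month_seq()`
#' enumerates the months intersecting a pair of dates (or keys), and
#' `month_days()` returns the number of days in a month.
#'
#' @param x a `Date` vector (for `month_key()`) or a month key (elsewhere).
#' @param from,to `Date`s or `"YYYY-MM"` keys; both endpoints inclusive.
#' @return `month_key()`: character vector of keys. `month_seq()`: character
#'   vector of consecutive keys. `month_days()`: integer vector.
#' @examples
#' month_key(as.Date("2019-04-15"))
#' month_seq("2019-04", "2019-06")
#' @export
month_key <- function(x) {
  stopifnot(inherits(x, "Date"))
  format(x, "%Y-%m")
}

#' @rdname month_key
#' @export
month_seq <- function(from, to) {
  from <- month_first_day(from)
  to <- month_first_day(to)
  if (from > to) stop("`from` month is after `to` month", call. = FALSE)
  format(seq(from, to, by = "month"), "%Y-%m")
}

#' @rdname month_key
#' @export
month_days <- function(x) {
  start <- month_first_day(x)
  nxt <- seq(start[1], by = "month", length.out = 2)[2]
  if (length(start) > 1) {
    vapply(start, function(s) {
      as.integer(seq(s, by = "month", length.out = 2)[2] - s)
    }, integer(1))
  } else {
    as.integer(nxt - start)
  }
}

# Accepts Date or "YYYY-MM" / "YYYY-MM-DD"; returns first day of the month.
month_first_day <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}(-\\d{2})?$", x)
  if (!all(ok)) {
    stop("invalid month key: ", paste(x[!ok], collapse = ", "), call. = FALSE)
  }
  as.Date(paste0(substr(x, 1, 7), "-01"))
}

# Split "YYYY-MM" keys into an integer year/month data frame.
month_parts <- function(keys) {
  tibble::tibble(
    year = as.integer(substr(keys, 1, 4)),
    month = as.integer(substr(keys, 6, 7))
  )
}
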