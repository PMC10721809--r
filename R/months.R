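## Calendar-month arithmetic on "YYYY-MM" labels.
## Months are carried internally as integer serial numbers
## (year * 12 + (month - 1)) so that differences are month counts.

#' Parse "YYYY-MM" month labels to serial month numbers
#'
#' @param x character vector of month labels in `YYYY-MM` form.
#' @return integer vector of serial month numbers (`year * 12 + month - 1`).
#' @examples
#' ymToSerial("2020-04") - ymToSerial("2020-01")  # 3
#' @export
ymToSerial <- function(x) {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  if (any(!ok)) {
    stop("malformed month label(s): ",
         paste(sQuote(x[!ok][seq_len(min(3, sum(!ok)))]), collapse = ", "),
         " (expected YYYY-MM)", call. = FALSE)
  }
  year <- as.integer(substr(x, 1L, 4L))
  mon <- as.integer(substr(x, 6L, 7L))
  if (any(mon < 1L | mon > 12L)) {
    bad <- x[mon < 1L | mon > 12L]
    stop("month out of range in label(s): ",
         paste(sQuote(bad[seq_len(min(3, length(bad)))]), collapse = ", "),
         call. = FALSE)
  }
  year * 12L + (mon - 1L)
}

#' Format serial month numbers as "YYYY-MM"
#'
#' @param s integer vector of serial month numbers.
#' @return character vector of `YYYY-MM` labels.
#' @export
ymFormat <- function(s) {
  s <- as.integer(s)
  sprintf("%04d-%02d", s %/% 12L, s %% 12L + 1L)
}

#' Contiguous month sequence
#'
#' @param from,to `YYYY-MM` labels, `from <= to`.
#' @return character vector of consecutive month labels.
#' @examples
#' ymSeq("2020-03", "2020-05")
#' @export
ymSeq <- function(from, to) {
  a <- ymToSerial(from)
  b <- ymToSerial(to)
  if (b < a) stop("'from' month is after 'to' month", call. = FALSE)
  ymFormat(seq.int(a, b))
}

## month-of-year (1..12) of a serial month
ymMonthOfYear <- function(s) as.integer(s) %% 12L + 1L

## calendar year of a serial month
ymYear <- function(s) as.integer(s) %/% 12L

## calendar quarter label, e.g. "2020-Q3"
ymQuarter <- function(ym) {
  s <- ymToSerial(ym)
  sprintf("%04d-Q%d", ymYear(s), (ymMonthOfYear(s) - 1L) %/% 3L + 1L)
}
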