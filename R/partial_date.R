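#' Partial calendar dates
#'
#' A `partial_date` is an ISO-8601 date prefix: a year, optionally a month,
#' optionally a day. Registry source data frequently record only "2015" or
#' "2015-06"; the imputation rules operate on these objects and complete them
#' deterministically. The class is vectorised: one object holds parallel
#' integer vectors of years, months and days, with `NA` marking an absent
#' component.
#'
#' Invariants: a day is only present when the month is, and a month only when
#' the year is; a complete entry is a valid calendar date. `partial_date()`
#' enforces both and refuses malformed input.
#'
#' @param year integer vector of CE years (NA = fully missing date).
#' @param month optional integer vector, 1-12.
#' @param day optional integer vector, 1-31 and valid for the month.
#' @return An object of class `partial_date`.
#' @examples
#' partial_date(2015, 6)            # "2015-06"
#' partial_date(c(2015, 2016), c(6, NA), c(11, NA))
#' @export
partial_date <- function(year, month = NA_integer_, day = NA_integer_) {
  n <- if (length(year) == 0L) 0L else
    max(length(year), length(month), length(day))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  if (any(!is.na(day) & is.na(month)))
    stop("day present without month", call. = FALSE)
  if (any(!is.na(month) & is.na(year)))
    stop("month present without year", call. = FALSE)
  if (any(!is.na(month) & (month < 1L | month > 12L)))
    stop("month out of range 1-12", call. = FALSE)
  cc <- !is.na(day)
  if (any(cc)) {
    probe <- as.Date(sprintf("%04d-%02d-%02d", year[cc], month[cc], day[cc]),
                     format = "%Y-%m-%d")
    if (anyNA(probe))
      stop("invalid calendar date among complete entries", call. = FALSE)
  }
  structure(list(year = year, month = month, day = day),
            class = "partial_date")
}

#' Parse ISO-8601 date prefixes
#'
#' Accepts exactly `"YYYY"`, `"YYYY-MM"` and `"YYYY-MM-DD"`. Anything else --
#' free text, out-of-range components, impossible calendar dates -- is a parse
#' failure: the entry is returned with all components `NA` and is flagged in
#' the `failed` attribute together with the verbatim text, so that no source
#' value is ever silently dropped.
#'
#' @param text character vector.
#' @return A `partial_date` with attributes `failed` (logical) and
#'   `verbatim` (the input strings).
#' @seealso [extract_date_from_text()] for free-text date recovery.
#' @examples
#' parse_partial_date(c("2016", "2016-02", "2016-02-30", "15 Jun 2016"))
#' @export
parse_partial_date <- function(text) {
  text <- as.character(text)
  n <- length(text)
  year <- month <- day <- rep(NA_integer_, n)
  ok <- rep(FALSE, n)
  blank <- is.na(text) | text == ""

  m_full <- regmatches(text, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", text))
  m_ym <- regmatches(text, regexec("^(\\d{4})-(\\d{2})$", text))
  m_y <- regmatches(text, regexec("^(\\d{4})$", text))
  for (i in seq_len(n)) {
    if (blank[i]) next
    if (length(m_full[[i]])) {
      y <- as.integer(m_full[[i]][2]); mo <- as.integer(m_full[[i]][3])
      d <- as.integer(m_full[[i]][4])
      if (mo >= 1L && mo <= 12L &&
          !is.na(as.Date(text[i], format = "%Y-%m-%d"))) {
        year[i] <- y; month[i] <- mo; day[i] <- d; ok[i] <- TRUE
      }
    } else if (length(m_ym[[i]])) {
      y <- as.integer(m_ym[[i]][2]); mo <- as.integer(m_ym[[i]][3])
      if (mo >= 1L && mo <= 12L) {
        year[i] <- y; month[i] <- mo; ok[i] <- TRUE
      }
    } else if (length(m_y[[i]])) {
      year[i] <- as.integer(m_y[[i]][2]); ok[i] <- TRUE
    }
  }
  out <- partial_date(year, month, day)
  attr(out, "failed") <- !ok & !blank
  attr(out, "verbatim") <- text
  out
}

#' @export
format.partial_date <- function(x, ...) {
  out <- rep(NA_character_, length(x$year))
  h_d <- !is.na(x$day)
  h_m <- !is.na(x$month) & !h_d
  h_y <- !is.na(x$year) & is.na(x$month)
  out[h_d] <- sprintf("%04d-%02d-%02d", x$year[h_d], x$month[h_d], x$day[h_d])
  out[h_m] <- sprintf("%04d-%02d", x$year[h_m], x$month[h_m])
  out[h_y] <- sprintf("%04d", x$year[h_y])
  out
}

#' @export
print.partial_date <- function(x, ...) {
  print(format(x))
  invisible(x)
}

#' @export
length.partial_date <- function(x) length(x$year)

#' @export
`[.partial_date` <- function(x, i) {
  partial_date(x$year[i], x$month[i], x$day[i])
}

#' @export
as.character.partial_date <- function(x, ...) format(x)

#' Completeness of a partial date
#' @param x a `partial_date`.
#' @return logical vector: TRUE where year, month and day are all present.
#' @export
pd_complete <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  !is.na(x$year) & !is.na(x$month) & !is.na(x$day)
}

#' Number of missing components of a partial date
#'
#' 0 for a complete date, 1 for a missing day, 2 for a missing day and month,
#' 3 for a fully missing date. Drives candidate selection in
#' [impute_death_date()].
#' @param x a `partial_date`.
#' @return integer vector in 0..3.
#' @export
pd_n_missing <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  is.na(x$year) + is.na(x$month) + is.na(x$day)
}

#' @export
as.Date.partial_date <- function(x, ...) {
  out <- rep(as.Date(NA), length(x$year))
  cc <- pd_complete(x)
  out[cc] <- as.Date(sprintf("%04d-%02d-%02d",
                             x$year[cc], x$month[cc], x$day[cc]))
  out
}

#' Extract a date from free text
#'
#' Registry CRFs sometimes bury the event date inside a free-text comment.
#' This scans text for date patterns in a fixed dialect list and returns the
#' first match as a `partial_date`, or NA components when nothing matches.
#' Recognised dialects, tried in order:
#' \itemize{
#'   \item ISO prefixes: `2015-06-11`, `2015-06`, `2015`
#'   \item `DD Mon YYYY` (`11 Jun 2015`, case-insensitive month)
#'   \item `Mon YYYY` (`Jun 2015`)
#'   \item `MM/DD/YYYY` (`06/11/2015`)
#' }
#' A bare 4-digit year only counts when it stands as its own token and lies in
#' 1900-2099, to avoid mistaking record identifiers for years.
#'
#' @param text character vector of free text.
#' @return A `partial_date`; entries with no recognisable date have all
#'   components `NA`.
#' @examples
#' extract_date_from_text("dose changed 2015-06-11 per chart")
#' extract_date_from_text("seen Jan 2016")
#' @export
extract_date_from_text <- function(text) {
  text <- as.character(text)
  n <- length(text)
  year <- month <- day <- rep(NA_integer_, n)
  months <- c(jan = 1L, feb = 2L, mar = 3L, apr = 4L, may = 5L, jun = 6L,
              jul = 7L, aug = 8L, sep = 9L, oct = 10L, nov = 11L, dec = 12L)
  mon_re <- "(Jan|Feb|Mar|Apr|May|Jun|Jul|Aug|Sep|Oct|Nov|Dec)"
  pats <- list(
    iso_full = "\\b(\\d{4})-(\\d{2})-(\\d{2})\\b",
    dmy = paste0("\\b(\\d{1,2})\\s+", mon_re, "\\s+(\\d{4})\\b"),
    mdy_slash = "\\b(\\d{1,2})/(\\d{1,2})/(\\d{4})\\b",
    iso_ym = "\\b(\\d{4})-(\\d{2})\\b",
    my = paste0("\\b", mon_re, "\\s+(\\d{4})\\b"),
    y = "(^|[^-/[:alnum:]])((19|20)\\d{2})($|[^-/[:alnum:]])"
  )
  set_if_valid <- function(i, y, mo, d) {
    if (!is.na(mo) && (mo < 1L || mo > 12L)) return(FALSE)
    if (!is.na(d)) {
      probe <- as.Date(sprintf("%04d-%02d-%02d", y, mo, d),
                       format = "%Y-%m-%d")
      if (is.na(probe)) return(FALSE)
    }
    year[i] <<- y; month[i] <<- mo; day[i] <<- d
    TRUE
  }
  for (i in seq_len(n)) {
    if (is.na(text[i])) next
    s <- text[i]
    for (nm in names(pats)) {
      mm <- regmatches(s, regexec(pats[[nm]], s, ignore.case = TRUE))[[1]]
      if (!length(mm)) next
      hit <- switch(nm,
        iso_full = set_if_valid(i, as.integer(mm[2]), as.integer(mm[3]),
                                as.integer(mm[4])),
        dmy = set_if_valid(i, as.integer(mm[4]),
                           months[[tolower(mm[3])]], as.integer(mm[2])),
        mdy_slash = set_if_valid(i, as.integer(mm[4]), as.integer(mm[2]),
                                 as.integer(mm[3])),
        iso_ym = set_if_valid(i, as.integer(mm[2]), as.integer(mm[3]),
                              NA_integer_),
        my = set_if_valid(i, as.integer(mm[3]), months[[tolower(mm[2])]],
                          NA_integer_),
        y = set_if_valid(i, as.integer(mm[3]), NA_integer_, NA_integer_)
      )
      if (isTRUE(hit)) break
    }
  }
  partial_date(year, month, day)
}
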