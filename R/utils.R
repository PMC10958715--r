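# Shared helpers: string normalization, FAERS date parsing, rounding.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables here follow the
#' round-half-up convention (73.034 -> 73.03, 73.035 -> 73.04).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half-up
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percent of a count over a denominator, two decimals
#' @param count numeric numerator
#' @param n denominator
#' @return percent on the 0-100 scale, rounded half-up to two decimals
#' @export
percent_of <- function(count, n) {
  if (length(n) == 1 && (is.na(n) || n == 0)) return(rep(NA_real_, length(count)))
  round_half_up(100 * count / n, 2)
}

# Uppercase, trim, collapse whitespace, strip punctuation to spaces.
# "LENVATINIB MESYLATE." -> "LENVATINIB MESYLATE"
normalize_term <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Parse FAERS digit-string dates
#'
#' FAERS encodes partial dates as shorter digit strings: 8 digits = day
#' precision (YYYYMMDD), 6 = month (YYYYMM), 4 = year (YYYY). Anything else
#' (including empty) is unknown.
#'
#' @param x character vector of digit strings
#' @return a tibble with columns `date` (class Date; first day of the period
#'   for partial dates, NA when unknown) and `precision`
#'   (one of "day", "month", "year", "none")
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  digits <- grepl("^[0-9]+$", x)
  nc <- nchar(x)
  precision <- rep("none", length(x))
  precision[digits & nc == 8] <- "day"
  precision[digits & nc == 6] <- "month"
  precision[digits & nc == 4] <- "year"
  full <- ifelse(precision == "day", x,
          ifelse(precision == "month", paste0(x, "01"),
          ifelse(precision == "year", paste0(x, "0101"), NA_character_)))
  date <- as.Date(full, format = "%Y%m%d")
  # calendar-invalid strings (e.g. 20200230) degrade to unknown
  bad <- !is.na(full) & is.na(date)
  precision[bad] <- "none"
  tibble(date = date, precision = precision)
}

# numeric coercion that maps non-numeric strings to NA without warnings
as_num <- function(x) suppressWarnings(as.numeric(x))

# write a tibble as plain CSV (no row names, NA as empty)
write_csv_plain <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
}
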