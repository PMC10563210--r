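# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Population (divide-by-n) variance; the strength statistics are defined on it.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

stop_arg <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

# Parse "YYYY-MM" or "YYYY-MM-DD" into (year, month). Vectorised.
parse_year_month <- function(date) {
  ok <- grepl("^\\d{4}-\\d{2}(-\\d{2})?$", date)
  if (!all(ok)) {
    stop_arg("malformed date(s): ", paste(utils::head(date[!ok], 3L), collapse = ", "),
             " (expected YYYY-MM or YYYY-MM-DD)")
  }
  year <- as.integer(substr(date, 1L, 4L))
  month <- as.integer(substr(date, 6L, 7L))
  if (any(month < 1L | month > 12L)) {
    stop_arg("month outside 1..12 in date(s): ",
             paste(utils::head(date[month < 1L | month > 12L], 3L), collapse = ", "))
  }
  list(year = year, month = month)
}

format_year_month <- function(year, month) {
  sprintf("%04d-%02d", year, month)
}

month_names <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
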