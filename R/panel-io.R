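#' Search-index panels
#'
#' A `search_panel` is a long-format data frame with one record per
#' (region, month): columns `region_id` (character), `year` (integer),
#' `month` (integer 1-12) and `value` (non-negative index units, `NA` for
#' missing months). Within each region the months form a contiguous range.
#'
#' @param x A data frame to validate/coerce.
#' @return `as_search_panel()` returns the validated panel.
#' @export
as_search_panel <- function(x) {
  if (!is.data.frame(x)) stop_arg("panel must be a data frame")
  need <- c("region_id", "year", "month", "value")
  if (!all(need %in% names(x))) {
    stop_arg("panel needs columns ", paste(need, collapse = ", "))
  }
  x$region_id <- as.character(x$region_id)
  x$year <- as.integer(x$year)
  x$month <- as.integer(x$month)
  x$value <- as.numeric(x$value)
  if (any(x$month < 1L | x$month > 12L, na.rm = TRUE)) {
    stop_arg("month outside 1..12")
  }
  key <- paste(x$region_id, x$year, x$month)
  if (anyDuplicated(key)) {
    stop_arg("duplicate (region, month): ", key[duplicated(key)][1L])
  }
  bad <- which(!is.na(x$value) & (!is.finite(x$value) | x$value < 0))
  if (length(bad)) {
    stop_arg("negative or non-finite index value at row ", bad[1L],
             " (", key[bad[1L]], ")")
  }
  x <- x[order(x$region_id, x$year, x$month), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- unique(c("search_panel", class(x)))
  x
}

#' @rdname as_search_panel
#' @export
is_search_panel <- function(x) inherits(x, "search_panel")

# Absolute month index (months since year 0), for gap arithmetic.
month_index <- function(year, month) 12L * year + (month - 1L)

# Complete each region's months to a contiguous range, inserting NA values.
complete_months <- function(panel) {
  pieces <- lapply(split(panel, panel$region_id), function(d) {
    mi <- month_index(d$year, d$month)
    full <- seq(min(mi), max(mi))
    if (length(full) == nrow(d)) return(d)
    out <- data.frame(region_id = d$region_id[1L],
                      year = full %/% 12L,
                      month = full %% 12L + 1L,
                      value = NA_real_, stringsAsFactors = FALSE)
    out$value[match(mi, full)] <- d$value
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  as_search_panel(out)
}

#' Read a search-index panel from CSV
#'
#' Expects a header `region_id,date,index` with dates `YYYY-MM` (monthly) or
#' `YYYY-MM-DD` (daily/weekly). Sub-monthly records are averaged to calendar
#' months before the panel is returned; each region's months are then
#' completed to a contiguous range (missing months become `NA`, to be handled
#' by [clean_panel()]).
#'
#' @param path Path to the CSV file.
#' @return A `search_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  if (!identical(names(raw)[1:3], c("region_id", "date", "index"))) {
    stop_arg("expected CSV header region_id,date,index in ", path)
  }
  key <- paste(raw$region_id, raw$date)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop_arg("duplicate (region, date) record at data row ", i, ": ", key[i])
  }
  bad <- which(!is.finite(raw$index) | raw$index < 0)
  if (length(bad)) {
    stop_arg("negative or non-finite index at data row ", bad[1L],
             " (", key[bad[1L]], ")")
  }
  ym <- parse_year_month(raw$date)
  agg <- stats::aggregate(raw$index,
                          by = list(region_id = raw$region_id,
                                    year = ym$year, month = ym$month),
                          FUN = mean)
  names(agg)[4L] <- "value"
  complete_months(as_search_panel(agg))
}

#' Write a search-index panel to CSV
#'
#' Writes the long `region_id,date,index` format (`date` as ISO `YYYY-MM`)
#' that [read_panel()] accepts. Missing values are written as empty fields.
#'
#' @param panel A `search_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- as_search_panel(panel)
  out <- data.frame(region_id = panel$region_id,
                    date = format_year_month(panel$year, panel$month),
                    index = sprintf_num(panel$value),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Deterministic full-precision number formatting for CSV output.
sprintf_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Clean a panel: robust outlier flagging and gap interpolation
#'
#' Per region: values whose robust z-score `|x - median| / (1.4826 * MAD)`
#' exceeds `outlier_z` are flagged and treated as missing; interior missing
#' runs of length at most `max_gap` are then linearly interpolated; longer
#' runs and missing endpoints are left missing and reported. Regions left
#' with fewer than 24 non-missing months are dropped with a warning. Every
#' change is listed in the cleaning report.
#'
#' If a region's MAD is zero (a flat series), any value different from the
#' median is treated as infinitely outlying.
#'
#' @param panel A `search_panel` (possibly with `NA` values).
#' @param outlier_z Positive robust z-score threshold (default 4).
#' @param max_gap Maximum length of an interior missing run to interpolate.
#' @return A list with elements `panel` (the cleaned `search_panel`) and
#'   `report` (a data frame with columns `region_id`, `year`, `month`,
#'   `action`, `old_value`, `new_value`; actions are `outlier_flagged`,
#'   `imputed`, `left_missing`, `region_dropped`).
#' @export
clean_panel <- function(panel, outlier_z = 4, max_gap = 2L) {
  panel <- complete_months(as_search_panel(panel))
  if (!is_number(outlier_z) || outlier_z <= 0) stop_arg("outlier_z must be positive")
  if (!is_count(max_gap) || max_gap < 0L) stop_arg("max_gap must be a non-negative integer")
  rep_rows <- list()
  note <- function(d, idx, action, old, new) {
    if (length(idx) == 0L) return()
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      region_id = d$region_id[idx], year = d$year[idx], month = d$month[idx],
      action = action, old_value = old, new_value = new,
      stringsAsFactors = FALSE)
  }
  pieces <- lapply(split(panel, panel$region_id), function(d) {
    v <- d$value
    med <- stats::median(v, na.rm = TRUE)
    mad <- stats::mad(v, na.rm = TRUE)  # includes the 1.4826 consistency factor
    dev <- abs(v - med)
    z <- ifelse(dev == 0, 0, ifelse(mad > 0, dev / mad, Inf))
    out_idx <- which(!is.na(v) & z > outlier_z)
    note(d, out_idx, "outlier_flagged", v[out_idx], NA_real_)
    v[out_idx] <- NA_real_
    # interior gaps of length <= max_gap: linear interpolation
    if (anyNA(v) && any(!is.na(v))) {
      obs <- which(!is.na(v))
      runs <- rle(is.na(v))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in seq_along(runs$lengths)) {
        if (!runs$values[k]) next
        idx <- starts[k]:ends[k]
        interior <- starts[k] > min(obs) && ends[k] < max(obs)
        if (interior && runs$lengths[k] <= max_gap && max_gap > 0L) {
          filled <- stats::approx(obs, v[obs], xout = idx)$y
          note(d, idx, "imputed", NA_real_, filled)
          v[idx] <- filled
        } else {
          note(d, idx, "left_missing", NA_real_, NA_real_)
        }
      }
    }
    d$value <- v
    if (sum(!is.na(v)) < 24L) {
      note(d, seq_len(nrow(d))[1L], "region_dropped", NA_real_, NA_real_)
      warning("region ", d$region_id[1L],
              " dropped: fewer than 24 non-missing months", call. = FALSE)
      return(NULL)
    }
    d
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (length(pieces) == 0L) stop_arg("no region survived cleaning")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(region_id = character(), year = integer(), month = integer(),
               action = character(), old_value = numeric(),
               new_value = numeric(), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(panel = as_search_panel(out), report = report)
}

#' Annual series (year, value)
#'
#' Validates an annual series: strictly increasing consecutive years,
#' non-negative finite values.
#'
#' @param x Data frame with columns `year`, `value`.
#' @return The validated `annual_series`.
#' @export
as_annual_series <- function(x) {
  if (!is.data.frame(x) || !all(c("year", "value") %in% names(x))) {
    stop_arg("annual series needs columns year, value")
  }
  x <- data.frame(year = as.integer(x$year), value = as.numeric(x$value))
  if (nrow(x) == 0L) stop_arg("annual series is empty")
  if (any(diff(x$year) != 1L)) stop_arg("years must be consecutive and increasing")
  if (any(!is.finite(x$value) | x$value < 0)) stop_arg("values must be finite and >= 0")
  class(x) <- unique(c("annual_series", class(x)))
  x
}

#' Read / write an annual series CSV (`year,value`)
#'
#' @param path CSV path.
#' @return `read_annual_series()` returns an `annual_series`;
#'   `write_annual_series()` returns `path` invisibly.
#' @export
read_annual_series <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "value") %in% names(raw))) {
    stop_arg("expected CSV header year,value in ", path)
  }
  as_annual_series(raw)
}

#' @rdname read_annual_series
#' @param series An `annual_series`.
#' @export
write_annual_series <- function(series, path) {
  series <- as_annual_series(series)
  out <- data.frame(year = series$year, value = sprintf_num(series$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
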