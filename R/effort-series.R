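#' Monthly fleet effort series
#'
#' Build the abundance-index container used by [amsy()]: an ordered monthly
#' series of a fleet's total fishing hours. In the fleet-as-stock view the
#' monthly total of fishing hours plays the role of a stock-abundance index,
#' so the series must be strictly positive and the months consecutive.
#'
#' @param fleet Gear label of the fleet (one of [gear_labels()]).
#' @param year,month Integer vectors of calendar year and month (1-12).
#' @param hours Strictly positive fishing hours per month.
#' @return A `data.frame` of class `"effort_series"` with columns
#'   `fleet`, `year`, `month`, `hours`.
#' @seealso [read_effort_series()], [simulate_effort_series()], [amsy()]
#' @export
effort_series <- function(fleet, year, month, hours) {
  check_gear(fleet)
  year <- as.integer(year)
  month <- as.integer(month)
  hours <- as.numeric(hours)
  n <- length(hours)
  if (length(year) != n || length(month) != n) {
    stop("year, month and hours must have equal length", call. = FALSE)
  }
  if (n < 1L) stop("effort series must contain at least one month", call. = FALSE)
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12", call. = FALSE)
  if (any(!is.finite(hours)) || any(hours <= 0)) {
    stop("hours must be strictly positive and finite", call. = FALSE)
  }
  idx <- ym_index(year, month)
  if (n > 1L && any(diff(idx) != 1L)) {
    stop("months must be consecutive", call. = FALSE)
  }
  out <- data.frame(fleet = fleet, year = year, month = month, hours = hours,
                    stringsAsFactors = FALSE)
  class(out) <- c("effort_series", "data.frame")
  out
}

#' Read a monthly effort series from CSV
#'
#' Expects columns `fleet`, `year`, `month`, `hours`. If several fleets are
#' present, a named list of `effort_series` (one per fleet) is returned.
#'
#' @param path Path to a CSV file.
#' @return An `effort_series`, or a named list of them.
#' @export
read_effort_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fleet", "year", "month", "hours")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("effort series CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  build <- function(d) {
    d <- d[order(ym_index(as.integer(d$year), as.integer(d$month))), ]
    effort_series(d$fleet[1], d$year, d$month, d$hours)
  }
  fleets <- unique(df$fleet)
  if (length(fleets) == 1L) return(build(df))
  out <- lapply(split(df, df$fleet), build)
  out[fleets]
}

#' Write a monthly effort series to CSV
#'
#' @param series An `effort_series` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effort_series <- function(series, path) {
  if (inherits(series, "effort_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
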