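#' Accumulate thermal time over a temperature log
#'
#' Thermal time (growing degree-days) from `start` to `end` is the sum over
#' calendar days of `max(0, daily mean temperature - base_temp)`. Daily means
#' are computed from that day's readings within the window; partial first and
#' last days contribute the mean of their available readings, weighted by the
#' fraction of the day covered by the window. Readings at `start` are
#' included, readings at `end` are not.
#'
#' With `method = "per_reading"` the accumulation is instead
#' `sum(max(0, temp - base) * dt) / 24 h` over individual readings, each
#' reading covering one cadence interval. The daily-mean convention is the
#' default because degree-days are conventionally defined on daily means; at
#' constant temperature both methods agree exactly.
#'
#' @param log data.frame with `timestamp` (POSIXct) and `temp_c`, as from
#'   [read_temperature_log()] or [generate_temperature_log()].
#' @param start,end POSIXct window bounds (start < end, both within the log
#'   span, up to one cadence of slack at the end).
#' @param base_temp Base temperature in deg C, default 0.
#' @param method `"daily_mean"` (default) or `"per_reading"`.
#' @param cadence_min Expected reading interval in minutes; gaps larger than
#'   twice this raise a warning (linear coverage is then assumed).
#' @return Accumulated thermal time in degree-days (deg C d).
#' @examples
#' log <- generate_temperature_log(days = 40, mean_c = 20, sd_c = 0)
#' accumulate_thermal_time(log, log$timestamp[1],
#'                         log$timestamp[1] + 40 * 86400)  # 800
#' @export
accumulate_thermal_time <- function(log, start, end, base_temp = 0,
                                    method = c("daily_mean", "per_reading"),
                                    cadence_min = 30) {
  method <- match.arg(method)
  validate_temperature_log(log)
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(start < end)) stop("start must precede end", call. = FALSE)
  span <- range(log$timestamp)
  if (start < span[1] || end > span[2] + cadence_min * 60) {
    stop("window outside the span of the temperature log", call. = FALSE)
  }
  keep <- log$timestamp >= start & log$timestamp < end
  if (!any(keep)) stop("no readings in the requested window", call. = FALSE)
  sub <- log[keep, , drop = FALSE]
  gaps <- diff(as.numeric(sub$timestamp))
  if (length(gaps) && max(gaps) > 2 * cadence_min * 60) {
    warning("gap exceeding twice the cadence detected; ",
            "assuming linear coverage across the gap", call. = FALSE)
  }
  if (method == "per_reading") {
    dt_days <- cadence_min / (24 * 60)
    return(sum(pmax(0, sub$temp_c - base_temp)) * dt_days)
  }
  day <- format(sub$timestamp, "%Y-%m-%d", tz = "UTC")
  daily_mean <- tapply(sub$temp_c, day, mean)
  # fraction of each calendar day covered by the window, so that partial
  # first/last days contribute pro rata and adjacent windows add up
  day_starts <- as.POSIXct(paste0(names(daily_mean), " 00:00:00"), tz = "UTC")
  cover_from <- pmax(as.numeric(day_starts), as.numeric(start))
  cover_to <- pmin(as.numeric(day_starts) + 86400, as.numeric(end))
  frac <- (cover_to - cover_from) / 86400
  sum(pmax(0, daily_mean - base_temp) * frac)
}

#' Planting density
#'
#' Plants per square metre, rounded half-up to the nearest integer. With 35
#' pots in a 0.64 m2 grow tent this gives the design density of 55
#' plants/m2.
#'
#' @param pots Number of pots (non-negative count).
#' @param area_m2 Floor area in m2 (> 0).
#' @return Integer plants per m2.
#' @examples
#' planting_density(35, 0.64)  # 55
#' @export
planting_density <- function(pots, area_m2) {
  stopifnot(is.numeric(pots), pots >= 0)
  if (!is.numeric(area_m2) || area_m2 <= 0) {
    stop("area_m2 must be positive", call. = FALSE)
  }
  round_half_up(pots / area_m2)
}

# round half away from zero (the everyday convention; base round() is
# banker's rounding)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# truncate (toward zero) to a number of decimal places
trunc_decimals <- function(x, digits) {
  f <- 10^digits
  trunc(x * f) / f
}
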