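#' Define a speed-breeding lighting scenario
#'
#' Collects the assumptions behind the lighting energy/cost comparisons:
#' a 0.65-kW LED fixture covering 8 sq ft, a 22-h/day baseline photoperiod
#' run year-round, a UK commercial tariff of 0.22 currency units per kWh,
#' and (for lifetime bookkeeping in the horticultural benchmark the
#' figures derive from) 3,000 operating hours per year over a 15-year
#' fixture life. Annual photoperiod-cut savings use 365 days/year of
#' operation; the 3,000 h/yr figure serves only the lifetime-consumption
#' benchmark, because the two conventions describe different duty cycles.
#'
#' @param reduced_photoperiod_h Tailored photoperiod in h/day (required;
#'   `0 <= reduced < baseline <= 24`).
#' @param baseline_photoperiod_h Baseline photoperiod, default 22 h/day.
#' @param fixture_power_kw Fixture draw, default 0.65 kW.
#' @param fixture_area_sqft Area covered per fixture, default 8 sq ft.
#' @param days_per_year Operating days per year, default 365.
#' @param tariff_per_kwh Electricity price, default 0.22 (currency is a
#'   label, not converted; think GBP).
#' @param facility_area_sqft Total lit facility area (optional; needed by
#'   [facility_cost_saving()]).
#' @param annual_operating_hours Hours/yr for lifetime bookkeeping,
#'   default 3000.
#' @param lifetime_years Fixture lifetime, default 15.
#' @return A list with class `"energy_scenario"`.
#' @examples
#' sc <- energy_scenario(reduced_photoperiod_h = 20)
#' annual_fixture_saving(sc)  # 474.5 kWh
#' @export
energy_scenario <- function(reduced_photoperiod_h,
                            baseline_photoperiod_h = 22,
                            fixture_power_kw = 0.65,
                            fixture_area_sqft = 8,
                            days_per_year = 365,
                            tariff_per_kwh = 0.22,
                            facility_area_sqft = NULL,
                            annual_operating_hours = 3000,
                            lifetime_years = 15) {
  if (!(reduced_photoperiod_h >= 0 &&
        reduced_photoperiod_h <= baseline_photoperiod_h &&
        baseline_photoperiod_h <= 24)) {
    stop("need 0 <= reduced <= baseline <= 24 hours", call. = FALSE)
  }
  vals <- c(fixture_power_kw, fixture_area_sqft, days_per_year,
            tariff_per_kwh, annual_operating_hours, lifetime_years)
  if (any(vals < 0)) stop("scenario magnitudes must be non-negative",
                          call. = FALSE)
  structure(list(
    reduced_photoperiod_h = reduced_photoperiod_h,
    baseline_photoperiod_h = baseline_photoperiod_h,
    fixture_power_kw = fixture_power_kw,
    fixture_area_sqft = fixture_area_sqft,
    days_per_year = days_per_year,
    tariff_per_kwh = tariff_per_kwh,
    facility_area_sqft = facility_area_sqft,
    annual_operating_hours = annual_operating_hours,
    lifetime_years = lifetime_years
  ), class = "energy_scenario")
}

#' Lifetime electricity consumption of a lighting fixture
#'
#' `power_kw * hours_per_year * years`. At the benchmark assumptions
#' (0.65 kW, 3,000 h/yr, 15 years) this is 29,250 kWh.
#'
#' @param power_kw Fixture draw in kW.
#' @param hours_per_year Operating hours per year.
#' @param years Fixture lifetime in years.
#' @return kWh.
#' @export
lifetime_consumption <- function(power_kw, hours_per_year, years) {
  stopifnot(power_kw >= 0, hours_per_year >= 0, years >= 0)
  power_kw * hours_per_year * years
}

#' Lighting-cost saving per hour of photoperiod cut
#'
#' With lighting cost proportional to lit hours, each hour removed from a
#' `baseline_h`-hour photoperiod saves `100 / baseline_h` percent of the
#' lighting bill. The value is truncated (not rounded) to two decimals,
#' the convention under which a 22-h baseline gives 4.54 %/h.
#'
#' @param baseline_h Baseline photoperiod in h/day (> 0), default 22.
#' @return Percent per hour, truncated to 2 decimals.
#' @examples
#' hourly_fraction_saving(22)  # 4.54
#' @export
hourly_fraction_saving <- function(baseline_h = 22) {
  if (baseline_h <= 0) stop("baseline_h must be positive", call. = FALSE)
  trunc_decimals(100 / baseline_h, 2)
}

#' Fractional lighting reduction of a scenario
#'
#' `100 * (baseline - reduced) / baseline`, rounded half-up to the nearest
#' integer percent: cutting a 22-h photoperiod to 20 h saves 9%, to 16 h
#' saves 27%.
#'
#' @param scenario An [energy_scenario()].
#' @return Integer percent of daily lighting saved.
#' @export
fractional_saving <- function(scenario) {
  stopifnot(inherits(scenario, "energy_scenario"))
  delta <- scenario$baseline_photoperiod_h - scenario$reduced_photoperiod_h
  round_half_up(100 * delta / scenario$baseline_photoperiod_h)
}

#' Annual energy saving per fixture
#'
#' `fixture_power_kw * (baseline - reduced) hours/day * days_per_year`,
#' in kWh per fixture (per 8 sq ft at the default geometry) per year.
#' Returned unrounded; `report = TRUE` rounds half-up to the nearest kWh
#' for display (a 1-h cut gives 237.25, reported 237).
#'
#' @param scenario An [energy_scenario()].
#' @param report Round half-up to whole kWh, default `FALSE`.
#' @return kWh per fixture per year.
#' @export
annual_fixture_saving <- function(scenario, report = FALSE) {
  stopifnot(inherits(scenario, "energy_scenario"))
  delta <- scenario$baseline_photoperiod_h - scenario$reduced_photoperiod_h
  kwh <- scenario$fixture_power_kw * delta * scenario$days_per_year
  if (report) round_half_up(kwh) else kwh
}

#' Annual facility-level cost saving
#'
#' Scales the per-fixture saving to a whole facility:
#' `(facility_area / fixture_area) * annual_fixture_saving * tariff`.
#' The fixture count uses exact division (a non-integer count is allowed:
#' the quantity is lit area, not discrete hardware). For a 10,000 sq ft
#' facility, a 22 h to 20 h cut at 0.22/kWh saves 130,487.50/yr
#' (130,000 at the nearest 1,000).
#'
#' @param scenario An [energy_scenario()] with `facility_area_sqft` set.
#' @param report_nearest Round the reported value half-up to this unit
#'   (e.g. 1000); `NULL` (default) returns the exact value.
#' @return Currency per year.
#' @export
facility_cost_saving <- function(scenario, report_nearest = NULL) {
  stopifnot(inherits(scenario, "energy_scenario"))
  if (is.null(scenario$facility_area_sqft)) {
    stop("facility_area_sqft must be set in the scenario", call. = FALSE)
  }
  n_fixtures <- scenario$facility_area_sqft / scenario$fixture_area_sqft
  cost <- n_fixtures * annual_fixture_saving(scenario) *
    scenario$tariff_per_kwh
  if (is.null(report_nearest)) cost else
    round_half_up(cost / report_nearest) * report_nearest
}

#' Full energy ledger for a scenario
#'
#' Computes every quantity of the lighting model, reporting raw and
#' rounded ("reported") values side by side.
#'
#' @param scenario An [energy_scenario()].
#' @return A nested list ready for JSON serialisation.
#' @export
energy_report <- function(scenario) {
  stopifnot(inherits(scenario, "energy_scenario"))
  afs <- annual_fixture_saving(scenario)
  out <- list(
    scenario = unclass(scenario),
    lifetime_consumption_kwh = lifetime_consumption(
      scenario$fixture_power_kw, scenario$annual_operating_hours,
      scenario$lifetime_years),
    hourly_fraction_saving_pct = hourly_fraction_saving(
      scenario$baseline_photoperiod_h),
    fractional_saving_pct = fractional_saving(scenario),
    annual_fixture_saving_kwh = afs,
    annual_fixture_saving_kwh_reported = round_half_up(afs)
  )
  if (!is.null(scenario$facility_area_sqft)) {
    out$facility_cost_saving <- facility_cost_saving(scenario)
    out$facility_cost_saving_reported_nearest_1000 <-
      facility_cost_saving(scenario, report_nearest = 1000)
  }
  out
}
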