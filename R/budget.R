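# Annual per-site carbon balances, CO2-equivalent (GWP) balances, and
# landscape extrapolation by wetland-type surface.
#
# Sign convention throughout: negative = net C capture / warming mitigation,
# positive = net C release / warming.

#' Open-water C balance for one site and date
#'
#' The joint plankton + benthos balance (R - GPP) at a sampling date,
#' unweighted by coverage. Missing processes are treated as 0 with a warning.
#'
#' @param rates Data frame of metabolic rates for one site/date with columns
#'   `compartment`, `process`, `value_mg_c_m2_d`.
#' @return Signed balance in mg C m-2 d-1 (negative = C sink).
#' @export
date_balance <- function(rates) {
  check_columns(rates, c("compartment", "process", "value_mg_c_m2_d"), "rates")
  if (nrow(rates) < 1) stop("no rates supplied", call. = FALSE)
  pick <- function(comp, proc) {
    v <- rates$value_mg_c_m2_d[rates$compartment == comp & rates$process == proc]
    if (length(v) == 0) {
      warning("missing ", comp, " ", proc, ", treated as 0", call. = FALSE)
      return(0)
    }
    sum(v)
  }
  (pick("plankton", "R") + pick("benthos", "R")) -
    (pick("plankton", "GPP") + pick("benthos", "GPP"))
}

#' Annual areal rate from dated daily rates
#'
#' Period-weighted trapezoidal integration of bi-monthly (or otherwise
#' irregular) daily rates. A series spanning less than a year is closed to
#' 365 days by wrapping the gap between the last and first date with the
#' mean of the two endpoint values; a series spanning more than one year is
#' integrated over its full span and normalised to 365 days. A single date
#' extrapolates flat (value x 0.365).
#'
#' @param dates `Date` vector (or coercible), strictly increasing.
#' @param values Daily rates (mg C m-2 d-1) at those dates.
#' @return Annual rate in g C m-2 y-1.
#' @examples
#' d <- as.Date(c("2016-01-15", "2016-05-15", "2016-09-15"))
#' annual_process_rate(d, c(100, 100, 100)) # 36.5
#' @export
annual_process_rate <- function(dates, values) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values))
  if (length(dates) < 1) stop("no dated values", call. = FALSE)
  if (length(dates) == 1) {
    return(values * 365 / 1000)
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing (no duplicates)", call. = FALSE)
  }
  d <- as.numeric(dates - dates[1])
  span <- d[length(d)]
  trap <- sum(diff(d) * (head(values, -1) + tail(values, -1)) / 2)
  n <- length(values)
  if (span < 370) {
    gap <- (365 - span) %% 365
    total_mg <- trap + gap * (values[1] + values[n]) / 2
    total_mg / 1000
  } else {
    trap / span * 365 / 1000
  }
}

#' Coverage-weighted annual carbon budget of a wetland
#'
#' Combines the six annual areal process rates into a whole-wetland areal C
#' balance: open-water processes (plankton and benthos GPP and R, CH4
#' emission) weighted by the open-water fraction, vegetation production by
#' the vegetated fraction. CH4 cores are taken in the open-water compartment,
#' so CH4 is weighted by the open-water fraction by default
#' (`ch4_coverage = "open"`); `"total"` applies it to the whole surface.
#'
#' @param processes Named numeric of annual areal rates in g C m-2 y-1
#'   (magnitudes): `gpp_plankton`, `r_plankton`, `gpp_benthos`, `r_benthos`,
#'   `veg_production`, `ch4`. Missing names default to 0.
#' @param config Site configuration: a list with `vegetated_fraction`
#'   (in \[0, 1\]) and optionally `open_water_fraction` (default
#'   1 - vegetated), `site_id`, `wetland_type`.
#' @param constants GWP constants, as [gwp_constants()].
#' @param ch4_coverage `"open"` or `"total"`.
#' @return An `annual_budget` object: list with `site_id`, `wetland_type`,
#'   `processes`, `contributions` (six signed areal terms, g C m-2 y-1;
#'   negative = sink), `ch4_c` (the weighted CH4-C term), `c_balance`
#'   (their sum) and `gwp_balance` (g CO2-eq m-2 y-1).
#' @export
annual_budget <- function(processes, config,
                          constants = gwp_constants(),
                          ch4_coverage = c("open", "total")) {
  ch4_coverage <- match.arg(ch4_coverage)
  keys <- c(
    "gpp_plankton", "r_plankton", "gpp_benthos", "r_benthos",
    "veg_production", "ch4"
  )
  p <- setNames(rep(0, length(keys)), keys)
  stopifnot(is.numeric(processes), !is.null(names(processes)))
  unknown <- setdiff(names(processes), keys)
  if (length(unknown) > 0) {
    stop("unknown process name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(processes)] <- processes

  veg <- config$vegetated_fraction
  stopifnot(is.numeric(veg), veg >= 0, veg <= 1)
  open <- config$open_water_fraction
  if (is.null(open) || is.na(open)) open <- 1 - veg
  if (veg + open > 1 + 1e-9) {
    stop("vegetated + open-water fractions exceed 1", call. = FALSE)
  }
  w_ch4 <- if (ch4_coverage == "open") open else 1

  contributions <- c(
    gpp_plankton = -open * p[["gpp_plankton"]],
    r_plankton = open * p[["r_plankton"]],
    gpp_benthos = -open * p[["gpp_benthos"]],
    r_benthos = open * p[["r_benthos"]],
    veg_production = -veg * p[["veg_production"]],
    ch4 = w_ch4 * p[["ch4"]]
  )
  c_balance <- sum(contributions)
  budget <- structure(
    list(
      site_id = config$site_id %||% NA_character_,
      wetland_type = config$wetland_type %||% NA_character_,
      processes = p,
      contributions = contributions,
      ch4_c = contributions[["ch4"]],
      c_balance = c_balance,
      gwp_balance = NA_real_
    ),
    class = "annual_budget"
  )
  budget$gwp_balance <- gwp_of_budget(budget, constants)
  budget
}

#' @export
print.annual_budget <- function(x, ...) {
  cat(sprintf(
    "Annual budget for %s (%s)\n", x$site_id, x$wetland_type
  ))
  for (nm in names(x$contributions)) {
    cat(sprintf("  %-15s %10.2f g C m-2 y-1\n", nm, x$contributions[[nm]]))
  }
  cat(sprintf("  C balance:   %10.2f g C m-2 y-1\n", x$c_balance))
  cat(sprintf("  GWP balance: %10.2f g CO2-eq m-2 y-1\n", x$gwp_balance))
  invisible(x)
}

#' CO2-equivalent balance of an annual carbon budget
#'
#' Mass-based GWP accounting: the net CO2-carbon flux (total balance minus
#' the CH4-carbon term) scales by 44/12 to CO2 gas mass; the CH4-carbon
#' term scales by 16/12 to CH4 gas mass and is weighted by the CH4/CO2
#' factor (28).
#'
#' @param budget An `annual_budget`, or a plain list with elements
#'   `c_balance` and `ch4_c` in g C m-2 y-1.
#' @param constants GWP constants, as [gwp_constants()].
#' @return GWP balance in g CO2-eq m-2 y-1 (negative = mitigation).
#' @examples
#' gwp_of_budget(list(c_balance = -42, ch4_c = 0)) # -154
#' @export
gwp_of_budget <- function(budget, constants = gwp_constants()) {
  b <- budget$c_balance
  ch4_c <- budget$ch4_c %||% 0
  (b - ch4_c) * constants$co2_per_c +
    ch4_c * constants$ch4_per_c * constants$ch4_co2_factor
}

#' Annual CH4-carbon flux implied by a (C balance, GWP balance) pair
#'
#' Exact inverse of [gwp_of_budget()]: given the areal C balance and GWP
#' balance of a site, returns the annual CH4-C flux consistent with both.
#'
#' @param c_balance Annual C balance (g C m-2 y-1).
#' @param gwp_balance Annual GWP balance (g CO2-eq m-2 y-1).
#' @param constants GWP constants, as [gwp_constants()].
#' @return CH4-C flux in g C m-2 y-1.
#' @examples
#' infer_ch4_from_balance_pair(-42, -29) # ~3.71
#' @export
infer_ch4_from_balance_pair <- function(c_balance, gwp_balance,
                                        constants = gwp_constants()) {
  denom <- constants$ch4_per_c * constants$ch4_co2_factor - constants$co2_per_c
  (gwp_balance - c_balance * constants$co2_per_c) / denom
}

#' Extrapolate an areal balance to a wetland-type surface
#'
#' @param areal_balance Areal rate in g m-2 y-1 (C or CO2-eq).
#' @param surface_ha Surface of the wetland type in hectares; must be > 0.
#' @return Landscape flux in metric tonnes per year (Tn y-1):
#'   areal x surface / 100 (1 ha = 1e4 m2, 1 Tn = 1e6 g).
#' @examples
#' extrapolate_balance(-100, 1) # -1 Tn y-1
#' @export
extrapolate_balance <- function(areal_balance, surface_ha) {
  if (any(!is.finite(surface_ha)) || any(surface_ha <= 0)) {
    stop("`surface_ha` must be positive", call. = FALSE)
  }
  areal_balance * surface_ha / 100
}

#' Landscape totals and per-type shares
#'
#' @param per_type Data frame with one row per wetland type and columns
#'   `wetland_type`, `c_tn_y` and optionally `co2eq_tn_y`.
#' @return List with `c_total_tn_y`, `co2eq_total_tn_y` and `table` (the
#'   input with a `share` column, each type's fraction of the C total).
#' @export
landscape_totals <- function(per_type) {
  check_columns(per_type, c("wetland_type", "c_tn_y"), "per_type")
  if (nrow(per_type) < 1) stop("no wetland types supplied", call. = FALSE)
  c_total <- sum(per_type$c_tn_y)
  co2_total <- if ("co2eq_tn_y" %in% names(per_type)) {
    sum(per_type$co2eq_tn_y)
  } else {
    NA_real_
  }
  per_type$share <- per_type$c_tn_y / c_total
  list(c_total_tn_y = c_total, co2eq_total_tn_y = co2_total, table = per_type)
}

#' Annual budgets for every site in a metabolic-rates table
#'
#' Integrates each process series to an annual areal rate with
#' [annual_process_rate()] and assembles the coverage-weighted budget and
#' GWP balance per site.
#'
#' @param rates Tibble of metabolic rates (`site_id`, `date`, `compartment`,
#'   `process`, `value_mg_c_m2_d`), as produced by [oxygen_rates()],
#'   [vegetation_rates()] and [site_flux()] bound together.
#' @param sites Site configuration as returned by [read_sites()]: a list
#'   with a `sites` tibble (`site_id`, `wetland_type`, `vegetated_fraction`,
#'   `plant_type`, `surface_ha`) and a `constants` list (`ch4_co2_factor`,
#'   `ch4_coverage`).
#' @return Tibble with one row per site: the six annual process rates
#'   (g C m-2 y-1), `c_balance_g_c_m2_y` and `gwp_g_co2eq_m2_y`; the full
#'   `annual_budget` objects are attached as attribute `"budgets"`.
#' @export
site_budgets <- function(rates, sites) {
  check_columns(
    rates, c("site_id", "date", "compartment", "process", "value_mg_c_m2_d"),
    "rates"
  )
  rates <- dplyr::mutate(rates, date = as.Date(.data$date))
  cfg <- sites$sites
  constants <- gwp_constants(sites$constants$ch4_co2_factor %||% 28)
  ch4_cov <- sites$constants$ch4_coverage %||% "open"

  proc_map <- list(
    gpp_plankton = c("plankton", "GPP"),
    r_plankton = c("plankton", "R"),
    gpp_benthos = c("benthos", "GPP"),
    r_benthos = c("benthos", "R"),
    veg_production = c("vegetation", "VEG_P"),
    ch4 = c("sediment", "CH4")
  )

  budgets <- lapply(seq_len(nrow(cfg)), function(i) {
    site <- cfg$site_id[i]
    sr <- rates[rates$site_id == site, ]
    ann <- vapply(proc_map, function(cp) {
      sub <- sr[sr$compartment == cp[1] & sr$process == cp[2], ]
      if (nrow(sub) == 0) {
        return(0)
      }
      sub <- sub[order(sub$date), ]
      annual_process_rate(sub$date, sub$value_mg_c_m2_d)
    }, numeric(1))
    annual_budget(
      ann,
      config = list(
        site_id = site,
        wetland_type = cfg$wetland_type[i],
        vegetated_fraction = cfg$vegetated_fraction[i],
        open_water_fraction = cfg$open_water_fraction[i] %||% NULL
      ),
      constants = constants,
      ch4_coverage = ch4_cov
    )
  })

  out <- dplyr::bind_rows(lapply(budgets, function(b) {
    tibble::tibble(
      site_id = b$site_id,
      wetland_type = b$wetland_type,
      gpp_plankton = b$processes[["gpp_plankton"]],
      r_plankton = b$processes[["r_plankton"]],
      gpp_benthos = b$processes[["gpp_benthos"]],
      r_benthos = b$processes[["r_benthos"]],
      veg_production = b$processes[["veg_production"]],
      ch4 = b$processes[["ch4"]],
      c_balance_g_c_m2_y = b$c_balance,
      gwp_g_co2eq_m2_y = b$gwp_balance
    )
  }))
  attr(out, "budgets") <- budgets
  out
}

#' Extrapolate per-site budgets to the landscape
#'
#' @param budgets Tibble from [site_budgets()].
#' @param sites Site configuration as in [site_budgets()].
#' @return Tibble with `wetland_type`, `surface_ha`, `c_tn_y`, `co2eq_tn_y`
#'   and `share` (fraction of the C total).
#' @export
landscape_extrapolation <- function(budgets, sites) {
  cfg <- sites$sites
  joined <- dplyr::left_join(
    budgets, cfg[, c("site_id", "surface_ha")],
    by = "site_id"
  )
  per_type <- tibble::tibble(
    wetland_type = joined$wetland_type,
    surface_ha = joined$surface_ha,
    c_tn_y = extrapolate_balance(joined$c_balance_g_c_m2_y, joined$surface_ha),
    co2eq_tn_y = extrapolate_balance(joined$gwp_g_co2eq_m2_y, joined$surface_ha)
  )
  totals <- landscape_totals(per_type)
  totals$table
}

#' Published landscape reference for the Ebro Delta wetland types
#'
#' The published per-type surfaces and extrapolated annual C and GWP
#' balances for the three main wetland types of the Ebro Delta (NE Spain),
#' used as a desk-scale reference for the landscape arithmetic.
#'
#' @return Tibble with `wetland_type`, `surface_ha`, `c_tn_y`, `co2eq_tn_y`.
#' @export
ebro_delta_reference <- function() {
  tibble::tibble(
    wetland_type = c("salt_marsh", "brackish", "freshwater"),
    surface_ha = c(1292.43, 1797.40, 563.06),
    c_tn_y = c(-546.51, -4514.50, -1225.37),
    co2eq_tn_y = c(-378.17, -2224.97, -358.14)
  )
}

#' Published per-site annual areal balances for the Ebro Delta sites
#'
#' The published annual areal C balances and GWP balances of the three
#' studied sites (salt marsh, brackish lagoon, restored freshwater wetland),
#' used for consistency checks such as [infer_ch4_from_balance_pair()].
#'
#' @return Tibble with `wetland_type`, `c_balance_g_c_m2_y`,
#'   `gwp_g_co2eq_m2_y`.
#' @export
ebro_annual_balances <- function() {
  tibble::tibble(
    wetland_type = c("salt_marsh", "brackish", "freshwater"),
    c_balance_g_c_m2_y = c(-42, -251, -210),
    gwp_g_co2eq_m2_y = c(-29, -124, -64)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
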