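# Light/dark oxygen incubations -> areal daily GPP, NCP and R in carbon units.
#
# Chain: per-bottle volumetric O2 rate -> per-replicate areal hourly rate
# (depth integration for plankton, jar volume/footprint for benthos) ->
# replicate means (NCP from light, R from dark) -> carbon units -> diel
# scaling (GPP over daylight hours, R over 24 h).

#' Volumetric oxygen rate of one bottle or jar
#'
#' @param o2_start,o2_end Dissolved O2 at start and end (mg O2 L-1).
#' @param duration_h Incubation length in hours (2-4 h typical); must be > 0.
#' @return Signed rate in mg O2 L-1 h-1: positive in light bottles with net
#'   production, negative in dark bottles (its magnitude is respiration).
#' @examples
#' bottle_rate(8.0, 8.8, 4) # +0.2
#' bottle_rate(8.0, 7.6, 4) # -0.1
#' @export
bottle_rate <- function(o2_start, o2_end, duration_h) {
  if (any(!is.finite(duration_h)) || any(duration_h <= 0)) {
    stop("`duration_h` must be positive", call. = FALSE)
  }
  if (any(o2_start < 0) || any(o2_end < 0)) {
    stop("O2 concentrations must be non-negative", call. = FALSE)
  }
  (o2_end - o2_start) / duration_h
}

#' Community metabolic rates from replicated light and dark incubations
#'
#' NCP is the mean of the light replicates; R is the magnitude of the mean
#' dark rate; GPP = NCP + R. Rates may be volumetric or areal as long as
#' light and dark share units. Net O2 production in the dark (mean dark
#' rate > 0) is physically uninterpretable as aerobic respiration: R is
#' clipped to 0 and the result flagged.
#'
#' @param light,dark Numeric vectors of per-replicate rates (>= 1 each).
#' @return A list: `ncp`, `r`, `gpp` (same units as input), replicate sds
#'   `ncp_sd`, `r_sd`, `gpp_sd` (quadrature of the two), counts `n_light`,
#'   `n_dark`, and logical `dark_production` flag.
#' @examples
#' community_rates(light = rep(0.2, 4), dark = rep(-0.1, 4))
#' @export
community_rates <- function(light, dark) {
  if (length(light) < 1 || length(dark) < 1) {
    stop("need at least one light and one dark replicate", call. = FALSE)
  }
  ncp <- mean(light)
  dark_mean <- mean(dark)
  dark_production <- dark_mean > 0
  if (dark_production) {
    warning("net O2 production in the dark; R clipped to 0", call. = FALSE)
    r <- 0
  } else {
    r <- -dark_mean
  }
  ncp_sd <- if (length(light) > 1) sd(light) else NA_real_
  r_sd <- if (length(dark) > 1) sd(dark) else NA_real_
  gpp_sd <- sqrt(sum(c(ncp_sd, r_sd)^2, na.rm = TRUE))
  list(
    ncp = ncp, r = r, gpp = ncp + r,
    ncp_sd = ncp_sd, r_sd = r_sd, gpp_sd = gpp_sd,
    n_light = length(light), n_dark = length(dark),
    dark_production = dark_production
  )
}

#' Depth-integrate a volumetric plankton rate to an areal rate
#'
#' Assumes a vertically well-mixed water column (the target systems are
#' 0.2-0.5 m deep), so the areal rate is volumetric rate x 1000 L m-3 x depth.
#'
#' @param rate Volumetric rate (mg L-1 h-1).
#' @param depth_m Water-column depth in metres; must be > 0.
#' @return Areal rate in mg m-2 h-1.
#' @examples
#' plankton_areal(0.3, 0.45) # 135
#' @export
plankton_areal <- function(rate, depth_m) {
  if (any(!is.finite(depth_m)) || any(depth_m <= 0)) {
    stop("`depth_m` must be positive", call. = FALSE)
  }
  rate * 1000 * depth_m
}

#' Convert a benthic jar volumetric rate to an areal rate
#'
#' A bell jar of enclosed volume V (litres) staked over a footprint A (m2)
#' relates concentration change to sediment-surface exchange as rate x V / A.
#'
#' @param rate Volumetric rate (mg L-1 h-1).
#' @param enclosed_volume_l Litres of water enclosed by the jar.
#' @param basal_area_m2 Jar footprint on the sediment in m2; must be > 0.
#' @return Areal rate in mg m-2 h-1.
#' @examples
#' benthic_areal(0.2, 2, 0.02) # 20
#' @export
benthic_areal <- function(rate, enclosed_volume_l, basal_area_m2) {
  if (any(!is.finite(basal_area_m2)) || any(basal_area_m2 <= 0)) {
    stop("`basal_area_m2` must be positive", call. = FALSE)
  }
  rate * enclosed_volume_l / basal_area_m2
}

#' Scale hourly rates to diel (daily) estimates
#'
#' GPP only runs during daylight; respiration is assumed constant over 24 h.
#' NCP is their daily difference.
#'
#' @param gpp_hourly,r_hourly Hourly areal rates (mg C m-2 h-1), magnitudes.
#' @param daylight_h Daytime length in hours, within \[0, 24\].
#' @return List with `gpp`, `r`, `ncp` in mg C m-2 d-1.
#' @examples
#' diel_scale(10, 5, 12) # GPP 120, R 120, NCP 0
#' @export
diel_scale <- function(gpp_hourly, r_hourly, daylight_h) {
  if (any(!is.finite(daylight_h)) || any(daylight_h < 0) || any(daylight_h > 24)) {
    stop("`daylight_h` must lie in [0, 24]", call. = FALSE)
  }
  gpp <- gpp_hourly * daylight_h
  r <- r_hourly * 24
  list(gpp = gpp, r = r, ncp = gpp - r)
}

#' Day length from the solar-declination formula
#'
#' Fallback when the observed daytime length of a campaign was not recorded.
#' Uses the Cooper declination approximation and the sunset hour angle;
#' accurate to ~0.2 h outside polar latitudes.
#'
#' @param date A `Date` (or coercible) vector.
#' @param latitude_deg Latitude in decimal degrees; |latitude| must be
#'   < 66.5 (no polar day/night).
#' @return Hours of daylight.
#' @examples
#' daylight_hours(as.Date("2016-03-21"), 40.65) # ~12 h
#' @export
daylight_hours <- function(date, latitude_deg = 40.65) {
  if (any(abs(latitude_deg) >= 66.5)) {
    stop("polar latitudes are not supported", call. = FALSE)
  }
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  decl <- 23.44 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  lat <- latitude_deg * pi / 180
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  24 * acos(x) / pi
}

#' Areal daily metabolic rates from an oxygen-incubation table
#'
#' Runs the full chain for every site/date/compartment group of a tidy
#' incubation table: per-bottle volumetric rates, areal normalisation
#' (depth integration for plankton, jar geometry for benthos), replicate
#' aggregation, O2 -> C stoichiometry and diel scaling.
#'
#' @param incubations Data frame with columns `site_id`, `date`,
#'   `compartment` ("plankton"/"benthos"), `treatment` ("light"/"dark"),
#'   `replicate`, `o2_start_mg_l`, `o2_end_mg_l`, `duration_h`, and for
#'   benthos `enclosed_volume_l`, `basal_area_m2`.
#' @param campaigns Data frame with `site_id`, `date`, `daylight_h`,
#'   `depth_m` (plus any other campaign metadata).
#' @param pq,rq Photosynthetic and respiratory quotients (mol O2 per mol C);
#'   defaults 1. GPP and NCP are divided by `pq`, R multiplied by `rq`.
#' @return A tibble of metabolic rates: `site_id`, `date`, `compartment`,
#'   `process` ("GPP", "NCP", "R"), `value_mg_c_m2_d`, `sd`, `n`. GPP and R
#'   are magnitudes; NCP is signed. For every group GPP = NCP + R by
#'   construction.
#' @export
oxygen_rates <- function(incubations, campaigns, pq = 1, rq = 1) {
  stopifnot(pq > 0, rq > 0)
  need <- c(
    "site_id", "date", "compartment", "treatment",
    "o2_start_mg_l", "o2_end_mg_l", "duration_h"
  )
  check_columns(incubations, need, "incubations")
  check_columns(campaigns, c("site_id", "date", "daylight_h", "depth_m"), "campaigns")
  bad <- setdiff(unique(incubations$compartment), c("plankton", "benthos"))
  if (length(bad) > 0) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  inc <- dplyr::left_join(
    dplyr::mutate(incubations, date = as.Date(.data$date)),
    dplyr::mutate(campaigns, date = as.Date(.data$date)),
    by = c("site_id", "date")
  )
  if (anyNA(inc$daylight_h) || anyNA(inc$depth_m)) {
    stop("every incubation needs a matching campaign row", call. = FALSE)
  }

  inc$vol_rate <- bottle_rate(inc$o2_start_mg_l, inc$o2_end_mg_l, inc$duration_h)
  inc$areal_o2 <- NA_real_
  is_p <- inc$compartment == "plankton"
  if (any(is_p)) {
    inc$areal_o2[is_p] <- plankton_areal(inc$vol_rate[is_p], inc$depth_m[is_p])
  }
  if (any(!is_p)) {
    check_columns(inc, c("enclosed_volume_l", "basal_area_m2"), "incubations")
    inc$areal_o2[!is_p] <- benthic_areal(
      inc$vol_rate[!is_p], inc$enclosed_volume_l[!is_p], inc$basal_area_m2[!is_p]
    )
  }

  groups <- dplyr::group_split(
    dplyr::group_by(inc, .data$site_id, .data$date, .data$compartment)
  )
  rows <- lapply(groups, function(g) {
    light <- g$areal_o2[g$treatment == "light"]
    dark <- g$areal_o2[g$treatment == "dark"]
    comm <- community_rates(light, dark)
    gpp_h <- o2_to_carbon(comm$gpp) / pq
    r_h <- o2_to_carbon(comm$r) * rq
    ncp_h <- gpp_h - r_h
    daylight <- g$daylight_h[1]
    daily <- diel_scale(gpp_h, r_h, daylight)
    gpp_sd <- o2_to_carbon(comm$gpp_sd) / pq * daylight
    r_sd <- o2_to_carbon(comm$r_sd) * rq * 24
    tibble::tibble(
      site_id = g$site_id[1],
      date = g$date[1],
      compartment = g$compartment[1],
      process = c("GPP", "NCP", "R"),
      value_mg_c_m2_d = c(daily$gpp, daily$ncp, daily$r),
      sd = c(gpp_sd, sqrt(sum(c(gpp_sd, r_sd)^2, na.rm = TRUE)), r_sd),
      n = c(comm$n_light, comm$n_light, comm$n_dark)
    )
  })
  out <- dplyr::bind_rows(rows)
  neg_gpp <- out$process == "GPP" & out$value_mg_c_m2_d < 0
  if (any(neg_gpp)) {
    warning(
      sum(neg_gpp), " group(s) with negative mean GPP retained (measurement noise)",
      call. = FALSE
    )
  }
  dplyr::arrange(out, .data$site_id, .data$date, .data$compartment, .data$process)
}
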