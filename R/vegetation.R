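# Quadrat harvest dry weights -> standing C stocks and interval net
# production for helophytes (reed-type) and halophytes (Salicornia-type).

#' Standing vegetation carbon stock from quadrat harvests
#'
#' Mean above-ground dry weight per m2 across replicate quadrats, converted
#' to carbon with the plant-type coefficient (see [carbon_coefficients()]).
#'
#' @param harvests Data frame for one site/date with columns `plant_type`
#'   ("helophyte"/"halophyte"), `dry_weight_g` and `quadrat_area_m2`
#'   (typically 15 quadrats of 0.25 m2).
#' @param coeffs Carbon coefficients, as [carbon_coefficients()].
#' @return List with `stock_g_c_m2` (mean), `sd`, `n` and `plant_type`.
#' @examples
#' standing_stock(data.frame(
#'   plant_type = "helophyte", dry_weight_g = 100, quadrat_area_m2 = 0.25
#' )) # 400 g DW m-2 x 0.45 = 180 g C m-2
#' @export
standing_stock <- function(harvests, coeffs = carbon_coefficients()) {
  check_columns(harvests, c("plant_type", "dry_weight_g", "quadrat_area_m2"), "harvests")
  if (nrow(harvests) < 1) stop("need at least one quadrat", call. = FALSE)
  type <- unique(harvests$plant_type)
  if (length(type) != 1) {
    stop("mixed plant types in one harvest set", call. = FALSE)
  }
  if (!type %in% names(coeffs)) {
    stop("unknown plant type: ", type, call. = FALSE)
  }
  if (any(harvests$dry_weight_g < 0) || any(harvests$quadrat_area_m2 <= 0)) {
    stop("dry weights must be >= 0 and quadrat areas > 0", call. = FALSE)
  }
  dens <- harvests$dry_weight_g / harvests$quadrat_area_m2
  coef <- coeffs[[type]]
  list(
    stock_g_c_m2 = mean(dens) * coef,
    sd = if (length(dens) > 1) sd(dens) * coef else NA_real_,
    n = length(dens),
    plant_type = type
  )
}

#' Net vegetation production between two sampling events
#'
#' The somatic-growth increment between consecutive standing stocks, as a
#' daily areal rate. Negative differences (senescence) are clipped to 0 by
#' default, with the raw signed rate reported alongside.
#'
#' @param stock_t1,stock_t2 Standing stocks (g C m-2) at the earlier and
#'   later event.
#' @param interval_days Days between the events; must be > 0.
#' @param clip_negative Clip negative production to 0 (default TRUE).
#' @return List with `production_mg_c_m2_d` and `raw_mg_c_m2_d` (the
#'   unclipped signed rate).
#' @examples
#' interval_production(100, 160, 60) # 1000 mg C m-2 d-1
#' interval_production(160, 120, 60) # clipped to 0, raw -666.7
#' @export
interval_production <- function(stock_t1, stock_t2, interval_days,
                                clip_negative = TRUE) {
  if (any(!is.finite(interval_days)) || any(interval_days <= 0)) {
    stop("`interval_days` must be positive", call. = FALSE)
  }
  raw <- (stock_t2 - stock_t1) * 1000 / interval_days
  prod <- if (clip_negative) pmax(raw, 0) else raw
  list(production_mg_c_m2_d = prod, raw_mg_c_m2_d = raw)
}

#' Vegetation production rates from a quadrat-harvest table
#'
#' Computes per-date standing stocks (quadrat means) for each site and the
#' interval net production between consecutive sampling events, assigned to
#' the end date of each interval.
#'
#' @param quadrats Data frame with `site_id`, `date`, `plant_type`,
#'   `dry_weight_g`, `quadrat_area_m2`.
#' @param coeffs Carbon coefficients, as [carbon_coefficients()].
#' @param clip_negative Clip negative interval production to 0 (default TRUE).
#' @return A tibble of rates: `site_id`, `date`, `compartment` =
#'   "vegetation", `process` = "VEG_P", `value_mg_c_m2_d`, `sd` (sd of the
#'   mean stock difference, independence between dates), `n`, plus
#'   `raw_mg_c_m2_d`. The per-date stocks are attached as attribute
#'   `"stocks"` (also returned by [vegetation_stocks()]).
#' @export
vegetation_rates <- function(quadrats, coeffs = carbon_coefficients(),
                             clip_negative = TRUE) {
  stocks <- vegetation_stocks(quadrats, coeffs)
  rows <- lapply(split(stocks, stocks$site_id), function(s) {
    s <- s[order(s$date), ]
    if (nrow(s) < 2) {
      return(NULL)
    }
    i <- seq_len(nrow(s) - 1)
    days <- as.numeric(s$date[i + 1] - s$date[i])
    p <- interval_production(
      s$stock_g_c_m2[i], s$stock_g_c_m2[i + 1], days, clip_negative
    )
    # sd of the mean stock difference, x1000/days to the rate scale
    sd_diff <- sqrt(s$sd[i]^2 / s$n[i] + s$sd[i + 1]^2 / s$n[i + 1]) * 1000 / days
    tibble::tibble(
      site_id = s$site_id[1],
      date = s$date[i + 1],
      compartment = "vegetation",
      process = "VEG_P",
      value_mg_c_m2_d = p$production_mg_c_m2_d,
      sd = sd_diff,
      n = pmin(s$n[i], s$n[i + 1]),
      raw_mg_c_m2_d = p$raw_mg_c_m2_d
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "stocks") <- stocks
  out
}

#' Per-date standing stocks for each site
#'
#' @inheritParams vegetation_rates
#' @return Tibble with `site_id`, `date`, `plant_type`, `stock_g_c_m2`,
#'   `sd`, `n`.
#' @export
vegetation_stocks <- function(quadrats, coeffs = carbon_coefficients()) {
  check_columns(
    quadrats,
    c("site_id", "date", "plant_type", "dry_weight_g", "quadrat_area_m2"),
    "quadrats"
  )
  quadrats <- dplyr::mutate(quadrats, date = as.Date(.data$date))
  groups <- dplyr::group_split(dplyr::group_by(quadrats, .data$site_id, .data$date))
  dplyr::bind_rows(lapply(groups, function(g) {
    st <- standing_stock(g, coeffs)
    tibble::tibble(
      site_id = g$site_id[1], date = g$date[1], plant_type = st$plant_type,
      stock_g_c_m2 = st$stock_g_c_m2, sd = st$sd, n = st$n
    )
  }))
}
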