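# Sediment-core headspace CH4 incubations -> areal emission rates, and the
# fitted response of those rates to temperature (exponential) and salinity
# (power law on conductivity).

#' Headspace volume of a sediment-core tube
#'
#' The cores are methacrylate tubes (default 50 cm x 4 cm diameter) holding
#' a sediment layer and a water layer, with an air headspace above in which
#' CH4 accumulates.
#'
#' @param tube_length_cm,tube_diameter_cm Tube geometry in cm.
#' @param sediment_depth_cm,water_depth_cm Sediment and water layer heights.
#' @return Headspace volume in litres.
#' @examples
#' headspace_volume(50, 4, 7.5, 20) # 0.2827 L
#' @export
headspace_volume <- function(tube_length_cm = 50, tube_diameter_cm = 4,
                             sediment_depth_cm, water_depth_cm) {
  head_cm <- tube_length_cm - sediment_depth_cm - water_depth_cm
  if (any(!is.finite(head_cm)) || any(head_cm <= 0)) {
    stop("sediment + water must leave a positive headspace", call. = FALSE)
  }
  pi * (tube_diameter_cm / 2)^2 * head_cm / 1000
}

#' Headspace CH4 mixing-ratio change to carbon mass
#'
#' Ideal-gas conversion of a ppmv change in a known headspace volume at the
#' incubation temperature and pressure: mol CH4 = dppm x 1e-6 x PV / (R T),
#' mass C = mol x 12.011 g/mol.
#'
#' @param delta_ppm Change in CH4 mixing ratio (ppmv).
#' @param volume_l Headspace volume (litres); must be > 0.
#' @param temp_c Incubation temperature (deg C); must exceed -273.15.
#' @param pressure_atm Headspace pressure (atm), default 1.
#' @return Carbon mass in mg CH4-C (signed as `delta_ppm`).
#' @examples
#' ppm_to_mass_c(500, 0.2827, 20) # ~0.0706 mg C
#' @export
ppm_to_mass_c <- function(delta_ppm, volume_l, temp_c, pressure_atm = 1) {
  if (any(volume_l <= 0)) stop("`volume_l` must be positive", call. = FALSE)
  if (any(temp_c <= -273.15)) stop("temperature below absolute zero", call. = FALSE)
  mol <- delta_ppm * 1e-6 * pressure_atm * volume_l /
    (GAS_CONSTANT_L_ATM * (temp_c + 273.15))
  mol * C_MOLAR_MASS * 1000
}

#' Areal CH4 flux of sediment cores
#'
#' Net methanogenesis-methanotrophy balance per core: headspace CH4
#' accumulation over the incubation, converted to carbon mass and normalised
#' by the core cross-section and the incubation length. Negative accumulation
#' (net methanotrophy) is kept but flagged with a message.
#'
#' @param cores Data frame with columns `tube_length_cm`, `tube_diameter_cm`,
#'   `sediment_depth_cm`, `water_depth_cm`, `duration_d`, `ch4_ppm_start`,
#'   `ch4_ppm_end`, `temp_c`, and optionally `pressure_atm` (default 1).
#' @return Numeric vector of fluxes in mg CH4-C m-2 d-1, one per row.
#' @export
core_flux <- function(cores) {
  check_columns(cores, c(
    "tube_length_cm", "tube_diameter_cm", "sediment_depth_cm",
    "water_depth_cm", "duration_d", "ch4_ppm_start", "ch4_ppm_end", "temp_c"
  ), "cores")
  if (any(cores$duration_d <= 0)) {
    stop("`duration_d` must be positive", call. = FALSE)
  }
  if (any(cores$ch4_ppm_start < 0) || any(cores$ch4_ppm_end < 0)) {
    stop("ppm readings must be non-negative", call. = FALSE)
  }
  pressure <- if ("pressure_atm" %in% names(cores)) cores$pressure_atm else 1
  vol_l <- headspace_volume(
    cores$tube_length_cm, cores$tube_diameter_cm,
    cores$sediment_depth_cm, cores$water_depth_cm
  )
  mass_mg <- ppm_to_mass_c(
    cores$ch4_ppm_end - cores$ch4_ppm_start, vol_l, cores$temp_c, pressure
  )
  area_m2 <- pi * (cores$tube_diameter_cm / 2 / 100)^2
  flux <- mass_mg / area_m2 / cores$duration_d
  if (any(flux < 0)) {
    message(sum(flux < 0), " core(s) with net CH4 uptake (negative flux)")
  }
  flux
}

#' Site-level CH4 emission rates from replicated cores
#'
#' Mean and replicate sd of the per-core fluxes for each site/date
#' (the field design uses 12 replicate cores).
#'
#' @param cores Data frame as in [core_flux()] plus `site_id` and `date`.
#' @return Tibble of rates: `site_id`, `date`, `compartment` = "sediment",
#'   `process` = "CH4", `value_mg_c_m2_d`, `sd`, `n`.
#' @export
site_flux <- function(cores) {
  check_columns(cores, c("site_id", "date"), "cores")
  if (nrow(cores) < 1) stop("no cores supplied", call. = FALSE)
  cores <- dplyr::mutate(cores, date = as.Date(.data$date))
  cores$flux <- core_flux(cores)
  out <- dplyr::summarise(
    dplyr::group_by(cores, .data$site_id, .data$date),
    compartment = "sediment",
    process = "CH4",
    value_mg_c_m2_d = mean(.data$flux),
    sd = if (dplyr::n() > 1) sd(.data$flux) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' @rdname site_flux
#' @export
methane_rates <- site_flux

# Nonlinear refinement with a guard for exact-fit data: nls-type models
# error on zero-residual input ("singular gradient"), in which case the
# initialisation already solves the problem and is returned with zero
# standard errors.
refine_nls <- function(formula, data, start) {
  tryCatch(
    {
      fit <- minpack.lm::nlsLM(
        formula,
        data = data, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      list(
        est = coef(fit),
        se = tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
          c(a = NA_real_, b = NA_real_)
        }),
        fitted = unname(stats::fitted(fit))
      )
    },
    error = function(e) {
      env <- c(as.list(data), start)
      fitted <- eval(formula[[3]], envir = env)
      resid <- data$flux - fitted
      if (sum(resid^2) > 1e-8 * max(1, sum(data$flux^2))) stop(e)
      list(
        est = unlist(start),
        se = c(a = 0, b = 0),
        fitted = fitted
      )
    }
  )
}

response_fit <- function(model, fit, flux) {
  fitted <- fit$fitted
  ss_res <- sum((flux - fitted)^2)
  ss_tot <- sum((flux - mean(flux))^2)
  r <- if (sd(fitted) > 0 && sd(flux) > 0) {
    cor(flux, fitted)
  } else if (ss_tot <= .Machine$double.eps * max(1, sum(flux^2))) {
    # constant observed flux fitted exactly: perfect but degenerate fit
    if (ss_res <= 1e-12 * max(1, ss_tot)) 1 else 0
  } else {
    0
  }
  n <- length(flux)
  p <- if (n > 2 && abs(r) < 1) {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), df = n - 2)
  } else if (abs(r) >= 1) {
    0
  } else {
    NA_real_
  }
  est <- fit$est
  se <- fit$se
  structure(
    list(
      model = model,
      a = unname(est["a"]), b = unname(est["b"]),
      se_a = unname(se["a"]), se_b = unname(se["b"]),
      r = r, p_value = p, n_points = n, df = n - 2
    ),
    class = "response_fit"
  )
}

#' @export
print.response_fit <- function(x, ...) {
  form <- if (x$model == "exponential_temperature") {
    "flux = a * exp(b * T)"
  } else {
    "flux = a * conductivity^b"
  }
  cat(sprintf(
    "%s fit  %s\n  a = %.4g (se %.3g), b = %.4g (se %.3g)\n  r = %.3f, p = %.3g, n = %d\n",
    x$model, form, x$a, x$se_a, x$b, x$se_b, x$r, x$p_value, x$n_points
  ))
  invisible(x)
}

#' Fit the exponential temperature response of CH4 emission
#'
#' Fits flux = a * exp(b * T) by nonlinear least squares, initialised from
#' the log-linear regression of log(flux) on temperature (positive fluxes
#' only; all points enter the nonlinear refinement). The fit quality `r` is
#' the correlation between observed and fitted fluxes, with a p-value from
#' the t-transform on n - 2 degrees of freedom.
#'
#' @param temp_c Incubation temperatures (deg C); at least 3 distinct values
#'   (the manipulation design uses 14, 20, 25 and 30 deg C with 5 replicates).
#' @param flux Observed CH4 fluxes (mg C m-2 d-1).
#' @return A `response_fit` object with elements `model`, `a`, `b`, `se_a`,
#'   `se_b`, `r`, `p_value`, `n_points`.
#' @examples
#' fit_temperature_response(c(14, 20, 25, 30), exp(0.1 * c(14, 20, 25, 30)))
#' @export
fit_temperature_response <- function(temp_c, flux) {
  stopifnot(length(temp_c) == length(flux))
  if (length(unique(temp_c)) < 3) {
    stop("need at least 3 distinct temperatures", call. = FALSE)
  }
  pos <- flux > 0
  if (sum(pos) < 3) stop("need at least 3 positive fluxes", call. = FALSE)
  init <- lm(log(flux[pos]) ~ temp_c[pos])
  start <- list(a = exp(coef(init)[[1]]), b = coef(init)[[2]])
  dat <- data.frame(temp_c = temp_c, flux = flux)
  fit <- refine_nls(flux ~ a * exp(b * temp_c), dat, start)
  response_fit("exponential_temperature", fit, flux)
}

#' Fit the power-law salinity response of CH4 emission
#'
#' Fits flux = a * x^b on conductivity x by nonlinear least squares,
#' initialised from the log-log regression. Points with non-positive
#' conductivity are excluded with a warning (the power law is undefined at
#' 0); non-positive fluxes are excluded from the log-space initialisation
#' but kept in the nonlinear refinement.
#'
#' @param conductivity Conductivities (mS cm-1), > 0; at least 3 distinct.
#' @param flux Observed CH4 fluxes (mg C m-2 d-1).
#' @return A `response_fit` object; a declining response has `b < 0`.
#' @export
fit_salinity_response <- function(conductivity, flux) {
  stopifnot(length(conductivity) == length(flux))
  keep <- conductivity > 0
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " point(s) with conductivity <= 0",
      call. = FALSE
    )
    conductivity <- conductivity[keep]
    flux <- flux[keep]
  }
  if (length(unique(conductivity)) < 3) {
    stop("need at least 3 distinct conductivities", call. = FALSE)
  }
  pos <- flux > 0
  if (sum(pos) < 3) stop("need at least 3 positive fluxes", call. = FALSE)
  init <- lm(log(flux[pos]) ~ log(conductivity[pos]))
  start <- list(a = exp(coef(init)[[1]]), b = coef(init)[[2]])
  dat <- data.frame(x = conductivity, flux = flux)
  fit <- refine_nls(flux ~ a * x^b, dat, start)
  response_fit("power_salinity", fit, flux)
}

#' Predict flux from a fitted response curve
#'
#' @param fit A `response_fit` from [fit_temperature_response()] or
#'   [fit_salinity_response()].
#' @param x Temperatures (deg C) or conductivities (mS cm-1).
#' @return Predicted fluxes, same units as the fitted data.
#' @export
predict_response <- function(fit, x) {
  stopifnot(inherits(fit, "response_fit"))
  switch(fit$model,
    exponential_temperature = fit$a * exp(fit$b * x),
    power_salinity = fit$a * x^fit$b,
    stop("unknown response model: ", fit$model, call. = FALSE)
  )
}

#' @export
predict.response_fit <- function(object, newdata, ...) {
  predict_response(object, newdata)
}

#' Wald confidence interval for the response exponent
#'
#' Normal-approximation interval b +/- t(df) x se(b) from the nonlinear fit.
#'
#' @param fit A `response_fit`.
#' @param level Coverage level, default 0.95.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
response_ci_b <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "response_fit"))
  tq <- qt(1 - (1 - level) / 2, df = max(fit$df, 1))
  c(fit$b - tq * fit$se_b, fit$b + tq * fit$se_b)
}
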