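make_core <- function(ppm_start = 0, ppm_end = 500, sed = 7.5, water = 20,
                      dur = 2, temp = 20, len = 50, dia = 4) {
  data.frame(
    site_id = "s", date = as.Date("2016-06-15"), replicate = 1,
    tube_length_cm = len, tube_diameter_cm = dia,
    sediment_depth_cm = sed, water_depth_cm = water,
    duration_d = dur, ch4_ppm_start = ppm_start, ch4_ppm_end = ppm_end,
    temp_c = temp, conductivity_ms_cm = 30, pressure_atm = 1
  )
}

test_that("headspace volume is the cylinder above sediment and water", {
  expect_equal(headspace_volume(50, 4, 7.5, 20), pi * 4 * 22.5 / 1000)
  expect_equal(headspace_volume(50, 4, 7.5, 20), 0.2827, tolerance = 1e-3)
  expect_equal(headspace_volume(50, 4, 5, 25), 0.2513, tolerance = 1e-3)
  expect_error(headspace_volume(50, 4, 25, 25), "headspace")
})

test_that("ppm to carbon mass follows the ideal gas law", {
  expect_equal(ppm_to_mass_c(0, 0.28, 20), 0)
  # pure CH4 filling one molar volume at STP is one mole of carbon
  expect_equal(ppm_to_mass_c(1e6, 22.414, 0, 1), 12011, tolerance = 1e-4)
  expect_equal(ppm_to_mass_c(500, 0.2827, 20, 1), 0.0706, tolerance = 1e-3)
  expect_error(ppm_to_mass_c(500, 0, 20), "volume")
  expect_error(ppm_to_mass_c(500, 0.28, -300), "absolute zero")
})

test_that("core flux chains accumulation, geometry and duration", {
  expect_equal(core_flux(make_core(ppm_end = 0)), 0)
  # the worked 0.0706 mg C over 2 d across the 1.2566e-3 m2 cross-section
  expect_equal(core_flux(make_core()), 28.1, tolerance = 1e-3)
  expect_equal(
    core_flux(make_core(dur = 4)), core_flux(make_core(dur = 2)) / 2
  )
  expect_message(core_flux(make_core(ppm_start = 500, ppm_end = 0)), "uptake")
  expect_error(core_flux(make_core(sed = 30, water = 20)), "headspace")
})

test_that("core flux only depends on geometry through the headspace length", {
  # same headspace (22.5 cm) from different sediment/water splits
  a <- core_flux(make_core(sed = 7.5, water = 20))
  b <- core_flux(make_core(sed = 17.5, water = 10))
  expect_equal(a, b)
})

test_that("site flux aggregates replicate cores", {
  flux12 <- c(4, 6, 5, 3, 7, 4, 5, 6, 2, 8, 5, 5)
  # back out ppm deltas giving exactly these fluxes
  vol <- headspace_volume(50, 4, 7.5, 20)
  area <- pi * 0.02^2
  dppm <- vapply(flux12, function(f) {
    mol <- f * area * 2 / 1000 / 12.011
    mol * 0.0820574 * 293.15 / vol / 1e-6
  }, numeric(1))
  cores <- do.call(rbind, lapply(seq_along(dppm), function(i) {
    make_core(ppm_start = 10, ppm_end = 10 + dppm[i])
  }))
  cores$replicate <- seq_along(dppm)
  sf <- site_flux(cores)
  expect_equal(nrow(sf), 1)
  expect_equal(sf$value_mg_c_m2_d, mean(flux12), tolerance = 1e-9)
  expect_equal(sf$sd, sd(flux12), tolerance = 1e-9)
  expect_equal(sf$n, 12)
  expect_equal(sf$process, "CH4")
})

test_that("exponential temperature fit recovers noiseless parameters", {
  temps <- rep(c(14, 20, 25, 30), each = 3)
  flux <- 1 * exp(0.1 * temps)
  fit <- fit_temperature_response(temps, flux)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0.1, tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-6)

  # constant flux: no temperature dependence
  fit0 <- fit_temperature_response(c(14, 20, 25, 30), rep(5, 4))
  expect_equal(fit0$b, 0, tolerance = 1e-8)

  expect_error(fit_temperature_response(rep(20, 6), exp(rnorm(6))), "distinct")
})

test_that("power-law salinity fit recovers noiseless parameters", {
  x <- rep(c(6, 15, 30, 60), each = 3)
  flux <- 100 * x^-0.8
  fit <- fit_salinity_response(x, flux)
  expect_equal(fit$a, 100, tolerance = 1e-6)
  expect_equal(fit$b, -0.8, tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  fit0 <- fit_salinity_response(c(6, 15, 30, 60), rep(5, 4))
  expect_equal(fit0$b, 0, tolerance = 1e-8)

  expect_warning(
    fitz <- fit_salinity_response(c(0, 6, 15, 30, 60), c(9, 100 * c(6, 15, 30, 60)^-0.8)),
    "conductivity"
  )
  expect_equal(fitz$b, -0.8, tolerance = 1e-6)
})

test_that("predicted responses evaluate the fitted curve monotonically", {
  temps <- c(14, 20, 25, 30)
  fit <- fit_temperature_response(temps, exp(0.1 * temps))
  expect_equal(predict_response(fit, 0), fit$a, tolerance = 1e-6)
  expect_equal(predict_response(fit, 10), exp(1), tolerance = 1e-5)
  grid <- predict_response(fit, seq(5, 35, by = 5))
  expect_true(all(diff(grid) > 0))

  x <- c(6, 15, 30, 60)
  sfit <- fit_salinity_response(x, 100 * x^-0.8)
  expect_equal(predict_response(sfit, 1), sfit$a, tolerance = 1e-6)
  expect_true(all(diff(predict_response(sfit, c(2, 10, 50))) < 0))
})

test_that("fitted exponential response peaks in the warmest period", {
  arch <- site_archetype("freshwater")
  cfg <- generator_config(seed = 13)
  cp <- simulate_environment(arch, cfg)
  cores <- simulate_cores(arch, cp, cfg, manipulation = "temperature")
  fit <- fit_temperature_response(cores$temp_c, core_flux(cores))
  doy <- 1:365
  pred <- predict_response(fit, wetlandC:::seasonal_temp(doy))
  warmest <- doy[which.max(wetlandC:::seasonal_temp(doy))]
  expect_equal(doy[which.max(pred)], warmest)
  expect_gt(fit$b, 0)
})

test_that("b estimates are recovered with near-nominal interval coverage", {
  arch <- site_archetype("brackish")
  n_sim <- 100
  bt <- bs <- covered <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    cfg <- generator_config(seed = 20000 + i)
    cp <- simulate_environment(arch, cfg)
    ct <- simulate_cores(arch, cp, cfg, manipulation = "temperature")
    ft <- fit_temperature_response(ct$temp_c, core_flux(ct))
    bt[i] <- ft$b
    ci <- response_ci_b(ft, 0.95)
    covered[i] <- ci[1] <= arch$ch4_b_temp && arch$ch4_b_temp <= ci[2]
    cs <- simulate_cores(arch, cp, cfg, manipulation = "salinity")
    bs[i] <- fit_salinity_response(cs$conductivity_ms_cm, core_flux(cs))$b
  }
  expect_lt(abs(median(bt) - arch$ch4_b_temp) / arch$ch4_b_temp, 0.10)
  expect_lt(abs(median(bs) - arch$ch4_b_sal) / abs(arch$ch4_b_sal), 0.15)
  expect_true(all(bt > 0))
  expect_true(all(bs < 0))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.99)
})
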