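test_that("bottle rates are signed linear O2 changes per hour", {
  expect_equal(bottle_rate(8.0, 8.8, 4), 0.2)
  expect_equal(bottle_rate(8.0, 8.0, 2), 0)
  expect_equal(bottle_rate(8.0, 7.6, 4), -0.1)
  expect_error(bottle_rate(8, 8.8, 0), "duration")
  expect_error(bottle_rate(8, 8.8, -2), "duration")
  expect_error(bottle_rate(-1, 8, 2), "non-negative")
})

test_that("community rates combine light and dark replicates as GPP = NCP + R", {
  cr <- community_rates(light = rep(0.2, 4), dark = rep(-0.1, 4))
  expect_equal(cr$ncp, 0.2)
  expect_equal(cr$r, 0.1)
  expect_equal(cr$gpp, 0.3)

  # light = dark: no photosynthesis
  cr <- community_rates(light = rep(-0.1, 4), dark = rep(-0.1, 4))
  expect_equal(cr$ncp, -0.1)
  expect_equal(cr$r, 0.1)
  expect_equal(cr$gpp, 0)

  # unequal replicates, hand-summed means
  cr <- community_rates(
    light = c(0.25, 0.15, 0.30, 0.10),
    dark = c(-0.12, -0.08, -0.10, -0.10)
  )
  expect_equal(cr$ncp, 0.2)
  expect_equal(cr$r, 0.1)
  expect_equal(cr$gpp, 0.3)
  expect_equal(cr$ncp_sd, sd(c(0.25, 0.15, 0.30, 0.10)))

  expect_error(community_rates(numeric(0), -0.1), "replicate")
})

test_that("net O2 production in the dark clips R to zero with a warning", {
  expect_warning(
    cr <- community_rates(light = rep(0.2, 4), dark = rep(0.05, 4)),
    "dark"
  )
  expect_equal(cr$r, 0)
  expect_equal(cr$gpp, cr$ncp)
  expect_true(cr$dark_production)
})

test_that("O2 to carbon conversion is the 12/32 molar stoichiometry and linear", {
  expect_equal(o2_to_carbon(32), 12)
  expect_equal(o2_to_carbon(0), 0)
  expect_equal(o2_to_carbon(0.3), 0.1125)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(1, 0, 10)
    b <- rnorm(1, 0, 10)
    k <- rnorm(1, 0, 5)
    expect_equal(o2_to_carbon(a + b), o2_to_carbon(a) + o2_to_carbon(b))
    expect_equal(o2_to_carbon(k * a), k * o2_to_carbon(a))
  }
})

test_that("areal normalisation follows depth and jar geometry", {
  expect_equal(plankton_areal(0.3, 0.45), 135)
  expect_equal(plankton_areal(0.1, 0.20), 20)
  expect_error(plankton_areal(0.3, 0), "depth")

  expect_equal(benthic_areal(0.2, 2, 0.02), 20)
  expect_equal(benthic_areal(0, 2, 0.02), 0)
  expect_equal(benthic_areal(0.15, 1.5, 0.0125), 18)
  expect_error(benthic_areal(0.2, 2, 0), "basal_area")
})

test_that("diel scaling runs GPP over daylight and R over 24 h", {
  d <- diel_scale(10, 5, 12)
  expect_equal(d$gpp, 120)
  expect_equal(d$r, 120)
  expect_equal(d$ncp, 0)
  expect_equal(diel_scale(10, 0, 0)$gpp, 0)
  d <- diel_scale(8.333, 2.5, 14.4)
  expect_equal(d$gpp, 119.9952)
  expect_equal(d$r, 60)
  expect_equal(d$ncp, d$gpp - d$r)
  expect_error(diel_scale(10, 5, 25), "daylight")
  expect_error(diel_scale(10, 5, -1), "daylight")
})

test_that("solar day length matches equinox, equator and winter references", {
  expect_equal(daylight_hours(as.Date("2016-03-21"), 40.65), 12, tolerance = 0.02)
  expect_equal(daylight_hours(as.Date("2016-06-21"), 0), 12, tolerance = 0.02)
  dec <- daylight_hours(as.Date("2016-12-21"), 40.65)
  expect_lt(dec, 10) # published day length near 40 N is ~9.2-9.4 h
  expect_gt(dec, 8.8)
  jun <- daylight_hours(as.Date("2016-06-21"), 40.65)
  expect_equal(dec + jun, 24, tolerance = 0.3) # solstice symmetry
  expect_error(daylight_hours(as.Date("2016-06-21"), 70), "polar")
})

test_that("unit scaling commutes with the carbon conversion", {
  set.seed(21)
  for (i in 1:10) {
    vol <- rnorm(1, 0.3, 0.2)
    depth <- runif(1, 0.1, 0.6)
    daylight <- runif(1, 8, 16)
    a <- diel_scale(
      o2_to_carbon(plankton_areal(vol, depth)),
      o2_to_carbon(plankton_areal(vol / 2, depth)), daylight
    )
    b <- diel_scale(
      plankton_areal(o2_to_carbon(vol), depth),
      plankton_areal(o2_to_carbon(vol / 2), depth), daylight
    )
    expect_equal(a$gpp, b$gpp, tolerance = 1e-12)
    expect_equal(a$ncp, b$ncp, tolerance = 1e-12)
  }
})

test_that("oxygen pipeline recovers known rates exactly at zero noise", {
  cfg <- generator_config(seed = 5, cv = 0)
  for (name in c("salt_marsh", "freshwater")) {
    arch <- site_archetype(name)
    cp <- simulate_environment(arch, cfg)
    inc <- simulate_oxygen_incubations(arch, cp, cfg)
    rates <- oxygen_rates(inc, cp)
    truth <- wetlandC:::true_oxygen_rates(arch, cp)
    for (comp in c("plankton", "benthos")) {
      tr_gpp <- if (comp == "plankton") truth$gpp_plankton else truth$gpp_benthos
      tr_r <- if (comp == "plankton") truth$r_plankton else truth$r_benthos
      got <- rates[rates$compartment == comp, ]
      expect_equal(
        got$value_mg_c_m2_d[got$process == "GPP"], tr_gpp,
        tolerance = 1e-9
      )
      expect_equal(
        got$value_mg_c_m2_d[got$process == "R"], tr_r,
        tolerance = 1e-9
      )
    }
  }
})

test_that("every site/date/compartment triple satisfies GPP = NCP + R", {
  cfg <- generator_config(seed = 3, cv = 0.2)
  arch <- site_archetype("brackish")
  cp <- simulate_environment(arch, cfg)
  rates <- oxygen_rates(simulate_oxygen_incubations(arch, cp, cfg), cp)
  wide <- tidyr::pivot_wider(
    rates[, c("site_id", "date", "compartment", "process", "value_mg_c_m2_d")],
    names_from = "process", values_from = "value_mg_c_m2_d"
  )
  expect_equal(wide$GPP, wide$NCP + wide$R, tolerance = 1e-9)
  expect_true(all(wide$R >= 0))
})

test_that("photosynthetic and respiratory quotients rescale the rates", {
  cfg <- generator_config(seed = 9, cv = 0)
  arch <- site_archetype("freshwater")
  cp <- simulate_environment(arch, cfg)
  inc <- simulate_oxygen_incubations(arch, cp, cfg)
  base <- oxygen_rates(inc, cp)
  adj <- oxygen_rates(inc, cp, pq = 1.25, rq = 0.8)
  expect_equal(
    adj$value_mg_c_m2_d[adj$process == "GPP"],
    base$value_mg_c_m2_d[base$process == "GPP"] / 1.25
  )
  expect_equal(
    adj$value_mg_c_m2_d[adj$process == "R"],
    base$value_mg_c_m2_d[base$process == "R"] * 0.8
  )
})
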