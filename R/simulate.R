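# Seeded synthetic-data generator. Emulates the field design: three site
# archetypes along a salinity gradient, bi-monthly campaigns over two
# hydrological cycles, replicated light/dark bottles and jars, quadrat
# harvests, sediment-core CH4 incubations and the temperature/salinity
# manipulation experiments.
#
# The generator INVERTS the measurement equations (true rate -> raw sensor
# readings) with its own inline arithmetic; the pipeline computes forward.
# With replicate noise CV = 0 every stage recovers the generator's truth to
# numerical precision.

#' Site archetypes along the salinity gradient
#'
#' Defaults encode the three deltaic wetland types: a *Salicornia* salt
#' marsh (mean conductivity 56.6 mS cm-1), a brackish coastal lagoon
#' (31.3 mS cm-1) and a restored freshwater wetland (2.0 mS cm-1), with
#' their water depths, vegetated coverages (0.37 halophyte / 0.50
#' helophyte), wetland-type surfaces, baseline metabolic rates at the 18 C
#' reference temperature, and the exponential temperature (b_T > 0) and
#' power-law salinity (b_S < 0) responses of CH4 emission.
#'
#' @param name One of `"salt_marsh"`, `"brackish"`, `"freshwater"`.
#' @return A list of archetype parameters (see Details in the vignette).
#' @export
site_archetype <- function(name = c("salt_marsh", "brackish", "freshwater")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    temp_b = 0.10, # 1/degC, exponential scaling of GPP and R
    resp_sal_exp = -0.15, # salinity damping exponent on respiration
    ch4_a = 5, # mg C m-2 d-1 scale of the CH4 response
    ch4_b_temp = 0.12, # 1/degC
    ch4_b_sal = -0.8 # dimensionless, on conductivity
  )
  spec <- switch(name,
    salt_marsh = list(
      conductivity_ms_cm = 56.6, depth_m = 0.45,
      vegetated_fraction = 0.37, plant_type = "halophyte",
      surface_ha = 1292.43,
      gpp_plankton_0 = 250, r_plankton_0 = 350,
      gpp_benthos_0 = 200, r_benthos_0 = 280,
      biomass_max_g_dw_m2 = 600, biomass_min_g_dw_m2 = 50
    ),
    brackish = list(
      conductivity_ms_cm = 31.3, depth_m = 0.20,
      vegetated_fraction = 0.37, plant_type = "halophyte",
      surface_ha = 1797.40,
      gpp_plankton_0 = 1200, r_plankton_0 = 900,
      gpp_benthos_0 = 200, r_benthos_0 = 350,
      biomass_max_g_dw_m2 = 600, biomass_min_g_dw_m2 = 50
    ),
    freshwater = list(
      conductivity_ms_cm = 2.0, depth_m = 0.50,
      vegetated_fraction = 0.50, plant_type = "helophyte",
      surface_ha = 563.06,
      gpp_plankton_0 = 600, r_plankton_0 = 650,
      gpp_benthos_0 = 120, r_benthos_0 = 180,
      biomass_max_g_dw_m2 = 1400, biomass_min_g_dw_m2 = 100
    )
  )
  c(base, spec)
}

#' Generator configuration
#'
#' @param seed Integer seed; fixes every emitted record.
#' @param dates Campaign dates; default 10 roughly bi-monthly dates over the
#'   2015/2016 and 2016/2017 hydrological cycles.
#' @param n_bottles Light and dark bottles/jars per treatment (4).
#' @param n_cores Replicate sediment cores per campaign (12).
#' @param n_quadrats Harvest quadrats per campaign (15).
#' @param cv Lognormal replicate noise coefficient of variation, in
#'   \[0, 1\]; default 0.2. `cv = 0` makes the generator exactly invertible.
#' @param latitude_deg Latitude for the day-length formula (40.65 N).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             dates = as.Date(c(
                               "2015-07-15", "2015-10-15", "2016-01-15",
                               "2016-04-15", "2016-06-15", "2016-08-15",
                               "2016-10-15", "2017-01-15", "2017-04-15",
                               "2017-07-15"
                             )),
                             n_bottles = 4, n_cores = 12, n_quadrats = 15,
                             cv = 0.2, latitude_deg = 40.65) {
  dates <- as.Date(dates)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_bottles >= 1, n_cores >= 1, n_quadrats >= 1,
    cv >= 0, cv <= 1,
    !is.unsorted(dates, strictly = TRUE)
  )
  structure(
    list(
      seed = as.integer(seed), dates = dates,
      n_bottles = n_bottles, n_cores = n_cores, n_quadrats = n_quadrats,
      cv = cv, latitude_deg = latitude_deg
    ),
    class = "generator_config"
  )
}

# Deterministic per-stage, per-site seed below 2^31.
sim_seed <- function(config, offset, site = "") {
  site_code <- if (nzchar(site)) sum(utf8ToInt(site)) %% 997 else 0
  (abs(config$seed) * 100003 + offset * 1000 + site_code) %% 2147483647
}

# Mean-one multiplicative lognormal noise at a given CV.
ln_noise <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Seasonal water temperature: annual sinusoid, mean 18 C, amplitude 10 C,
# peak in early August (day 215).
seasonal_temp <- function(doy) {
  18 + 10 * cos(2 * pi * (doy - 215) / 365)
}

# Seasonal standing-biomass index in [0, 1]: logistic growth through the
# vegetative period (centred mid-summer), exponential dieback after
# late September.
season_index <- function(doy) {
  grow <- plogis((pmin(doy, 270) - 185) / 20)
  decay <- plogis((270 - 185) / 20) * exp(-(doy - 270) / 45)
  ifelse(doy <= 270, grow, decay)
}

#' Simulate the campaign environment of one site
#'
#' Sinusoidal annual water temperature (mean 18 C, amplitude 10 C, peak
#' early August) with small observational jitter, site conductivity with
#' modest lognormal jitter around the archetype mean, constant depth, and
#' day length from the solar formula.
#'
#' @param archetype A [site_archetype()].
#' @param config A [generator_config()].
#' @return Tibble of campaigns: `site_id`, `date`, `daylight_h`,
#'   `water_temp_c`, `conductivity_ms_cm`, `depth_m`.
#' @export
simulate_environment <- function(archetype, config = generator_config()) {
  set.seed(sim_seed(config, 1, archetype$name))
  doy <- as.integer(format(config$dates, "%j"))
  n <- length(doy)
  cond_sd <- 0.08
  tibble::tibble(
    site_id = archetype$name,
    date = config$dates,
    daylight_h = round(daylight_hours(config$dates, config$latitude_deg), 2),
    water_temp_c = round(seasonal_temp(doy) + rnorm(n, 0, 0.8), 2),
    conductivity_ms_cm = round(
      archetype$conductivity_ms_cm *
        exp(rnorm(n, 0, cond_sd) - cond_sd^2 / 2), 2
    ),
    depth_m = archetype$depth_m
  )
}

# True campaign-level daily rates (mg C m-2 d-1) implied by the archetype
# and the realised environment.
true_oxygen_rates <- function(archetype, campaigns) {
  tscale <- exp(archetype$temp_b * (campaigns$water_temp_c - 18))
  damp <- (campaigns$conductivity_ms_cm / 2)^archetype$resp_sal_exp
  tibble::tibble(
    site_id = campaigns$site_id,
    date = campaigns$date,
    gpp_plankton = archetype$gpp_plankton_0 * tscale,
    r_plankton = archetype$r_plankton_0 * tscale * damp,
    gpp_benthos = archetype$gpp_benthos_0 * tscale,
    r_benthos = archetype$r_benthos_0 * tscale * damp
  )
}

true_ch4_flux <- function(archetype, temp_c, conductivity) {
  archetype$ch4_a * exp(archetype$ch4_b_temp * temp_c) *
    conductivity^archetype$ch4_b_sal
}

#' Simulate light/dark oxygen incubations
#'
#' Draws per-bottle true rates (lognormal multiplicative noise around the
#' temperature-driven campaign means, with salinity damping of respiration)
#' and inverts them through the measurement chain - diel scaling, depth or
#' jar-geometry normalisation, O2:C stoichiometry - into bottle O2 start/end
#' concentrations. Bottles incubate 3 h; benthic jars enclose 2 L over a
#' 0.02 m2 footprint.
#'
#' @inheritParams simulate_environment
#' @param campaigns Campaign tibble from [simulate_environment()].
#' @return Tibble matching the `oxygen_incubations.csv` schema.
#' @export
simulate_oxygen_incubations <- function(archetype, campaigns,
                                        config = generator_config()) {
  set.seed(sim_seed(config, 2, archetype$name))
  truth <- true_oxygen_rates(archetype, campaigns)
  dur <- 3
  jar_vol <- 2
  jar_area <- 0.02
  nb <- config$n_bottles
  o2_per_c <- 32 / 12

  rows <- lapply(seq_len(nrow(campaigns)), function(i) {
    cp <- campaigns[i, ]
    tr <- truth[i, ]
    per_comp <- lapply(c("plankton", "benthos"), function(comp) {
      gpp_true <- if (comp == "plankton") tr$gpp_plankton else tr$gpp_benthos
      r_true <- if (comp == "plankton") tr$r_plankton else tr$r_benthos
      # mg C m-2 h-1 -> mg O2 L-1 h-1 for this compartment's enclosure
      to_vol <- function(areal_c_h) {
        areal_o2 <- areal_c_h * o2_per_c
        if (comp == "plankton") {
          areal_o2 / (1000 * cp$depth_m)
        } else {
          areal_o2 * jar_area / jar_vol
        }
      }
      gpp_i <- gpp_true * ln_noise(nb, config$cv)
      r_light_i <- r_true * ln_noise(nb, config$cv)
      r_dark_i <- r_true * ln_noise(nb, config$cv)
      ncp_vol <- to_vol(gpp_i / cp$daylight_h - r_light_i / 24)
      r_vol <- to_vol(r_dark_i / 24)
      light_start <- ifelse(ncp_vol >= 0, 8, pmax(8, -ncp_vol * dur + 1))
      dark_start <- pmax(8, r_vol * dur + 0.5)
      tibble::tibble(
        site_id = cp$site_id,
        date = cp$date,
        compartment = comp,
        treatment = rep(c("light", "dark"), each = nb),
        replicate = rep(seq_len(nb), 2),
        o2_start_mg_l = c(light_start, dark_start),
        o2_end_mg_l = c(light_start + ncp_vol * dur, dark_start - r_vol * dur),
        duration_h = dur,
        enclosed_volume_l = if (comp == "benthos") jar_vol else NA_real_,
        basal_area_m2 = if (comp == "benthos") jar_area else NA_real_
      )
    })
    dplyr::bind_rows(per_comp)
  })
  dplyr::bind_rows(rows)
}

#' Simulate vegetation quadrat harvests
#'
#' Standing above-ground biomass follows a seasonal trajectory (logistic
#' growth through the vegetative period, dieback after late September)
#' between the archetype's minimum and maximum; each quadrat samples the
#' trajectory with lognormal noise over a 0.25 m2 frame.
#'
#' @inheritParams simulate_oxygen_incubations
#' @return Tibble matching the `quadrats.csv` schema.
#' @export
simulate_quadrats <- function(archetype, campaigns,
                              config = generator_config()) {
  set.seed(sim_seed(config, 3, archetype$name))
  quadrat_area <- 0.25
  doy <- as.integer(format(campaigns$date, "%j"))
  biomass <- archetype$biomass_min_g_dw_m2 +
    (archetype$biomass_max_g_dw_m2 - archetype$biomass_min_g_dw_m2) *
      season_index(doy)
  rows <- lapply(seq_len(nrow(campaigns)), function(i) {
    tibble::tibble(
      site_id = campaigns$site_id[i],
      date = campaigns$date[i],
      plant_type = archetype$plant_type,
      replicate = seq_len(config$n_quadrats),
      dry_weight_g = biomass[i] * quadrat_area *
        ln_noise(config$n_quadrats, config$cv),
      quadrat_area_m2 = quadrat_area
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate sediment-core CH4 incubations
#'
#' True flux follows a x exp(b_T T) x conductivity^b_S; per-core noisy
#' fluxes are converted to headspace ppm accumulation through the exact
#' inverse of the ideal-gas flux computation (tube 50 x 4 cm, 7.5 cm
#' sediment, 20 cm water, 3 d, ambient 1.9 ppm start).
#'
#' With `manipulation = "temperature"` the factorial lab design is emitted
#' instead: 5 replicate cores at 14, 20, 25 and 30 C at the site's mean
#' conductivity. With `manipulation = "salinity"`, 5 replicates at 20 C
#' across the site's salinity-factor series (1/5x, 1/2x, 1x, 2x for the
#' salt marsh and brackish archetypes; 1/2x, 1x, 2x, 5x for freshwater).
#'
#' @inheritParams simulate_oxygen_incubations
#' @param manipulation `NULL` (field campaigns), `"temperature"` or
#'   `"salinity"`.
#' @return Tibble matching the `cores.csv` schema.
#' @export
simulate_cores <- function(archetype, campaigns, config = generator_config(),
                           manipulation = NULL) {
  sed <- 7.5
  water <- 20
  tube_l <- 50
  tube_d <- 4
  dur <- 3
  n_rep_lab <- 5
  vol_l <- pi * (tube_d / 2)^2 * (tube_l - sed - water) / 1000
  area_m2 <- pi * (tube_d / 2 / 100)^2

  if (is.null(manipulation)) {
    set.seed(sim_seed(config, 4, archetype$name))
    design <- tibble::tibble(
      date = rep(campaigns$date, each = config$n_cores),
      replicate = rep(seq_len(config$n_cores), nrow(campaigns)),
      temp_c = rep(campaigns$water_temp_c, each = config$n_cores),
      conductivity_ms_cm = rep(campaigns$conductivity_ms_cm, each = config$n_cores)
    )
  } else {
    manipulation <- match.arg(manipulation, c("temperature", "salinity"))
    set.seed(sim_seed(config, if (manipulation == "temperature") 5 else 6,
      archetype$name
    ))
    if (manipulation == "temperature") {
      levels_t <- c(14, 20, 25, 30)
      design <- tibble::tibble(
        date = config$dates[1],
        replicate = seq_len(n_rep_lab * length(levels_t)),
        temp_c = rep(levels_t, each = n_rep_lab),
        conductivity_ms_cm = archetype$conductivity_ms_cm
      )
    } else {
      factors <- if (archetype$name == "freshwater") {
        c(0.5, 1, 2, 5)
      } else {
        c(0.2, 0.5, 1, 2)
      }
      design <- tibble::tibble(
        date = config$dates[1],
        replicate = seq_len(n_rep_lab * length(factors)),
        temp_c = 20,
        conductivity_ms_cm = archetype$conductivity_ms_cm * rep(factors, each = n_rep_lab)
      )
    }
  }

  flux_true <- true_ch4_flux(archetype, design$temp_c, design$conductivity_ms_cm)
  flux_i <- flux_true * ln_noise(nrow(design), config$cv)
  # invert: mg C m-2 d-1 -> accumulated mol -> headspace ppm change
  mass_mg <- flux_i * area_m2 * dur
  mol <- mass_mg / 1000 / 12.011
  dppm <- mol * 0.0820574 * (design$temp_c + 273.15) / (1 * vol_l) / 1e-6
  tibble::tibble(
    site_id = archetype$name,
    date = design$date,
    replicate = design$replicate,
    tube_length_cm = tube_l,
    tube_diameter_cm = tube_d,
    sediment_depth_cm = sed,
    water_depth_cm = water,
    duration_d = dur,
    ch4_ppm_start = 1.9,
    ch4_ppm_end = 1.9 + dppm,
    temp_c = design$temp_c,
    conductivity_ms_cm = design$conductivity_ms_cm,
    pressure_atm = 1
  )
}

#' Write a complete synthetic fixture set
#'
#' Generates all three archetypes (or a subset) under one seed and writes
#' `campaigns.csv`, `oxygen_incubations.csv`, `quadrats.csv`, `cores.csv`,
#' `sites.yaml` and `truth.csv` (the generator's campaign-level true rates,
#' for recovery tests) to `outdir`. Reruns with the same config are
#' byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [generator_config()].
#' @param archetypes Archetype names to include.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_set <- function(outdir, config = generator_config(),
                              archetypes = c(
                                "salt_marsh", "brackish", "freshwater"
                              )) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  camp <- list()
  oxy <- list()
  quad <- list()
  cores <- list()
  truth <- list()
  site_cfg <- list()
  for (name in archetypes) {
    arch <- site_archetype(name)
    cp <- simulate_environment(arch, config)
    camp[[name]] <- cp
    oxy[[name]] <- simulate_oxygen_incubations(arch, cp, config)
    quad[[name]] <- simulate_quadrats(arch, cp, config)
    cores[[name]] <- simulate_cores(arch, cp, config)
    tr <- true_oxygen_rates(arch, cp)
    tr$ch4 <- true_ch4_flux(arch, cp$water_temp_c, cp$conductivity_ms_cm)
    doy <- as.integer(format(cp$date, "%j"))
    coefs <- carbon_coefficients()
    tr$veg_stock_g_c_m2 <- (archetype_biomass(arch, doy)) *
      coefs[[arch$plant_type]]
    truth[[name]] <- tr
    site_cfg[[name]] <- list(
      wetland_type = name,
      vegetated_fraction = arch$vegetated_fraction,
      plant_type = arch$plant_type,
      surface_ha = arch$surface_ha,
      depth_m = arch$depth_m
    )
  }
  paths <- c(
    campaigns = file.path(outdir, "campaigns.csv"),
    oxygen_incubations = file.path(outdir, "oxygen_incubations.csv"),
    quadrats = file.path(outdir, "quadrats.csv"),
    cores = file.path(outdir, "cores.csv"),
    sites = file.path(outdir, "sites.yaml"),
    truth = file.path(outdir, "truth.csv")
  )
  readr::write_csv(dplyr::bind_rows(camp), paths[["campaigns"]])
  readr::write_csv(dplyr::bind_rows(oxy), paths[["oxygen_incubations"]])
  readr::write_csv(dplyr::bind_rows(quad), paths[["quadrats"]])
  readr::write_csv(dplyr::bind_rows(cores), paths[["cores"]])
  readr::write_csv(dplyr::bind_rows(truth), paths[["truth"]])
  yaml::write_yaml(
    list(
      sites = site_cfg,
      constants = list(
        ch4_co2_factor = 28, ch4_coverage = "open", pq = 1, rq = 1
      )
    ),
    paths[["sites"]]
  )
  invisible(paths)
}

archetype_biomass <- function(archetype, doy) {
  archetype$biomass_min_g_dw_m2 +
    (archetype$biomass_max_g_dw_m2 - archetype$biomass_min_g_dw_m2) *
      season_index(doy)
}
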