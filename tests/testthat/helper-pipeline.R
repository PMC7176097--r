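# Runs the full synthetic pipeline (generator -> rates -> budget ->
# landscape) in a temp directory; used by the integration and budget tests.
run_synthetic_pipeline <- function(seed = 1, cv = 0.2,
                                   dir = tempfile("fixtures")) {
  cfg <- generator_config(seed = seed, cv = cv)
  paths <- write_fixture_set(dir, cfg)
  camp <- read_campaigns(paths[["campaigns"]])
  rates <- dplyr::bind_rows(
    oxygen_rates(read_incubations(paths[["oxygen_incubations"]]), camp),
    vegetation_rates(read_quadrats(paths[["quadrats"]])),
    site_flux(read_cores(paths[["cores"]]))
  )
  sites <- read_sites(paths[["sites"]])
  budgets <- site_budgets(rates, sites)
  list(
    config = cfg, paths = paths, campaigns = camp, rates = rates,
    sites = sites, budgets = budgets,
    landscape = landscape_extrapolation(budgets, sites)
  )
}
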