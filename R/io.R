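# CSV and YAML interfaces. Column schemas follow the fixture files emitted
# by write_fixture_set(); all readers return tibbles with dates parsed.

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop("`", what, "` must be a data frame", call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(
      "`", what, "` is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(df)
}

read_wetland_csv <- function(path, required, what) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, what)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' Read pipeline input tables
#'
#' Thin CSV readers with schema validation for the tables the pipeline
#' consumes: sampling campaigns, oxygen incubations, vegetation quadrats and
#' sediment cores.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the validated columns, `date` parsed as `Date`.
#' @name readers
NULL

#' @rdname readers
#' @export
read_campaigns <- function(path) {
  read_wetland_csv(path, c(
    "site_id", "date", "daylight_h", "water_temp_c",
    "conductivity_ms_cm", "depth_m"
  ), "campaigns")
}

#' @rdname readers
#' @export
read_incubations <- function(path) {
  read_wetland_csv(path, c(
    "site_id", "date", "compartment", "treatment", "replicate",
    "o2_start_mg_l", "o2_end_mg_l", "duration_h"
  ), "incubations")
}

#' @rdname readers
#' @export
read_quadrats <- function(path) {
  read_wetland_csv(path, c(
    "site_id", "date", "plant_type", "replicate",
    "dry_weight_g", "quadrat_area_m2"
  ), "quadrats")
}

#' @rdname readers
#' @export
read_cores <- function(path) {
  read_wetland_csv(path, c(
    "site_id", "date", "replicate", "tube_length_cm", "tube_diameter_cm",
    "sediment_depth_cm", "water_depth_cm", "duration_d",
    "ch4_ppm_start", "ch4_ppm_end", "temp_c", "conductivity_ms_cm"
  ), "cores")
}

#' @rdname readers
#' @export
read_rates <- function(path) {
  read_wetland_csv(path, c(
    "site_id", "date", "compartment", "process", "value_mg_c_m2_d"
  ), "rates")
}

#' Read a site-configuration YAML file
#'
#' The YAML holds one `sites` mapping (per site: `wetland_type`,
#' `vegetated_fraction`, `plant_type`, `surface_ha`, optionally
#' `open_water_fraction`, `depth_m`) and an optional `constants` mapping
#' (`ch4_co2_factor`, `ch4_coverage`, `pq`, `rq`).
#'
#' @param path Path to the YAML file.
#' @return List with `sites` (a tibble, one row per site) and `constants`.
#' @export
read_sites <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sites)) stop("`sites` mapping missing in ", path, call. = FALSE)
  sites <- dplyr::bind_rows(lapply(names(raw$sites), function(id) {
    s <- raw$sites[[id]]
    tibble::tibble(
      site_id = id,
      wetland_type = s$wetland_type,
      vegetated_fraction = s$vegetated_fraction,
      open_water_fraction = s$open_water_fraction %||%
        (1 - s$vegetated_fraction),
      plant_type = s$plant_type,
      surface_ha = s$surface_ha,
      depth_m = s$depth_m %||% NA_real_
    )
  }))
  constants <- raw$constants %||% list()
  constants$ch4_co2_factor <- constants$ch4_co2_factor %||% 28
  constants$ch4_coverage <- constants$ch4_coverage %||% "open"
  constants$pq <- constants$pq %||% 1
  constants$rq <- constants$rq %||% 1
  list(sites = sites, constants = constants)
}

#' Write a metabolic-rates table
#'
#' @param rates Tibble of rates (`site_id`, `date`, `compartment`,
#'   `process`, `value_mg_c_m2_d`, `sd`, `n`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  keep <- intersect(
    c("site_id", "date", "compartment", "process", "value_mg_c_m2_d", "sd", "n"),
    names(rates)
  )
  readr::write_csv(rates[, keep], path)
  invisible(path)
}
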