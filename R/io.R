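#' Read a shell-production series from CSV
#'
#' Expects a two-column numeric CSV with a header row: year marks in the
#' first column, production rates (kg/m^2/yr) in the second. Years must be
#' strictly increasing and production non-negative; violations are reported
#' with the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A [production_series()].
#' @export
load_production_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) {
    stop("production CSV needs two columns: year, production", call. = FALSE)
  }
  yr <- suppressWarnings(as.numeric(df[[1L]]))
  pr <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(yr) || anyNA(pr)) {
    bad <- which(is.na(yr) | is.na(pr))[1L]
    stop(sprintf("non-numeric or missing value at data row %d of %s", bad, path),
         call. = FALSE)
  }
  if (any(diff(yr) <= 0)) {
    bad <- which(diff(yr) <= 0)[1L] + 1L
    stop(sprintf("years must be strictly increasing: violation at data row %d of %s",
                 bad, path), call. = FALSE)
  }
  if (any(pr < 0)) {
    bad <- which(pr < 0)[1L]
    stop(sprintf("negative production at data row %d of %s", bad, path),
         call. = FALSE)
  }
  production_series(yr, pr)
}

#' Write a production series to CSV
#'
#' Writes the two-column format read back by [load_production_csv()];
#' the write/read round trip is the identity on values.
#'
#' @param series [production_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_production_csv <- function(series, path) {
  stopifnot(inherits(series, "production_series"))
  utils::write.csv(
    data.frame(year = series$time, production_kg_m2_yr = series$production),
    path, row.names = FALSE)
  invisible(path)
}

#' Landscape presets for the sampling-design study
#'
#' Three canonical landscapes of 30 lakes holding high- (slope 3),
#' moderate- (slope 1) and low-slope (slope 0.2) ecosystem types:
#' \describe{
#'   \item{equal-even}{equal numbers of each type, invader densities laid
#'     out on an even grid (1-10) within each type;}
#'   \item{equal-uneven}{equal numbers of each type, densities drawn from
#'     each lake's lognormal trajectory (uneven spacing);}
#'   \item{unequal-even}{types in proportions 0.6/0.3/0.1, densities on the
#'     even grid.}
#' }
#'
#' @return Named list; each element has `landscape` ([landscape()]) and
#'   `abundances` (fixed per-lake densities, or `NULL` for trajectory
#'   draws), ready for [snapshot_sample()] / [compare_designs()].
#' @export
design_presets <- function() {
  types <- list(ecosystem_type(3, "high-slope"),
                ecosystem_type(1, "moderate-slope"),
                ecosystem_type(0.2, "low-slope"))
  traj <- trajectory_params(n_years = 25, mean_level = 4)
  even_grid <- function(props, n_lakes) {
    counts <- largest_remainder(n_lakes, props)
    unlist(lapply(counts, function(ct) seq(1, 10, length.out = ct)))
  }
  list(
    `equal-even` = list(
      landscape = landscape(types, rep(1 / 3, 3), n_lakes = 30, trajectory = traj),
      abundances = even_grid(rep(1 / 3, 3), 30)),
    `equal-uneven` = list(
      landscape = landscape(types, rep(1 / 3, 3), n_lakes = 30, trajectory = traj),
      abundances = NULL),
    `unequal-even` = list(
      landscape = landscape(types, c(0.6, 0.3, 0.1), n_lakes = 30, trajectory = traj),
      abundances = even_grid(c(0.6, 0.3, 0.1), 30))
  )
}

config_error <- function(key, msg) {
  stop(sprintf("configuration error in `%s`: %s", key, msg), call. = FALSE)
}

get_key <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) config_error(key, "required key is missing")
  default
}

#' Run a named analysis stage from a configuration
#'
#' Executes one of the three stages — `shell` (shell-hash accumulation),
#' `macrophyte` (habitat-gain curve) or `designs` (sampling-design
#' comparison) — from a configuration list or YAML file, writes its output
#' tables as CSV into `out_dir`, and writes a `manifest.json` recording the
#' stage, full parameter set, seed and package version, so every output
#' directory can be re-run exactly. Identical configuration and seed give
#' byte-identical outputs.
#'
#' Configuration keys (stage-specific keys may come from a `preset`):
#' \describe{
#'   \item{shell}{`preset` (one of [shell_presets()] names) or
#'     `k_per_year`; `s0` (default 0); either `production` (a constant
#'     rate) with `years`, or `production = "hudson"` with `years`;
#'     optionally `production_csv` (path).}
#'   \item{macrophyte}{`preset` (one of [lake_presets()] names) or
#'     `bathymetry` (list: `kind` = conical/shelf plus its parameters) with
#'     `chl_pre`; optional `dfr_max` (default 100) and `dfr_step` (1).}
#'   \item{designs}{`preset` (one of [design_presets()] names) or `slopes`,
#'     `proportions`, `n_lakes`, optional trajectory keys `n_years`,
#'     `mean_level`, `log_sd`, `autocorr`.}
#' }
#'
#' @param config A named list, or path to a YAML file of one. Must contain
#'   `stage`; `seed` defaults to 1.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out`.
#' @return Invisibly, a named list of the output tables (and the manifest).
#' @export
run_stage <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config", "must be a list or a YAML path")
  stage <- get_key(config, "stage", required = TRUE)
  if (!stage %in% c("shell", "macrophyte", "designs")) {
    config_error("stage", sprintf(
      "unknown stage '%s' (expected shell, macrophyte or designs)", stage))
  }
  seed <- get_key(config, "seed", default = 1L)
  if (is.null(out_dir)) out_dir <- get_key(config, "out", required = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- switch(stage,
    shell = run_shell_stage(config, seed),
    macrophyte = run_macrophyte_stage(config),
    designs = run_designs_stage(config, seed)
  )
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(stage = stage, seed = seed,
                   parameters = config[setdiff(names(config), c("out"))],
                   package = "impactcurves",
                   version = as.character(utils::packageVersion("impactcurves")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tables, list(manifest = manifest)))
}

run_shell_stage <- function(config, seed) {
  preset <- get_key(config, "preset")
  params <- if (!is.null(preset)) {
    ps <- shell_presets()
    if (!preset %in% names(ps)) {
      config_error("preset", sprintf("unknown shell preset '%s'", preset))
    }
    ps[[preset]]
  } else {
    shell_params(get_key(config, "k_per_year", required = TRUE))
  }
  s0 <- get_key(config, "s0", default = 0)
  series <- if (!is.null(config$production_csv)) {
    load_production_csv(config$production_csv)
  } else {
    years <- get_key(config, "years", default = 25)
    prod <- get_key(config, "production", default = 1)
    if (identical(prod, "hudson")) {
      generate_trajectory(hudson_trajectory(n_years = years), seed = seed)
    } else {
      if (!is.numeric(prod)) config_error("production", "must be numeric or 'hudson'")
      production_series(seq_len(years), rep(prod, years))
    }
  }
  traj <- simulate_stock(series, params, S0 = s0)
  tables <- list(trajectory = data.frame(year = traj$time,
                                         production = traj$production,
                                         stock = traj$stock))
  variable <- stats::sd(series$production) > 0
  if (variable && nrow(series) >= max(5 / params$k, 10) + 5) {
    cp <- production_stock_coupling(series, params, S0 = s0)
    tables$coupling <- data.frame(year = cp$points$time,
                                  production = cp$points$production,
                                  stock = cp$points$stock)
    tables$coupling_summary <- data.frame(
      k_per_year = params$k, burn_in_years = cp$burn_in,
      n_years = nrow(cp$points), pearson_r = cp$r,
      undefined = cp$undefined)
  }
  tables
}

run_macrophyte_stage <- function(config) {
  preset <- get_key(config, "preset")
  lake <- if (!is.null(preset)) {
    ps <- lake_presets()
    if (!preset %in% names(ps)) {
      config_error("preset", sprintf("unknown lake preset '%s'", preset))
    }
    ps[[preset]]
  } else {
    b <- get_key(config, "bathymetry", required = TRUE)
    bath <- switch(get_key(b, "kind", required = TRUE),
      conical = conical_bathymetry(get_key(b, "max_depth", required = TRUE)),
      shelf = shelf_bathymetry(
        max_depth = get_key(b, "max_depth", default = 15),
        shelf_top = get_key(b, "shelf_top", default = 2.5),
        shelf_bottom = get_key(b, "shelf_bottom", default = 3),
        shelf_area_fraction = get_key(b, "shelf_area_fraction", default = 0.5)),
      config_error("bathymetry.kind", "must be 'conical' or 'shelf'")
    )
    lake_scenario(bath, get_key(config, "chl_pre", required = TRUE))
  }
  dfr_max <- get_key(config, "dfr_max", default = 100)
  dfr_step <- get_key(config, "dfr_step", default = 1)
  curve <- habitat_gain_curve(lake, dfr_grid = seq(0, dfr_max, by = dfr_step))
  list(habitat_curve = data.frame(
    dfr = curve$abundance, chl_post = curve$chl_post,
    secchi_m = curve$secchi_m, eta_per_m = curve$eta_per_m,
    z_star_m = curve$z_star_m,
    colonizable_fraction = curve$colonizable_fraction,
    gain = curve$impact))
}

run_designs_stage <- function(config, seed) {
  preset <- get_key(config, "preset")
  if (!is.null(preset)) {
    ps <- design_presets()
    if (!preset %in% names(ps)) {
      config_error("preset", sprintf("unknown design preset '%s'", preset))
    }
    ls <- ps[[preset]]$landscape
    abundances <- ps[[preset]]$abundances
  } else {
    slopes <- get_key(config, "slopes", required = TRUE)
    props <- get_key(config, "proportions", required = TRUE)
    types <- lapply(unlist(slopes), ecosystem_type)
    traj <- trajectory_params(
      n_years = get_key(config, "n_years", default = 25),
      mean_level = get_key(config, "mean_level", default = 1),
      log_sd = get_key(config, "log_sd", default = 0.61),
      autocorr = get_key(config, "autocorr", default = 0.3))
    ls <- landscape(types, unlist(props),
                    n_lakes = get_key(config, "n_lakes", required = TRUE),
                    trajectory = traj)
    abundances <- NULL
  }
  cmp <- compare_designs(ls, seed = seed, abundances = abundances)
  points <- rbind(
    data.frame(lake_id = cmp$snapshot$lake_id, type = cmp$snapshot$type,
               abundance = cmp$snapshot$abundance,
               impact = cmp$snapshot$impact, design_kind = "snapshot"),
    data.frame(lake_id = cmp$long_term$lake_id, type = cmp$long_term$type,
               abundance = cmp$long_term$abundance,
               impact = cmp$long_term$impact, design_kind = "long_term")
  )
  fits <- rbind(
    data.frame(design_kind = "snapshot", slope = cmp$snapshot_fit$slope,
               intercept = cmp$snapshot_fit$intercept,
               r_squared = cmp$snapshot_fit$r_squared),
    data.frame(design_kind = "long_term", slope = cmp$long_term_fit$slope,
               intercept = cmp$long_term_fit$intercept,
               r_squared = cmp$long_term_fit$r_squared),
    data.frame(design_kind = paste0("within:", names(cmp$within_slopes)),
               slope = unname(cmp$within_slopes), intercept = 0, r_squared = 1)
  )
  list(points = points, fits = fits, discrepancy = cmp$discrepancy)
}
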