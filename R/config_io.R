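## JSON run-configuration files.  Parameter keys carry the model's table
## names verbatim ("NOMAD POPULATION", "MOVE RANGE", ...) so a config can
## be read against the published parameter table directly.

param_key_map <- c(
  "NOMAD POPULATION" = "population",
  "MOVE RANGE" = "move_range_km",
  "GRAZE RANGE" = "graze_range_km",
  "SCOUTING FREQUENCY" = "scouting_frequency",
  "SCOUTING RANGE" = "scouting_range_km",
  "CARRYING CAPACITY" = "carrying_capacity",
  "INTERVALS OF ROUTE UPDATE" = "update_interval_years",
  "NUMBER OF ALTERNATIVE ROUTES" = "n_alternatives",
  "PENALTY TO MOVEMENT BEYOND MOVE RANGE" = "penalty",
  "STOCHASTIC NOISE (Minimum)" = "noise_min",
  "STOCHASTIC NOISE (Maximum)" = "noise_max",
  "DISRUPTION EFFECT" = "disruption_effect",
  "ALPHA" = "alpha",
  "BETA" = "beta",
  "COST MODE" = "cost_mode",
  "LINEAR SLOPE" = "linear_slope",
  "RESOURCE SHARE" = "share_mode")

#' Read a run configuration from a JSON file
#'
#' The file has up to three blocks: `parameters` (model-table names, see
#' [nomad_params()]), `environment` (either `synthetic` with
#' [synth_params()] fields, or `rasters`/`landcover`/`tsetse` file paths
#' for ASCII-grid inputs), and `run` (`n_years`, `burn_in_years`, `seed`,
#' optional `access_months`, `use_tsetse`).  `"RESOURCE SHARE": false`
#' selects lottery mode.
#'
#' @param path Path to the JSON config.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pj <- cfg$parameters %||% list()
  args <- list()
  for (key in names(pj)) {
    nm <- unname(param_key_map[key])
    if (is.na(nm)) stop("unknown parameter key: ", key)
    v <- pj[[key]]
    if (nm == "share_mode" && is.logical(v))
      v <- if (v) "share" else "lottery"
    args[[nm]] <- v
  }
  params <- do.call(nomad_params, args)

  ej <- cfg$environment %||% list()
  if (!is.null(ej$synthetic)) {
    sp <- ej$synthetic
    g <- grid_spec(sp$height %||% 64, sp$width %||% 64,
                   sp$pixel_km %||% 1)
    sp$height <- sp$width <- sp$pixel_km <- NULL
    env <- do.call(synth_params, c(list(grid = g), sp))
  } else {
    grid <- grid_spec(ej$height, ej$width, ej$pixel_km %||% 1)
    raw <- load_resource_stack(ej$rasters, grid,
                               start_year = ej$start_year %||% 2005L,
                               start_month = ej$start_month %||% 1L,
                               scale = ej$scale %||% 1)
    lc_mat <- read_ascii_grid(ej$landcover)
    ct <- unlist(ej$code_table)
    lc <- landcover_map(lc_mat, grid, code_table = ct)
    stack <- preprocess_ndvi(raw, lc,
                             reduction = ej$reduction %||% 0.5)
    ts <- if (!is.null(ej$tsetse))
      tsetse_map(read_ascii_grid(ej$tsetse), grid)
    env <- list(stack = stack, landcover = lc, tsetse = ts)
  }

  rj <- cfg$run %||% list()
  schedule <- if (!is.null(rj$access_months))
    access_schedule(unlist(rj$access_months))
  run_config(params, env,
             n_years = rj$n_years %||% 20000L,
             burn_in_years = rj$burn_in_years %||% 1000L,
             schedule = schedule,
             use_tsetse = isTRUE(rj$use_tsetse),
             seed = rj$seed %||% 1L,
             record_gains = !isFALSE(rj$record_gains),
             intensity_counting = rj$intensity_counting %||% "site")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an intensity map as monthly ASCII-grid rasters
#'
#' One single-band raster per calendar month, named
#' `<prefix>_m01.asc` ... `<prefix>_m12.asc`.
#'
#' @param m An [intensity_map()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_intensity_map <- function(m, dir, prefix = "intensity") {
  stopifnot(inherits(m, "intensity_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_m%02d.asc", prefix, 1:12))
  for (k in 1:12)
    write_ascii_grid(m$values[, , k], paths[k],
                     cellsize = m$grid$pixel_km * 1000)
  invisible(paths)
}

#' Write a seasonal classification as a coded ASCII-grid raster
#'
#' Codes: 1 = dry_dominant, 2 = wet_dominant, 3 = not_seasonal,
#' 0 = not_exploited.
#'
#' @param cls Category matrix from [classify_sites()].
#' @param path Output file.
#' @param pixel_km Cell size in km.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(cls, path, pixel_km = 1) {
  codes <- c(dry_dominant = 1, wet_dominant = 2, not_seasonal = 3,
             not_exploited = 0)
  m <- matrix(codes[cls], nrow(cls), ncol(cls))
  write_ascii_grid(m, path, cellsize = pixel_km * 1000)
  invisible(path)
}
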