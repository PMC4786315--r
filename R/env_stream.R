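#' Monthly resource stack (ENV)
#'
#' The model's environment is a stack of `n_months` monthly 2-D resource
#' fields over one [grid_spec()].  Layers are calendar months in
#' chronological order; the stack must span whole years (`n_months`
#' divisible by 12, at least one year).  Raw NDVI stacks hold values in
#' `[-1, 1]`; after [preprocess_ndvi()] the stack is flagged `adjusted` and
#' all values lie in `[0, 1]`.
#'
#' @param values Numeric array `height x width x n_months`, or a list of
#'   `height x width` matrices.
#' @param grid A [grid_spec()].
#' @param start_year,start_month Calendar label of the first layer (layer
#'   labels are inferred from file/layer order, not parsed from names).
#' @param adjusted Logical; `TRUE` once land-cover discounting and negative
#'   clipping have been applied.
#' @return An object of class `resource_stack` with fields `grid`, `values`,
#'   `labels` (data.frame of `year`, `month`) and attribute `adjusted`.
#' @export
resource_stack <- function(values, grid, start_year = 2005L,
                           start_month = 1L, adjusted = FALSE) {
  if (is.list(values))
    values <- array(unlist(values, use.names = FALSE),
                    dim = c(grid$height, grid$width, length(values)))
  stopifnot(length(dim(values)) == 3)
  if (dim(values)[1] != grid$height || dim(values)[2] != grid$width)
    stop("values dimensions do not match grid")
  n_months <- dim(values)[3]
  if (n_months < 12L || n_months %% 12L != 0L)
    stop("a resource stack must cover whole years: n_months = ", n_months,
         " is not a positive multiple of 12")
  if (start_month < 1L || start_month > 12L) stop("start_month must be 1..12")
  lo <- if (adjusted) 0 else -1
  rng <- range(values)
  if (rng[1] < lo - 1e-9 || rng[2] > 1 + 1e-9)
    stop(sprintf("resource values outside [%g, 1]", lo))
  idx <- seq_len(n_months) - 1L
  labels <- data.frame(
    year = start_year + (start_month - 1L + idx) %/% 12L,
    month = ((start_month - 1L + idx) %% 12L) + 1L)
  structure(list(grid = grid, n_months = n_months, values = values,
                 labels = labels),
            adjusted = adjusted, class = "resource_stack")
}

#' @export
print.resource_stack <- function(x, ...) {
  l <- x$labels
  cat(sprintf(
    "<resource_stack> %d months (%d-%02d .. %d-%02d), %d x %d grid, %s\n",
    x$n_months, l$year[1], l$month[1], l$year[x$n_months],
    l$month[x$n_months], x$grid$height, x$grid$width,
    if (isTRUE(attr(x, "adjusted"))) "adjusted" else "raw"))
  invisible(x)
}

#' Land-cover map
#'
#' One land-cover class per site, using the five-class subset of the UMD
#' scheme the model distinguishes: `grassland`, `savanna`, `woody_savanna`
#' (the classes pastoralists prefer), `cropland` (subject to access
#' schedules) and `other`.
#'
#' @param classes Character matrix `height x width` of class names, or an
#'   integer matrix plus a `code_table` mapping integer codes to class names
#'   (for maps exported from MCD12Q1-style products).
#' @param grid A [grid_spec()].
#' @param code_table Named character vector, names = integer codes as
#'   strings, values = class names; unlisted codes become `"other"`.
#' @export
landcover_map <- function(classes, grid, code_table = NULL) {
  valid <- c("grassland", "savanna", "woody_savanna", "cropland", "other")
  if (is.numeric(classes)) {
    if (is.null(code_table)) stop("integer class codes need a code_table")
    cls <- code_table[as.character(classes)]
    cls[is.na(cls)] <- "other"
    classes <- matrix(cls, nrow(classes), ncol(classes))
  }
  if (!all(dim(classes) == c(grid$height, grid$width)))
    stop("classes dimensions do not match grid")
  if (!all(classes %in% valid))
    stop("unknown land-cover class: ",
         paste(setdiff(unique(as.vector(classes)), valid), collapse = ", "))
  structure(list(grid = grid, classes = classes), class = "landcover_map")
}

#' @export
print.landcover_map <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("<landcover_map> %d x %d grid: %s\n", x$grid$height,
              x$grid$width,
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tsetse-presence probability map
#'
#' Per-site probability in `[0, 1]` that an agent encounters tsetse flies
#' when it grazes or scouts the site (the *Morsitans*-group savanna-fly
#' extension).
#'
#' @param p Numeric matrix `height x width` of probabilities.
#' @param grid A [grid_spec()].
#' @export
tsetse_map <- function(p, grid) {
  if (!all(dim(p) == c(grid$height, grid$width)))
    stop("p dimensions do not match grid")
  if (any(p < 0 | p > 1)) stop("tsetse probabilities must lie in [0, 1]")
  structure(list(grid = grid, p = p), class = "tsetse_map")
}

#' Cropland access schedule
#'
#' Restricts grazing on one land-cover class (normally `cropland`) to a set
#' of calendar months.  Outside `allowed_months` the restricted sites return
#' a resource value of 0 but remain traversable: access to vegetation is
#' denied, presence is not.
#'
#' @param allowed_months Integer subset of `1:12`; `1:12` is open access,
#'   `integer(0)` total exclusion.
#' @param restricted_class Land-cover class name the schedule applies to.
#' @examples
#' access_schedule(c(1, 2, 3))         # dry-season access Jan-Mar
#' access_schedule(c(11, 12, 1:4))     # half-year access Nov-Apr
#' access_schedule(integer(0))         # total exclusion
#' @export
access_schedule <- function(allowed_months, restricted_class = "cropland") {
  allowed_months <- as.integer(allowed_months)
  if (length(allowed_months) && !all(allowed_months %in% 1:12))
    stop("allowed_months must be a subset of 1..12")
  structure(list(restricted_class = restricted_class,
                 allowed_months = sort(unique(allowed_months))),
            class = "access_schedule")
}

#' Read an ESRI ASCII grid raster
#'
#' Minimal reader for the plain-text single-band ASCII grid format
#' (`ncols`/`nrows`/... header followed by rows of values, first row =
#' northern edge).  `NODATA_value` cells become `NA`.
#'
#' @param path File path.
#' @return Numeric matrix (rows = grid rows from the north).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values in ", path, ", found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "cellsize") <- hdr$cellsize
  m
}

#' Write an ESRI ASCII grid raster
#'
#' @param m Numeric matrix (rows from the north).
#' @param path Output file path.
#' @param cellsize Cell size in the map units (default 1000 m = 1 km).
#' @param xll,yll Lower-left corner coordinates.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1000, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", xll), paste("yllcorner", yll),
               paste("cellsize", cellsize), "NODATA_value -9999"), con)
  m[is.na(m)] <- -9999
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load an ordered series of monthly rasters as a resource stack
#'
#' Reads one single-band ASCII-grid raster per month, in chronological
#' order, and assembles the raw (unadjusted) resource stack.  Values are
#' multiplied by `scale` (e.g. `1e-4` for MODIS NDVI digital numbers) but
#' otherwise untouched; layer labels are inferred from file order and the
#' configured start year/month.
#'
#' @param raster_paths Character vector of file paths, chronological.
#' @param grid A [grid_spec()]; every raster must match its dimensions.
#' @param start_year,start_month Calendar label of the first raster.
#' @param scale Multiplier applied to raw cell values (default 1).
#' @param na_fill Value substituted for NODATA cells (default 0).
#' @return A raw `resource_stack`.
#' @export
load_resource_stack <- function(raster_paths, grid, start_year = 2005L,
                                start_month = 1L, scale = 1,
                                na_fill = 0) {
  n <- length(raster_paths)
  vals <- array(NA_real_, dim = c(grid$height, grid$width, n))
  for (k in seq_len(n)) {
    m <- read_ascii_grid(raster_paths[k])
    if (nrow(m) != grid$height || ncol(m) != grid$width)
      stop("raster ", raster_paths[k], " is ", nrow(m), "x", ncol(m),
           ", expected ", grid$height, "x", grid$width)
    m <- m * scale
    m[is.na(m)] <- na_fill
    vals[, , k] <- m
  }
  resource_stack(vals, grid, start_year = start_year,
                 start_month = start_month, adjusted = FALSE)
}

#' Preprocess a raw NDVI stack into model resource values
#'
#' Two adjustments turn satellite NDVI into the grazing-resource values the
#' model consumes: negative NDVI (clouds, water, snow) is clipped to 0, and
#' values on land-cover classes pastoralists do not prefer are discounted by
#' `reduction` (default 50%).  Preferred classes (`grassland`, `savanna`,
#' `woody_savanna` by default) are left untouched.  An already-adjusted
#' stack is returned unchanged, so the operation is idempotent.
#'
#' @param raw A raw `resource_stack` with values in `[-1, 1]`.
#' @param landcover A [landcover_map()] on the same grid.
#' @param reduction Discount fraction in `[0, 1]` for non-preferred classes.
#' @param preferred Character vector of undiscounted class names.
#' @return An adjusted `resource_stack` with values in `[0, 1]`.
#' @export
preprocess_ndvi <- function(raw, landcover,
                            reduction = 0.5,
                            preferred = c("grassland", "savanna",
                                          "woody_savanna")) {
  stopifnot(inherits(raw, "resource_stack"))
  if (isTRUE(attr(raw, "adjusted"))) return(raw)
  if (!is.finite(reduction) || reduction < 0 || reduction > 1)
    stop("reduction must lie in [0, 1]")
  if (!identical(landcover$grid[c("height", "width")],
                 raw$grid[c("height", "width")]))
    stop("landcover grid does not match stack grid")
  factor <- ifelse(landcover$classes %in% preferred, 1, 1 - reduction)
  vals <- pmax(raw$values, 0)
  for (k in seq_len(raw$n_months)) vals[, , k] <- vals[, , k] * factor
  resource_stack(vals, raw$grid, start_year = raw$labels$year[1],
                 start_month = raw$labels$month[1], adjusted = TRUE)
}

## layer index for (sim_year, month) under the cyclic data stream:
## after the last layer the stream returns to the first
layer_index <- function(stack, sim_year, month) {
  ((sim_year * 12L + (month - 1L)) %% stack$n_months) + 1L
}

#' Monthly resource field with access restrictions applied
#'
#' Returns the full `height x width` field the environment serves for one
#' simulated month: the cyclically indexed stack layer, with sites of the
#' schedule's restricted land-cover class zeroed in months outside the
#' schedule.  Carrying-capacity zeroing is applied by the simulation layer,
#' not here.
#'
#' @param stack An adjusted `resource_stack`.
#' @param sim_year 0-based simulation year.
#' @param month Calendar month 1..12.
#' @param schedule An [access_schedule()] or `NULL`.
#' @param landcover A [landcover_map()]; required when `schedule` is given.
#' @return Numeric matrix.
#' @export
env_month_field <- function(stack, sim_year, month, schedule = NULL,
                            landcover = NULL) {
  field <- stack$values[, , layer_index(stack, sim_year, month)]
  if (!is.null(schedule) && !(month %in% schedule$allowed_months)) {
    if (is.null(landcover))
      stop("an access schedule needs a landcover map")
    field[landcover$classes == schedule$restricted_class] <- 0
  }
  field
}

#' Resource value served at one site in one simulated month
#'
#' @inheritParams env_month_field
#' @param site Site as `(row, col)` or linear index.
#' @return Scalar resource value.
#' @export
env_value <- function(stack, site, sim_year, month, schedule = NULL,
                      landcover = NULL) {
  rc <- as_rc(site, stack$grid)
  assert_on_grid(rc[1], rc[2], stack$grid)
  idx <- as_index(site, stack$grid)
  v <- stack$values[, , layer_index(stack, sim_year, month)][idx]
  if (!is.null(schedule) && !(month %in% schedule$allowed_months)) {
    if (is.null(landcover))
      stop("an access schedule needs a landcover map")
    if (landcover$classes[idx] == schedule$restricted_class) v <- 0
  }
  v
}
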