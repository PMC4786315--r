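#' Grid specification
#'
#' Defines the raster geometry of the simulated environment (ENV): a regular
#' `height` x `width` grid of square sites with edge length `pixel_km`.
#' Coordinates throughout the package are 1-based `(row, col)` pairs with
#' row 1 at the northern edge; a site may equivalently be addressed by its
#' column-major linear index `row + (col - 1) * height`, which is how routes
#' and placements are stored internally.
#'
#' @param height,width Grid dimensions in sites (>= 1).
#' @param pixel_km Edge length of one site in km (> 0); 1 km matches the
#'   MODIS MYD13A3 resolution the model was designed around.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(324, 324)
#' @export
grid_spec <- function(height, width, pixel_km = 1.0) {
  stopifnot(length(height) == 1, length(width) == 1, length(pixel_km) == 1)
  height <- as.integer(height)
  width <- as.integer(width)
  if (is.na(height) || height < 1L) stop("height must be >= 1")
  if (is.na(width) || width < 1L) stop("width must be >= 1")
  if (!is.finite(pixel_km) || pixel_km <= 0) stop("pixel_km must be > 0")
  structure(list(height = height, width = width, pixel_km = pixel_km),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d sites, %.3g km/pixel (%d sites)\n",
              x$height, x$width, x$pixel_km, x$height * x$width))
  invisible(x)
}

n_sites <- function(grid) grid$height * grid$width

## linear index <-> (row, col); column-major to match R matrix storage
site_index <- function(row, col, grid) {
  as.integer(row + (col - 1L) * grid$height)
}

site_rc <- function(idx, grid) {
  idx <- as.integer(idx)
  cbind(row = ((idx - 1L) %% grid$height) + 1L,
        col = ((idx - 1L) %/% grid$height) + 1L)
}

assert_on_grid <- function(row, col, grid) {
  if (any(row < 1L | row > grid$height | col < 1L | col > grid$width))
    stop("site (", row[1], ",", col[1], ") is off the ", grid$height, "x",
         grid$width, " grid")
  invisible(TRUE)
}

#' Euclidean distance between two sites in km
#'
#' Inter-site movement distances (MOVE RANGE, SCOUTING RANGE eligibility,
#' route range) use the Euclidean metric on site centres, scaled by
#' `pixel_km`.
#'
#' @param a,b Sites as length-2 `(row, col)` vectors or linear indices.
#' @param grid A [grid_spec()].
#' @return Distance in km.
#' @export
site_distance_km <- function(a, b, grid) {
  a <- as_rc(a, grid)
  b <- as_rc(b, grid)
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2) * grid$pixel_km
}

## accept either a linear index or a (row, col) pair
as_rc <- function(s, grid) {
  if (length(s) == 1L) as.numeric(site_rc(s, grid)[1L, ]) else as.numeric(s)
}

as_index <- function(s, grid) {
  if (length(s) == 1L) as.integer(s) else site_index(s[1], s[2], grid)
}

#' Grazing neighborhood of a site
#'
#' Returns all on-grid sites within `range_km` of `site` under the Chebyshev
#' (square-window) metric, i.e. the `(2w+1) x (2w+1)` window with
#' `w = floor(range_km / pixel_km)`, clipped at the grid edges.  This is the
#' window over which grazing and scouting assessments average (GRAZE RANGE).
#'
#' @param site Site as `(row, col)` or linear index.
#' @param range_km Radius in km (>= 0).
#' @param grid A [grid_spec()].
#' @return Integer vector of linear site indices; always contains `site`.
#' @examples
#' g <- grid_spec(5, 5)
#' length(neighborhood(c(3, 3), 1, g))  # 9
#' length(neighborhood(c(1, 1), 1, g))  # 4 (clipped corner)
#' @export
neighborhood <- function(site, range_km, grid) {
  if (!is.finite(range_km) || range_km < 0) stop("range_km must be >= 0")
  rc <- as_rc(site, grid)
  assert_on_grid(rc[1], rc[2], grid)
  w <- floor(range_km / grid$pixel_km + 1e-9)
  rows <- max(1L, rc[1] - w):min(grid$height, rc[1] + w)
  cols <- max(1L, rc[2] - w):min(grid$width, rc[2] + w)
  as.integer(outer(rows, (cols - 1L) * grid$height, `+`))
}

## relative (drow, dcol) offsets of sites within a Euclidean disc of radius
## range_km; precomputed once per run for uniform scouting-target draws
disc_offsets <- function(range_km, pixel_km) {
  w <- floor(range_km / pixel_km + 1e-9)
  dr <- rep(-w:w, times = 2L * w + 1L)
  dc <- rep(-w:w, each = 2L * w + 1L)
  keep <- (dr^2 + dc^2) * pixel_km^2 <= range_km^2 + 1e-9
  cbind(dr = dr[keep], dc = dc[keep])
}

## uniform draw among on-grid sites within the Euclidean disc around `rc`
## (rejection from the precomputed offset list keeps the draw uniform on the
## clipped disc)
sample_disc_site <- function(rc, offsets, grid) {
  repeat {
    k <- sample.int(nrow(offsets), 1L)
    r <- rc[1] + offsets[k, 1L]
    c <- rc[2] + offsets[k, 2L]
    if (r >= 1L && r <= grid$height && c >= 1L && c <= grid$width)
      return(site_index(r, c, grid))
  }
}
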