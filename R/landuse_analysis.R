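#' Land-use intensity map
#'
#' Mean number of grazing agents per year on each site in each calendar
#' month — the quantity the simulation accumulates over the recorded years
#' and the input to seasonal classification.
#'
#' @param values Numeric array `height x width x 12` (month = 3rd dim).
#' @param grid A [grid_spec()].
#' @return An object of class `intensity_map`.
#' @export
intensity_map <- function(values, grid) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == 12L)
  if (!all(dim(values)[1:2] == c(grid$height, grid$width)))
    stop("values dimensions do not match grid")
  if (any(values < 0)) stop("intensity values must be >= 0")
  structure(list(grid = grid, values = values), class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %d x %d grid, max %.3g agents/site/year (month %d)\n",
              x$grid$height, x$grid$width, max(x$values),
              which.max(apply(x$values, 3, max))))
  invisible(x)
}

#' Seasonal summary of an intensity map
#'
#' Collapses the 12 monthly layers into the dry-season mean
#' (January-March), the rainy-season mean (July-September) and the annual
#' mean over all 12 months.
#'
#' @param m An [intensity_map()].
#' @return An object of class `seasonal_summary` with matrices `dry`,
#'   `wet`, `annual` and the `grid`.
#' @export
seasonal_summary <- function(m) {
  stopifnot(inherits(m, "intensity_map"))
  structure(list(grid = m$grid,
                 dry = apply(m$values[, , 1:3, drop = FALSE], 1:2, mean),
                 wet = apply(m$values[, , 7:9, drop = FALSE], 1:2, mean),
                 annual = apply(m$values, 1:2, mean)),
            class = "seasonal_summary")
}

#' Dry/wet RGB composite of a seasonal summary
#'
#' The visual convention for seasonal land use: the dry-season intensity
#' drives the red band and the rainy-season intensity the green band (blue
#' stays 0), both scaled by the common maximum, so sites used equally in
#' both seasons render yellow and unexploited sites black.
#'
#' @param s A [seasonal_summary()].
#' @return Numeric array `height x width x 3` in `[0, 1]`.
#' @export
seasonal_composite <- function(s) {
  stopifnot(inherits(s, "seasonal_summary"))
  top <- max(s$dry, s$wet, 1e-12)
  array(c(s$dry / top, s$wet / top,
          matrix(0, s$grid$height, s$grid$width)),
        dim = c(s$grid$height, s$grid$width, 3L))
}

landuse_categories <- c("dry_dominant", "wet_dominant", "not_seasonal",
                        "not_exploited")

#' Seasonal land-use classification
#'
#' Assigns each site one of four exclusive categories.  A site whose annual
#' mean visit frequency does not exceed `exploit_threshold` is
#' `not_exploited`; otherwise it is `dry_dominant` (`wet_dominant`) when
#' the dry (wet) season mean exceeds the other season's by more than the
#' land-use threshold `land_use_threshold`, and `not_seasonal` when
#' neither does.  The exploitation test is applied first, which makes the
#' `not_exploited` count invariant to the land-use threshold.
#'
#' @param s A [seasonal_summary()].
#' @param land_use_threshold Seasonal-difference threshold (> 0); the
#'   published classifications use 0.001, 0.01 and 0.1.
#' @param exploit_threshold Exploitation threshold (default 0.001, held
#'   constant in the published scheme).
#' @return Character matrix of categories (levels
#'   `dry_dominant`, `wet_dominant`, `not_seasonal`, `not_exploited`).
#' @export
classify_sites <- function(s, land_use_threshold,
                           exploit_threshold = 0.001) {
  stopifnot(inherits(s, "seasonal_summary"))
  if (land_use_threshold <= 0 || exploit_threshold <= 0)
    stop("thresholds must be > 0")
  out <- matrix("not_seasonal", s$grid$height, s$grid$width)
  out[s$dry - s$wet > land_use_threshold] <- "dry_dominant"
  out[s$wet - s$dry > land_use_threshold] <- "wet_dominant"
  out[s$annual <= exploit_threshold] <- "not_exploited"
  out
}

#' Confusion matrix of two classified maps
#'
#' Cross-tabulates sites by their category under pattern A (rows) and
#' pattern B (columns), in the fixed category order `dry_dominant`,
#' `wet_dominant`, `not_seasonal`, `not_exploited`.
#'
#' @param a,b Category matrices from [classify_sites()] on the same grid.
#' @return A 4x4 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("classified maps are on different grids")
  m <- table(factor(a, levels = landuse_categories),
             factor(b, levels = landuse_categories))
  structure(unclass(m), class = "confusion_matrix")
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement between the two patterns:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and expected agreement
#' `p_e = sum_i row_i * col_i / total^2`.  Degenerate all-mass-in-one-cell
#' matrices (`p_e = 1`) return 1 when the mass is on the diagonal.
#'
#' @param m A square count matrix (e.g. from [confusion_matrix()]).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(m) {
  m <- as.matrix(unclass(m))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (1 - p_e < .Machine$double.eps) {
    if (abs(p_o - 1) < .Machine$double.eps) return(1.0)
    stop("expected agreement is 1 with imperfect observed agreement")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Range of a route
#'
#' The distance between the two sites of a route that are farthest apart
#' (maximum pairwise Euclidean distance, in km).
#'
#' @param route Integer vector of 12 linear site indices, or a 12x2
#'   `(row, col)` matrix.
#' @param grid A [grid_spec()].
#' @return Range in km.
#' @export
route_range <- function(route, grid) {
  rc <- if (is.matrix(route)) route else site_rc(route, grid)
  max(stats::dist(rc)) * grid$pixel_km
}

#' Summarize obtained resources
#'
#' Collapses per-agent monthly gain logs into the published summary
#' numbers: the mean over agent-months, the inter-annual SD (SD of the
#' yearly means within a run; sample SD, divisor n-1), and — when several
#' runs are supplied — the SD of the run means across runs.
#'
#' @param gain_log A recorded-months x agents matrix (one run), or a list
#'   of such matrices (an ensemble).  Rows must cover whole years.
#' @return List with `mean`, `interannual_sd`, and (for ensembles)
#'   `across_run_sd` and per-run means `run_means`.
#' @export
summarize_resources <- function(gain_log) {
  one <- function(g) {
    if (!is.matrix(g)) g <- matrix(g, ncol = 1)
    if (nrow(g) %% 12L != 0L || nrow(g) == 0L)
      stop("gain log must cover whole years")
    yearly <- rowsum(rowMeans(g), rep(seq_len(nrow(g) / 12L),
                                      each = 12L)) / 12
    list(mean = mean(g),
         interannual_sd = if (length(yearly) > 1) stats::sd(yearly) else 0)
  }
  if (is.list(gain_log) && !is.data.frame(gain_log)) {
    per <- lapply(gain_log, one)
    run_means <- vapply(per, `[[`, numeric(1), "mean")
    list(mean = mean(run_means),
         interannual_sd = mean(vapply(per, `[[`, numeric(1),
                                      "interannual_sd")),
         across_run_sd = if (length(run_means) > 1) stats::sd(run_means)
         else 0,
         run_means = run_means)
  } else one(gain_log)
}
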