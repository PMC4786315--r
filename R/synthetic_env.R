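#' Parameters of the synthetic dryland environment generator
#'
#' Describes a stylized Sudano-Sahelian landscape: monthly NDVI-like
#' resource values in `[0, 1]` with strong intra-annual seasonality (a
#' single wet season), a north-to-south gradient of annual mean greenness,
#' persistent localized "key resource" patches, lognormal inter-annual
#' variation (drought/good-year multipliers), additive observation noise, a
#' spatially autocorrelated land-cover mosaic with a controllable cropland
#' fraction, and a smooth tsetse-presence field confined to a southern band.
#'
#' Defaults state the emulated world once: a 10-year stream (the length of
#' the MODIS series the model was built around), dry-season baseline NDVI
#' around 0.25 rising by 0.2 from north to south, wet-season amplitude 0.25
#' peaking in June-September, inter-annual coefficient of variation 0.15
#' (Sahelian drought cycles), cropland fraction 0.53 (the study area's
#' share), and tsetse presence over the southern 40% of rows.
#'
#' @param grid A [grid_spec()].
#' @param n_years Years of monthly layers to generate (>= 1).
#' @param base_level Mean dry-season resource level in `[0, 1]`.
#' @param seasonal_amplitude Wet-season peak increment in `[0, 1]`.
#' @param wet_months Months of the rainy season (default June-September).
#' @param latitudinal_gradient North-to-south difference in annual mean
#'   (positive = greener south).
#' @param n_key_sites Number of persistent high-resource patches.
#' @param patch_radius_km Gaussian radius of each patch in km.
#' @param patch_height Peak resource boost at a patch centre.
#' @param interannual_cv Coefficient of variation of the lognormal yearly
#'   multipliers.
#' @param noise_sd SD of additive per-site-month Gaussian noise.
#' @param cropland_fraction Target cropland share of the land-cover map.
#' @param tsetse_south_extent Fraction of rows, from the southern edge, over
#'   which tsetse presence rises from 0.
#' @param seed Integer seed; all three generators derive sub-seeds from it
#'   so each product is reproducible independently.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(grid = grid_spec(64, 64),
                         n_years = 10L,
                         base_level = 0.25,
                         seasonal_amplitude = 0.25,
                         wet_months = 6:9,
                         latitudinal_gradient = 0.2,
                         n_key_sites = 10L,
                         patch_radius_km = 3,
                         patch_height = 0.3,
                         interannual_cv = 0.15,
                         noise_sd = 0.02,
                         cropland_fraction = 0.53,
                         tsetse_south_extent = 0.4,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), n_years >= 1)
  fr <- c(base_level = base_level, seasonal_amplitude = seasonal_amplitude,
          cropland_fraction = cropland_fraction,
          tsetse_south_extent = tsetse_south_extent)
  bad <- fr < 0 | fr > 1
  if (any(bad)) stop(names(fr)[bad][1], " must lie in [0, 1]")
  if (length(wet_months) && !all(wet_months %in% 1:12))
    stop("wet_months must be a subset of 1..12")
  structure(list(grid = grid, n_years = as.integer(n_years),
                 base_level = base_level,
                 seasonal_amplitude = seasonal_amplitude,
                 wet_months = as.integer(wet_months),
                 latitudinal_gradient = latitudinal_gradient,
                 n_key_sites = as.integer(n_key_sites),
                 patch_radius_km = patch_radius_km,
                 patch_height = patch_height,
                 interannual_cv = interannual_cv,
                 noise_sd = noise_sd,
                 cropland_fraction = cropland_fraction,
                 tsetse_south_extent = tsetse_south_extent,
                 seed = as.integer(seed)),
            class = "synth_params")
}

## evaluate expr under a temporary seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

## cosine annual cycle peaking at the circular mean of the wet months,
## rescaled to [0, 1]
seasonal_profile <- function(wet_months) {
  ang <- 2 * pi * (wet_months - 0.5) / 12
  peak <- atan2(mean(sin(ang)), mean(cos(ang))) * 12 / (2 * pi) + 0.5
  m <- 1:12
  (1 + cos(2 * pi * (m - peak) / 12)) / 2
}

## smooth random field in roughly [-1, 1]: coarse iid normals bilinearly
## upsampled -- cheap spatial autocorrelation without an extra dependency
smooth_field <- function(h, w, coarse = 8L) {
  ch <- max(2L, ceiling(h / coarse) + 1L)
  cw <- max(2L, ceiling(w / coarse) + 1L)
  z <- matrix(rnorm(ch * cw), ch, cw)
  ri <- seq(1, ch, length.out = h)
  ci <- seq(1, cw, length.out = w)
  r0 <- pmin(floor(ri), ch - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), cw - 1L); cf <- ci - c0
  a <- z[cbind(rep(r0, w), rep(c0, each = h))]
  b <- z[cbind(rep(r0 + 1, w), rep(c0, each = h))]
  cc <- z[cbind(rep(r0, w), rep(c0 + 1, each = h))]
  d <- z[cbind(rep(r0 + 1, w), rep(c0 + 1, each = h))]
  rfv <- rep(rf, w); cfv <- rep(cf, each = h)
  f <- (1 - rfv) * (1 - cfv) * a + rfv * (1 - cfv) * b +
    (1 - rfv) * cfv * cc + rfv * cfv * d
  matrix(f / 2, h, w)
}

#' Generate a synthetic monthly resource stack
#'
#' Builds `12 * n_years` monthly layers as
#' `clip01( base(site) + amplitude * season(month) + patches(site) )
#'  * yearly_mult(year) + noise`, clipped to `[0, 1]`.  The base level
#' increases toward the south by `latitudinal_gradient`; the seasonal cycle
#' peaks in `wet_months`; the key-resource patches are drawn once and
#' persist across all years; yearly multipliers are lognormal with mean 1
#' and CV `interannual_cv`.  Deterministic given `p$seed`.
#'
#' @param p A [synth_params()].
#' @return An adjusted `resource_stack`.
#' @export
generate_resource_stack <- function(p) {
  g <- p$grid
  h <- g$height; w <- g$width
  with_seed(p$seed + 1L, {
    lat <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0.5
    base <- matrix(p$base_level + p$latitudinal_gradient * (lat - 0.5),
                   h, w)
    patches <- matrix(0, h, w)
    if (p$n_key_sites > 0) {
      centres <- cbind(sample.int(h, p$n_key_sites, replace = TRUE),
                       sample.int(w, p$n_key_sites, replace = TRUE))
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      s2 <- (p$patch_radius_km / g$pixel_km)^2
      for (k in seq_len(p$n_key_sites)) {
        d2 <- (rr - centres[k, 1])^2 + (cc - centres[k, 2])^2
        patches <- pmax(patches, p$patch_height * exp(-d2 / (2 * s2)))
      }
    }
    season <- seasonal_profile(p$wet_months)
    if (p$interannual_cv > 0) {
      s2l <- log(1 + p$interannual_cv^2)
      mult <- exp(rnorm(p$n_years, -s2l / 2, sqrt(s2l)))
    } else mult <- rep(1, p$n_years)
    vals <- array(0, dim = c(h, w, 12L * p$n_years))
    for (y in seq_len(p$n_years)) for (m in 1:12) {
      f <- pmin(pmax(base + p$seasonal_amplitude * season[m] + patches,
                     0), 1) * mult[y]
      if (p$noise_sd > 0) f <- f + rnorm(h * w, 0, p$noise_sd)
      vals[, , (y - 1L) * 12L + m] <- pmin(pmax(f, 0), 1)
    }
    resource_stack(vals, g, start_year = 2005L, adjusted = TRUE)
  })
}

#' Generate a synthetic land-cover map
#'
#' Thresholds a smooth random field so that the realized cropland fraction
#' equals `cropland_fraction` (to quantile precision, well within the
#' contract's 0.05); the remaining sites are split among the three preferred
#' classes by the terciles of a second independent smooth field, giving the
#' blocky mosaic of cultivated and rangeland patches typical of the region.
#'
#' @param p A [synth_params()].
#' @return A [landcover_map()].
#' @export
generate_landcover <- function(p) {
  g <- p$grid
  with_seed(p$seed + 2L, {
    f1 <- smooth_field(g$height, g$width)
    f2 <- smooth_field(g$height, g$width)
    classes <- matrix("other", g$height, g$width)
    q <- stats::quantile(f2, c(1 / 3, 2 / 3))
    classes[f2 <= q[1]] <- "grassland"
    classes[f2 > q[1] & f2 <= q[2]] <- "savanna"
    classes[f2 > q[2]] <- "woody_savanna"
    if (p$cropland_fraction > 0) {
      thr <- stats::quantile(f1, 1 - p$cropland_fraction)
      classes[f1 >= thr] <- "cropland"
    }
    landcover_map(classes, g)
  })
}

#' Generate a synthetic tsetse-presence probability map
#'
#' A smooth field that is zero in the north and rises linearly over the
#' southern `tsetse_south_extent` fraction of rows, modulated laterally by
#' a smooth random factor, emulating the southern savanna-fly belt.
#'
#' @param p A [synth_params()].
#' @param p_max Peak presence probability at the southern edge.
#' @return A [tsetse_map()].
#' @export
generate_tsetse <- function(p, p_max = 0.8) {
  g <- p$grid
  with_seed(p$seed + 3L, {
    if (p$tsetse_south_extent <= 0)
      return(tsetse_map(matrix(0, g$height, g$width), g))
    band <- max(1, ceiling(p$tsetse_south_extent * g$height))
    north_edge <- g$height - band
    profile <- pmax(0, (seq_len(g$height) - north_edge) / band)
    mod <- 0.75 + 0.25 * pmin(pmax(smooth_field(g$height, g$width), -1), 1)
    prob <- matrix(profile, g$height, g$width) * p_max * mod
    tsetse_map(pmin(pmax(prob, 0), 1), g)
  })
}

#' Generate the complete synthetic environment
#'
#' Convenience wrapper returning the resource stack, land-cover map and
#' tsetse map for one [synth_params()] in a single list, ready to hand to
#' [run_config()].
#'
#' @param p A [synth_params()].
#' @return List with elements `stack`, `landcover`, `tsetse`.
#' @export
generate_environment <- function(p) {
  list(stack = generate_resource_stack(p),
       landcover = generate_landcover(p),
       tsetse = generate_tsetse(p))
}
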