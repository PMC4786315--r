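#' Model parameters
#'
#' Bundles every behavioral parameter of the agents.  Names follow the
#' model's parameter table: `population` (NOMAD POPULATION),
#' `move_range_km` (MOVE RANGE), `graze_range_km` (GRAZE RANGE),
#' `scouting_frequency`/`scouting_range_km` (SCOUTING FREQUENCY/RANGE),
#' `carrying_capacity` (CARRYING CAPACITY, agent-visits per site per year),
#' `update_interval_years` (INTERVALS OF ROUTE UPDATE), `n_alternatives`
#' (NUMBER OF ALTERNATIVE ROUTES), `penalty` (PENALTY TO MOVEMENT BEYOND
#' MOVE RANGE), `noise_min`/`noise_max` (STOCHASTIC NOISE bounds).
#'
#' Defaults are the baseline setting: carrying capacity 4, move range
#' 100 km, scouting 0.2/month over 100 km, yearly route updates, penalty
#' 100, noise in `[1e-6, 1e-2]`, and the fixed potential scalings
#' `alpha = 2`, `beta = 1`.  `population = 20`, `graze_range_km = 2` and
#' `n_alternatives = 10` are assumptions (the baseline values for these are
#' not recoverable from the published table); they are drawn from the
#' published parameter grids and flagged as such in the vignette.
#'
#' @param population Number of agents (>= 1).
#' @param move_range_km Monthly mobility threshold in km.
#' @param graze_range_km Radius of the grazing-assessment window in km.
#' @param scouting_frequency Probability per month of a scouting trip.
#' @param scouting_range_km Maximum Euclidean distance of a scouted site.
#' @param carrying_capacity Agent-visits a site hosts per year before its
#'   resources are zeroed for the rest of that year.
#' @param update_interval_years Years between route-update opportunities.
#' @param n_alternatives Number N of candidate routes at an update (>= 2).
#' @param penalty Movement cost for a step beyond `move_range_km`
#'   (step-function cost mode).
#' @param noise_min,noise_max Annealing-noise bounds: E equals `noise_min`
#'   when the current route's potential is 0 and `noise_max` when it is 1.
#' @param alpha,beta Potential scaling and offset (fixed at 2 and 1).
#' @param disruption_effect Weight of the remembered tsetse-encounter
#'   frequency in the potential (DISRUPTION EFFECT; 0 disables the term).
#' @param cost_mode `"step"` (threshold + penalty) or `"linear"`
#'   (`linear_slope` per km).
#' @param linear_slope Cost per km in linear cost mode.
#' @param share_mode `"share"` (co-located agents split resources equally)
#'   or `"lottery"` (each contested site goes wholly to one uniformly
#'   chosen overlapping agent).
#' @param cc_counting `"agent_months"` (an agent camping two months counts
#'   twice against carrying capacity) or `"unique_agents"`.
#' @param graze_metric Metric of the grazing window, `"chebyshev"` (square
#'   window) or `"euclidean"` (disc).
#' @param move_metric Metric of inter-site movement distances,
#'   `"euclidean"` or `"chebyshev"`.
#' @return An object of class `nomad_params`.
#' @export
nomad_params <- function(population = 20L,
                         move_range_km = 100,
                         graze_range_km = 2,
                         scouting_frequency = 0.2,
                         scouting_range_km = 100,
                         carrying_capacity = 4L,
                         update_interval_years = 1L,
                         n_alternatives = 10L,
                         penalty = 100,
                         noise_min = 1e-6,
                         noise_max = 1e-2,
                         alpha = 2.0,
                         beta = 1.0,
                         disruption_effect = 0,
                         cost_mode = c("step", "linear"),
                         linear_slope = 0.001,
                         share_mode = c("share", "lottery"),
                         cc_counting = c("agent_months", "unique_agents"),
                         graze_metric = c("chebyshev", "euclidean"),
                         move_metric = c("euclidean", "chebyshev")) {
  if (population < 1) stop("population must be >= 1")
  if (n_alternatives < 2) stop("n_alternatives must be >= 2")
  if (scouting_frequency < 0 || scouting_frequency > 1)
    stop("scouting_frequency must lie in [0, 1]")
  if (noise_min > noise_max) stop("noise_min must be <= noise_max")
  structure(list(population = as.integer(population),
                 move_range_km = move_range_km,
                 graze_range_km = graze_range_km,
                 scouting_frequency = scouting_frequency,
                 scouting_range_km = scouting_range_km,
                 carrying_capacity = as.integer(carrying_capacity),
                 update_interval_years = as.integer(update_interval_years),
                 n_alternatives = as.integer(n_alternatives),
                 penalty = penalty,
                 noise_min = noise_min, noise_max = noise_max,
                 alpha = alpha, beta = beta,
                 disruption_effect = disruption_effect,
                 cost_mode = match.arg(cost_mode),
                 linear_slope = linear_slope,
                 share_mode = match.arg(share_mode),
                 cc_counting = match.arg(cc_counting),
                 graze_metric = match.arg(graze_metric),
                 move_metric = match.arg(move_metric)),
            class = "nomad_params")
}

#' @export
print.nomad_params <- function(x, ...) {
  cat("<nomad_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

## -- memory ------------------------------------------------------------

#' Empty agent memory
#'
#' Memory maps each visited or scouted `(site, month)` pair to the running
#' time-mean of observed resource availability (and, under the tsetse
#' extension, the experienced encounter frequency), with observation
#' counts.  Stored as 12 per-month named vectors keyed by linear site
#' index.
#'
#' @return An object of class `nomad_memory`.
#' @export
new_memory <- function() {
  e <- list(res = rep(list(numeric(0)), 12L),
            n = rep(list(integer(0)), 12L),
            tse = rep(list(numeric(0)), 12L),
            tn = rep(list(integer(0)), 12L))
  structure(e, class = "nomad_memory")
}

#' Record an observation into agent memory
#'
#' Integrates a new assessment of `site` in calendar `month` with any
#' earlier ones: the stored value is the arithmetic time-mean of all
#' observations so far.  A tsetse encounter indicator (0/1), when supplied,
#' updates the remembered encounter frequency the same way.
#'
#' @param memory A `nomad_memory`.
#' @param site Site as `(row, col)` or linear index (grid needed for pairs).
#' @param month Calendar month 1..12.
#' @param value Observed resource availability in `[0, 1]`.
#' @param tsetse_hit 0/1 encounter indicator, or `NULL`.
#' @param grid A [grid_spec()], only needed when `site` is a coordinate pair.
#' @return The updated memory.
#' @export
record_observation <- function(memory, site, month, value,
                               tsetse_hit = NULL, grid = NULL) {
  key <- as.character(if (length(site) == 1L) as.integer(site)
                      else site_index(site[1], site[2], grid))
  n0 <- memory$n[[month]][key]
  if (is.na(n0)) {
    memory$res[[month]][key] <- value
    memory$n[[month]][key] <- 1L
  } else {
    memory$res[[month]][key] <- (memory$res[[month]][key] * n0 + value) /
      (n0 + 1L)
    memory$n[[month]][key] <- n0 + 1L
  }
  if (!is.null(tsetse_hit)) {
    t0 <- memory$tn[[month]][key]
    if (is.na(t0)) {
      memory$tse[[month]][key] <- tsetse_hit
      memory$tn[[month]][key] <- 1L
    } else {
      memory$tse[[month]][key] <- (memory$tse[[month]][key] * t0 +
                                     tsetse_hit) / (t0 + 1L)
      memory$tn[[month]][key] <- t0 + 1L
    }
  }
  memory
}

## remembered R_m for each site of a route; unknown (site, month) -> 0
remembered_resources <- function(route, memory) {
  out <- numeric(12L)
  for (m in 1:12) {
    v <- memory$res[[m]][as.character(route[m])]
    if (!is.na(v)) out[m] <- v
  }
  out
}

remembered_tsetse <- function(route, memory) {
  out <- numeric(12L)
  for (m in 1:12) {
    v <- memory$tse[[m]][as.character(route[m])]
    if (!is.na(v)) out[m] <- v
  }
  out
}

## -- agent -------------------------------------------------------------

#' Initialize an agent
#'
#' A new agent is settled on one uniformly drawn site: its initial route is
#' twelve repetitions of that site and its memory is empty.  Uses the
#' current RNG stream.
#'
#' @param grid A [grid_spec()].
#' @param id Integer agent id.
#' @return An object of class `nomad` with fields `id`, `route` (integer
#'   vector of 12 linear site indices, one per calendar month) and `memory`.
#' @export
init_nomad <- function(grid, id = 1L) {
  home <- sample.int(n_sites(grid), 1L)
  structure(list(id = as.integer(id), route = rep(home, 12L),
                 memory = new_memory()),
            class = "nomad")
}

#' @export
print.nomad <- function(x, ...) {
  cat(sprintf("<nomad %d> route over %d distinct sites, %d remembered (site, month) pairs\n",
              x$id, length(unique(x$route)),
              sum(lengths(x$memory$n))))
  invisible(x)
}

#' Assess the grazing conditions around a site
#'
#' The arithmetic mean of a resource field over the grazing window of
#' radius `graze_range_km` around `site`.  The field passed in already
#' reflects whatever sharing, carrying-capacity or access adjustments the
#' caller wants assessed.
#'
#' @param field Numeric `height x width` matrix for one month.
#' @param site Site as `(row, col)` or linear index.
#' @param graze_range_km Radius in km.
#' @param grid A [grid_spec()].
#' @param metric Window metric, `"chebyshev"` or `"euclidean"`.
#' @return Mean resource value.
#' @export
assess_area <- function(field, site, graze_range_km, grid,
                        metric = "chebyshev") {
  nb <- neighborhood(site, graze_range_km, grid)
  if (metric == "euclidean" && graze_range_km > 0) {
    rc <- as_rc(site, grid)
    nrc <- site_rc(nb, grid)
    d2 <- (nrc[, 1] - rc[1])^2 + (nrc[, 2] - rc[2])^2
    nb <- nb[d2 * grid$pixel_km^2 <= graze_range_km^2 + 1e-9]
  }
  mean(field[nb])
}

#' Possibly scout a remote site
#'
#' With probability `scouting_frequency` the agent dispatches a scout: one
#' site is drawn uniformly among on-grid sites within `scouting_range_km`
#' (Euclidean) of the current grazing site, its surroundings are assessed
#' with [assess_area()] on the supplied availability field, and the result
#' is recorded in memory under the current month.  Scouts observe
#' availability; they do not consume, share, or count against carrying
#' capacity.
#'
#' @param nomad A `nomad`.
#' @param current_site The agent's camping site this month.
#' @param month Calendar month 1..12.
#' @param field Availability field for the month (post-access, post-CC,
#'   pre-sharing).
#' @param params A [nomad_params()].
#' @param grid A [grid_spec()].
#' @param tsetse A [tsetse_map()] or `NULL`; when given, the scout also
#'   draws a Bernoulli encounter at the scouted site.
#' @param offsets Optional precomputed [disc_offsets()] for the scouting
#'   range (a per-run cache; recomputed when missing).
#' @return List with the updated `nomad` and `site` (linear index of the
#'   scouted site, or `NULL` when no scout went out).
#' @export
maybe_scout <- function(nomad, current_site, month, field, params, grid,
                        tsetse = NULL, offsets = NULL) {
  if (params$scouting_frequency <= 0 ||
      stats::runif(1) >= params$scouting_frequency)
    return(list(nomad = nomad, site = NULL))
  if (is.null(offsets))
    offsets <- disc_offsets(params$scouting_range_km, grid$pixel_km)
  rc <- as_rc(current_site, grid)
  target <- sample_disc_site(rc, offsets, grid)
  value <- assess_area(field, target, params$graze_range_km, grid,
                       params$graze_metric)
  hit <- if (!is.null(tsetse)) as.integer(stats::runif(1) < tsetse$p[target])
  nomad$memory <- record_observation(nomad$memory, target, month, value,
                                     tsetse_hit = hit)
  list(nomad = nomad, site = target)
}

#' Movement cost between two adjacent route sites
#'
#' Step mode (the default): cost 0 up to `move_range_km`, a flat `penalty`
#' beyond it — the threshold rule that discourages physically unrealistic
#' routes.  Linear mode: `linear_slope` per km of distance.
#'
#' @param a,b Sites as `(row, col)` or linear indices.
#' @param params A [nomad_params()].
#' @param grid A [grid_spec()].
#' @return Cost (same units as the potential).
#' @export
movement_cost <- function(a, b, params, grid) {
  ra <- as_rc(a, grid); rb <- as_rc(b, grid)
  d <- if (params$move_metric == "chebyshev")
    max(abs(ra - rb)) * grid$pixel_km
  else sqrt(sum((ra - rb)^2)) * grid$pixel_km
  if (params$cost_mode == "linear") params$linear_slope * d
  else if (d <= params$move_range_km + 1e-9) 0 else params$penalty
}

#' Potential of a candidate route
#'
#' The score minimized by route adaptation:
#' `H = alpha * ( -sum_m R_m + sum_m C(m, m+1) + delta * sum_m T_m ) + beta`
#' over the cyclic 12-month route (month 13 = month 1).  `R_m` is the
#' remembered time-mean availability at the month-m site (0 when the agent
#' has no record), `C` the movement cost of each step, and the `T_m`
#' tsetse-frequency term enters only when `disruption_effect > 0`.
#'
#' @param route Integer vector of 12 linear site indices.
#' @param memory A `nomad_memory`.
#' @param params A [nomad_params()].
#' @param grid A [grid_spec()].
#' @return Scalar potential H.
#' @export
route_potential <- function(route, memory, params, grid) {
  r_sum <- sum(remembered_resources(route, memory))
  nxt <- c(route[-1L], route[1L])
  c_sum <- 0
  for (m in 1:12)
    c_sum <- c_sum + movement_cost(route[m], nxt[m], params, grid)
  inner <- -r_sum + c_sum
  if (params$disruption_effect > 0)
    inner <- inner +
      params$disruption_effect * sum(remembered_tsetse(route, memory))
  params$alpha * inner + params$beta
}

#' Annealing noise level
#'
#' The softmax temperature of route selection depends on the current
#' route's potential: `noise_min` when H <= 0, `noise_max` when H >= 1,
#' linear in between — agents on good routes explore little, agents on poor
#' routes explore a lot.
#'
#' @param h_current Potential of the current route.
#' @param params A [nomad_params()].
#' @return Noise level E in `[noise_min, noise_max]`.
#' @export
noise_level <- function(h_current, params) {
  params$noise_min + min(max(h_current, 0), 1) *
    (params$noise_max - params$noise_min)
}

#' Generate candidate routes for a route update
#'
#' Returns `n_alternatives` routes: the first is the agent's current route;
#' each other candidate assigns to month m a site drawn uniformly from the
#' sites the agent has visited or scouted in month m, falling back to the
#' current route's month-m site when the agent has no record for that month.
#' Uses the current RNG stream.
#'
#' @param nomad A `nomad`.
#' @param params A [nomad_params()].
#' @return List of `n_alternatives` routes (integer vectors of length 12).
#' @export
generate_alternatives <- function(nomad, params) {
  known <- lapply(1:12, function(m)
    as.integer(names(nomad$memory$res[[m]])))
  alts <- vector("list", params$n_alternatives)
  alts[[1L]] <- nomad$route
  for (i in seq_len(params$n_alternatives - 1L) + 1L) {
    r <- integer(12L)
    for (m in 1:12) {
      pool <- known[[m]]
      r[m] <- if (length(pool) == 0L) nomad$route[m]
      else pool[sample.int(length(pool), 1L)]
    }
    alts[[i]] <- r
  }
  alts
}

#' Stochastic route selection
#'
#' Softmax choice over candidate routes: with potentials `H_i` and noise
#' `E = noise_level(H_1)` (the current route's potential), route i is
#' adopted with probability `exp(-H_i/E) / sum_j exp(-H_j/E)`.  Computed
#' with a min-H shift so that potential gaps up to ~1e8 noise units stay
#' finite.  Uses the current RNG stream.
#'
#' @param routes List of candidate routes; `routes[[1]]` must be the
#'   current route.
#' @param memory The agent's `nomad_memory`.
#' @param params A [nomad_params()].
#' @param grid A [grid_spec()].
#' @return List with the chosen `route`, the index `chosen`, the vector of
#'   potentials `h` and selection probabilities `prob`.
#' @export
select_route <- function(routes, memory, params, grid) {
  h <- vapply(routes, route_potential, numeric(1), memory = memory,
              params = params, grid = grid)
  e <- noise_level(h[1L], params)
  z <- exp(-(h - min(h)) / e)
  prob <- z / sum(z)
  chosen <- sample.int(length(routes), 1L, prob = prob)
  list(route = routes[[chosen]], chosen = chosen, h = h, prob = prob)
}
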