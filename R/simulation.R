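## RNG stream plumbing: one L'Ecuyer-CMRG substream per agent plus one
## environment-level stream, all derived from the run seed, so that the
## order in which agents are processed can never change a result.

put_rng <- function(s) assign(".Random.seed", s, envir = globalenv())
get_rng <- function() get(".Random.seed", envir = globalenv())

make_streams <- function(seed, n_agents) {
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get_rng()
  agents <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    s <- parallel::nextRNGStream(s)
    agents[[i]] <- s
  }
  env <- parallel::nextRNGStream(s)
  list(agents = agents, env = env)
}

## restore the caller's RNG state (kind included) when a run finishes
preserve_rng <- function() {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get_rng()
  kind <- RNGkind()
  function() {
    RNGkind(kind[1], kind[2], kind[3])
    if (has) put_rng(old)
  }
}

#' Run configuration
#'
#' Bundles everything one simulation run needs: agent parameters, the
#' environment (either pre-built objects or a [synth_params()] to generate
#' them from), run length, burn-in, an optional cropland access schedule,
#' an optional tsetse map, and the seed.  Statistics are accumulated only
#' for years after `burn_in_years` (the published experiments sample years
#' 1001-20000 of 20000-year runs; scaled configurations override this).
#'
#' @param params A [nomad_params()].
#' @param env Either a list with elements `stack` (adjusted
#'   [resource_stack()]), and optionally `landcover` and `tsetse`, or a
#'   [synth_params()] from which [generate_environment()] builds them.
#' @param n_years Total simulated years (> `burn_in_years`).
#' @param burn_in_years Years discarded before sampling (default 1000).
#' @param schedule An [access_schedule()] or `NULL`.
#' @param use_tsetse Logical; expose the environment's tsetse map to the
#'   agents (encounters are drawn and remembered; the potential weighs them
#'   by `params$disruption_effect`).
#' @param seed Integer run seed.
#' @param record_gains Keep the full per-agent monthly gain log.
#' @param intensity_counting `"site"` counts an agent on its camping site
#'   only (the published intensity maps); `"neighborhood"` spreads the
#'   count over its grazing window.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params, env, n_years, burn_in_years = 1000L,
                       schedule = NULL, use_tsetse = FALSE, seed = 1L,
                       record_gains = TRUE,
                       intensity_counting = c("site", "neighborhood")) {
  stopifnot(inherits(params, "nomad_params"))
  if (n_years <= burn_in_years)
    stop("n_years (", n_years, ") must exceed burn_in_years (",
         burn_in_years, ")")
  if (!is.null(schedule) && !inherits(schedule, "access_schedule"))
    stop("schedule must be an access_schedule or NULL")
  structure(list(params = params, env = env,
                 n_years = as.integer(n_years),
                 burn_in_years = as.integer(burn_in_years),
                 schedule = schedule, use_tsetse = isTRUE(use_tsetse),
                 seed = as.integer(seed),
                 record_gains = isTRUE(record_gains),
                 intensity_counting = match.arg(intensity_counting)),
            class = "run_config")
}

resolve_env <- function(env) {
  if (inherits(env, "synth_params")) env <- generate_environment(env)
  if (!inherits(env$stack, "resource_stack"))
    stop("env$stack must be a resource_stack")
  if (!isTRUE(attr(env$stack, "adjusted")))
    stop("env$stack must be preprocessed (adjusted) before simulation")
  env
}

#' Fresh simulation state
#'
#' @param grid A [grid_spec()].
#' @param n_agents Number of agents.
#' @return An object of class `sim_state` holding the 0-based `sim_year`,
#'   the yearly site-visit ledger (carrying capacity bookkeeping), current
#'   agent placements, per-agent visited-site sets, and RNG streams (filled
#'   in by [run_simulation()]).
#' @export
new_sim_state <- function(grid, n_agents) {
  structure(list(sim_year = 0L,
                 ledger = matrix(0L, grid$height, grid$width),
                 placements = rep(NA_integer_, n_agents),
                 visited = rep(list(integer(0)), n_agents),
                 streams = NULL),
            class = "sim_state")
}

#' Advance the simulation by one month
#'
#' One month of the ROUTE cycle: every agent moves to its route's site for
#' `month`; new visits are charged to the yearly site ledger; sites whose
#' ledger already exceeded the carrying capacity before this month serve 0;
#' the month's availability field (after access schedule and
#' capacity-zeroing) is shared among agents with overlapping grazing
#' windows — divided equally in `"share"` mode, or awarded whole to one
#' uniformly chosen overlapping agent per site in `"lottery"` mode; each
#' agent's gain is the mean of its shared window; agents record the
#' *pre-sharing* availability of their site (and a Bernoulli tsetse
#' encounter when a tsetse map is active) and may scout.  Sites pushed over
#' capacity by this month's visits serve 0 from next month on.
#'
#' @param state A `sim_state`.
#' @param agents List of `nomad` agents.
#' @param env List with `stack`, optional `landcover`, optional `tsetse`.
#' @param month Calendar month 1..12.
#' @param params A [nomad_params()].
#' @param schedule An [access_schedule()] or `NULL`.
#' @param scout_offsets Optional precomputed [disc_offsets()] cache.
#' @return List with updated `state`, `agents`, and numeric `gains` (one
#'   per agent).
#' @export
step_month <- function(state, agents, env, month, params, schedule = NULL,
                       scout_offsets = NULL) {
  grid <- env$stack$grid
  n <- length(agents)
  tsetse <- if (!is.null(env$tsetse)) env$tsetse

  ## (1) move along routes; (2) capacity mask from the ledger as it stood
  ## before this month, then charge this month's visits
  sites <- vapply(agents, function(a) a$route[month], integer(1))
  over <- state$ledger > params$carrying_capacity
  for (i in seq_len(n)) {
    s <- sites[i]
    if (params$cc_counting == "agent_months") {
      state$ledger[s] <- state$ledger[s] + 1L
    } else if (!(s %in% state$visited[[i]])) {
      state$ledger[s] <- state$ledger[s] + 1L
      state$visited[[i]] <- c(state$visited[[i]], s)
    }
  }
  state$placements <- sites

  ## (3) month's availability field: cyclic layer, access schedule,
  ## capacity zeroing
  field <- env_month_field(env$stack, state$sim_year, month,
                           schedule = schedule,
                           landcover = env$landcover)
  field[over] <- 0

  ## (4) sharing: divisor = number of agents whose grazing windows cover a
  ## site; gains are window means of the shared field
  nbs <- lapply(sites, function(s)
    graze_window(s, params, grid))
  gains <- numeric(n)
  if (params$share_mode == "share" || n == 1L) {
    div <- matrix(0L, grid$height, grid$width)
    for (nb in nbs) div[nb] <- div[nb] + 1L
    for (i in seq_len(n))
      gains[i] <- mean(field[nbs[[i]]] / div[nbs[[i]]])
  } else {
    ## lottery: each covered site is awarded whole to one overlapping agent
    site_v <- unlist(nbs, use.names = FALSE)
    agent_v <- rep(seq_len(n), lengths(nbs))
    put_rng(state$streams$env)
    owner <- vapply(split(agent_v, site_v), function(a)
      if (length(a) == 1L) a else a[sample.int(length(a), 1L)],
      integer(1))
    state$streams$env <- get_rng()
    own_sites <- as.integer(names(owner))
    for (i in seq_len(n)) {
      nb <- nbs[[i]]
      mine <- own_sites[owner == i]
      gains[i] <- sum(field[intersect(nb, mine)]) / length(nb)
    }
  }

  ## (5) information gathering: pre-sharing availability, tsetse
  ## encounters, (6) scouting -- all on the agent's own RNG stream
  for (i in seq_len(n)) {
    obs <- assess_area(field, sites[i], params$graze_range_km, grid,
                       params$graze_metric)
    put_rng(state$streams$agents[[i]])
    hit <- if (!is.null(tsetse))
      as.integer(stats::runif(1) < tsetse$p[sites[i]])
    agents[[i]]$memory <- record_observation(agents[[i]]$memory, sites[i],
                                             month, obs, tsetse_hit = hit)
    sc <- maybe_scout(agents[[i]], sites[i], month, field, params, grid,
                      tsetse = tsetse, offsets = scout_offsets)
    agents[[i]] <- sc$nomad
    state$streams$agents[[i]] <- get_rng()
  }
  list(state = state, agents = agents, gains = gains)
}

graze_window <- function(site, params, grid) {
  nb <- neighborhood(site, params$graze_range_km, grid)
  if (params$graze_metric == "euclidean" && params$graze_range_km > 0) {
    rc <- as_rc(site, grid)
    nrc <- site_rc(nb, grid)
    d2 <- (nrc[, 1] - rc[1])^2 + (nrc[, 2] - rc[2])^2
    nb <- nb[d2 * grid$pixel_km^2 <= params$graze_range_km^2 + 1e-9]
  }
  nb
}

#' Close a simulated year
#'
#' At the configured interval each agent independently builds its candidate
#' routes ([generate_alternatives()]) and adopts one by the softmax rule
#' ([select_route()]), on its own RNG stream; the visit ledger resets and
#' the simulation year advances.  Because updates use only the agent's own
#' memory and stream, the processing order cannot affect the outcome.
#'
#' @param state A `sim_state` at the end of a year.
#' @param agents List of `nomad` agents.
#' @param params A [nomad_params()].
#' @param grid A [grid_spec()].
#' @param order Agent processing order (for order-invariance checks).
#' @return List with updated `state` and `agents`.
#' @export
step_year <- function(state, agents, params, grid,
                      order = seq_along(agents)) {
  if (state$sim_year %% params$update_interval_years == 0L) {
    for (i in order) {
      put_rng(state$streams$agents[[i]])
      alts <- generate_alternatives(agents[[i]], params)
      sel <- select_route(alts, agents[[i]]$memory, params, grid)
      agents[[i]]$route <- sel$route
      state$streams$agents[[i]] <- get_rng()
    }
  }
  state$ledger[] <- 0L
  state$visited <- rep(list(integer(0)), length(agents))
  state$sim_year <- state$sim_year + 1L
  list(state = state, agents = agents)
}

#' Run one simulation
#'
#' The full ROUTE cycle: agents are settled at random, then live
#' `n_years` years of twelve [step_month()]s each followed by a
#' [step_year()] route update.  Land-use intensity counts, gain logs and
#' route ranges are accumulated for years after `burn_in_years` only.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return An object of class `run_result` with fields `intensity` (an
#'   [intensity_map()]: mean grazing agents per site per month per year),
#'   `mean_resource_per_agent_month`, `interannual_sd`, `route_ranges`
#'   (final per-agent), `route_range_yearly` (per recorded year, mean over
#'   agents), `gain_log` (recorded months x agents, when
#'   `record_gains`), `yearly_mean_gain`, `n_recorded_years`, and the
#'   `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  env <- resolve_env(config$env)
  grid <- env$stack$grid
  params <- config$params
  if (!config$use_tsetse) env$tsetse <- NULL
  if (config$use_tsetse && is.null(env$tsetse))
    stop("use_tsetse = TRUE but the environment has no tsetse map")
  restore <- preserve_rng()
  on.exit(restore())

  n <- params$population
  state <- new_sim_state(grid, n)
  state$streams <- make_streams(config$seed, n)
  agents <- vector("list", n)
  for (i in seq_len(n)) {
    put_rng(state$streams$agents[[i]])
    agents[[i]] <- init_nomad(grid, id = i)
    state$streams$agents[[i]] <- get_rng()
  }
  scout_offsets <- disc_offsets(params$scouting_range_km, grid$pixel_km)

  n_rec <- config$n_years - config$burn_in_years
  counts <- array(0, dim = c(grid$height, grid$width, 12L))
  gain_log <- if (config$record_gains)
    matrix(NA_real_, n_rec * 12L, n)
  yearly_gain <- numeric(n_rec)
  yearly_range <- numeric(n_rec)
  rec_row <- 0L

  for (y in seq_len(config$n_years) - 1L) {
    recording <- y >= config$burn_in_years
    year_gains <- 0
    for (m in 1:12) {
      sm <- step_month(state, agents, env, m, params,
                       schedule = config$schedule,
                       scout_offsets = scout_offsets)
      state <- sm$state
      agents <- sm$agents
      if (recording) {
        if (config$intensity_counting == "site") {
          for (s in state$placements)
            counts[, , m][s] <- counts[, , m][s] + 1
        } else {
          for (s in state$placements) {
            nb <- graze_window(s, params, grid)
            counts[, , m][nb] <- counts[, , m][nb] + 1
          }
        }
        rec_row <- rec_row + 1L
        if (config$record_gains) gain_log[rec_row, ] <- sm$gains
        year_gains <- year_gains + mean(sm$gains)
      }
    }
    if (recording) {
      k <- y - config$burn_in_years + 1L
      yearly_gain[k] <- year_gains / 12
      yearly_range[k] <- mean(vapply(agents, function(a)
        route_range(a$route, grid), numeric(1)))
    }
    sy <- step_year(state, agents, params, grid)
    state <- sy$state
    agents <- sy$agents
  }

  structure(list(
    intensity = intensity_map(counts / n_rec, grid),
    mean_resource_per_agent_month = mean(yearly_gain),
    interannual_sd = if (n_rec > 1) stats::sd(yearly_gain) else 0,
    route_ranges = vapply(agents, function(a) route_range(a$route, grid),
                          numeric(1)),
    route_range_yearly = yearly_range,
    gain_log = if (config$record_gains) gain_log,
    yearly_mean_gain = yearly_gain,
    n_recorded_years = n_rec,
    agents = agents,
    config = config), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_result> %d agents, %d years (%d recorded)\n",
    "  mean resource / agent / month: %.3f (interannual SD %.3f)\n",
    "  mean final route range: %.1f km\n"),
    x$config$params$population, x$config$n_years, x$n_recorded_years,
    x$mean_resource_per_agent_month, x$interannual_sd,
    mean(x$route_ranges)))
  invisible(x)
}

#' Run an ensemble of independent simulations
#'
#' Repeats [run_simulation()] with seeds `base_seed`, `base_seed + 1`, ...
#' and aggregates: mean and SD across runs of the mean obtained resources,
#' and the pooled intensity map (mean across runs).
#'
#' @param config A [run_config()]; its `seed` is ignored.
#' @param n_runs Number of runs (>= 1).
#' @param base_seed First seed.
#' @return List with `runs` (list of `run_result`), `mean_resource`,
#'   `across_run_sd`, and `intensity` (pooled [intensity_map()]).
#' @export
run_ensemble <- function(config, n_runs, base_seed = config$seed) {
  stopifnot(n_runs >= 1)
  env <- resolve_env(config$env)   # generate synthetic env once, share it
  config$env <- env
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + k - 1L)
    runs[[k]] <- run_simulation(cfg)
  }
  means <- vapply(runs, `[[`, numeric(1), "mean_resource_per_agent_month")
  pooled <- Reduce(`+`, lapply(runs, function(r) r$intensity$values)) /
    n_runs
  list(runs = runs,
       mean_resource = mean(means),
       across_run_sd = if (n_runs > 1) stats::sd(means) else 0,
       intensity = intensity_map(pooled, env$stack$grid))
}

#' Non-adaptive random-route baseline
#'
#' The benchmark the adaptive agents are judged against: each of `n_agents`
#' agents follows, for one year and with no interaction, sharing, carrying
#' capacity or adaptation, a uniformly random cyclic route whose every step
#' (including the December-to-January wrap) respects `move_range_km`.
#' Routes are built by sequential sampling from the step-feasible disc of
#' the previous site, restarting when the wrap step cannot be closed.
#' Agents cycle through the stack's years in turn.
#'
#' @param env List with `stack` and optional `landcover` (or a
#'   [synth_params()]).
#' @param n_agents Number of independent baseline agents.
#' @param params A [nomad_params()] (uses `move_range_km`,
#'   `graze_range_km`, `graze_metric`).
#' @param schedule An [access_schedule()] or `NULL`.
#' @param seed Integer seed.
#' @return List with `mean` and `sd` of the per-agent mean monthly gains,
#'   and the per-agent means `agent_means`.
#' @export
random_route_baseline <- function(env, n_agents, params, schedule = NULL,
                                  seed = 1L) {
  env <- resolve_env(env)
  grid <- env$stack$grid
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  offsets <- disc_offsets(params$move_range_km, grid$pixel_km)
  n_years_env <- env$stack$n_months / 12L
  agent_means <- numeric(n_agents)
  for (k in seq_len(n_agents)) {
    route <- sample_random_route(grid, params$move_range_km, offsets)
    sim_year <- (k - 1L) %% n_years_env
    g <- 0
    for (m in 1:12) {
      field <- env_month_field(env$stack, sim_year, m, schedule = schedule,
                               landcover = env$landcover)
      g <- g + assess_area(field, route[m], params$graze_range_km, grid,
                           params$graze_metric)
    }
    agent_means[k] <- g / 12
  }
  list(mean = mean(agent_means),
       sd = if (n_agents > 1) stats::sd(agent_means) else 0,
       agent_means = agent_means)
}

#' Sample one step-feasible random cyclic route
#'
#' @param grid A [grid_spec()].
#' @param move_range_km Step bound in km (Euclidean).
#' @param offsets Optional precomputed [disc_offsets()].
#' @return Integer vector of 12 linear site indices.
#' @export
sample_random_route <- function(grid, move_range_km,
                                offsets = disc_offsets(move_range_km,
                                                       grid$pixel_km)) {
  repeat {
    route <- integer(12L)
    route[1L] <- sample.int(n_sites(grid), 1L)
    rc1 <- as.numeric(site_rc(route[1L], grid)[1L, ])
    ok <- TRUE
    for (m in 2:12) {
      prev <- as.numeric(site_rc(route[m - 1L], grid)[1L, ])
      if (m < 12L) {
        route[m] <- sample_disc_site(prev, offsets, grid)
      } else {
        ## last step must also close the cycle back to month 1
        cand_r <- prev[1] + offsets[, 1L]
        cand_c <- prev[2] + offsets[, 2L]
        keep <- cand_r >= 1 & cand_r <= grid$height &
          cand_c >= 1 & cand_c <= grid$width &
          ((cand_r - rc1[1])^2 + (cand_c - rc1[2])^2) * grid$pixel_km^2 <=
            move_range_km^2 + 1e-9
        if (!any(keep)) { ok <- FALSE; break }
        pick <- which(keep)[sample.int(sum(keep), 1L)]
        route[12L] <- site_index(cand_r[pick], cand_c[pick], grid)
      }
    }
    if (ok) return(route)
  }
}
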