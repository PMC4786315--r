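test_that("co-located agents share resources equally", {
  s <- colocated_setup(3, value = 0.6, graze_range_km = 0)
  out <- step_month(s$state, s$agents, s$env, 1, s$params)
  expect_equal(out$gains, rep(0.2, 3))

  # a lone agent keeps the whole site
  s1 <- colocated_setup(1, value = 0.6, graze_range_km = 0)
  out1 <- step_month(s1$state, s1$agents, s1$env, 1, s1$params)
  expect_equal(out1$gains, 0.6)

  # agents remember availability (pre-sharing), not their realized share
  expect_equal(unname(out$agents[[1]]$memory$res[[1]]["6"]), 0.6)
})

test_that("exceeding carrying capacity zeroes a site for the rest of the year", {
  s <- colocated_setup(2, value = 0.6, graze_range_km = 0)
  s$params$carrying_capacity <- 1L
  jan <- step_month(s$state, s$agents, s$env, 1, s$params)
  expect_equal(jan$gains, rep(0.3, 2))  # breaching month still yields
  feb <- step_month(jan$state, jan$agents, s$env, 2, s$params)
  expect_equal(feb$gains, rep(0, 2))    # ledger 2 > capacity 1
  expect_equal(unname(feb$agents[[1]]$memory$res[[2]]["6"]), 0)

  # after the yearly reset the site serves again
  sy <- step_year(feb$state, feb$agents, s$params, s$grid)
  mar <- step_month(sy$state, sy$agents, s$env, 3, s$params)
  expect_equal(mar$gains, rep(0.3, 2))
})

test_that("unique-agent capacity counting ignores repeat visits", {
  s <- colocated_setup(1, value = 0.6, graze_range_km = 0)
  s$params$carrying_capacity <- 1L
  s$params$cc_counting <- "unique_agents"
  st <- s$state; ag <- s$agents
  for (m in 1:6) {
    out <- step_month(st, ag, s$env, m, s$params)
    st <- out$state; ag <- out$agents
    expect_equal(out$gains, 0.6)  # one camper never breaches capacity 1
  }
})

test_that("lottery mode equals share mode for a single agent and conserves totals", {
  env <- small_synth_env(16, 16, n_years = 1, seed = 8)
  for (mode in c("share", "lottery")) {
    p <- nomad_params(population = 1, share_mode = mode)
    cfg <- run_config(p, env, n_years = 12, burn_in_years = 2, seed = 21)
    assign(paste0("r_", mode), run_simulation(cfg))
  }
  expect_identical(r_share$gain_log, r_lottery$gain_log)
  expect_identical(r_share$intensity$values, r_lottery$intensity$values)

  # two co-located agents, graze range 0: the site's whole value is paid
  # out in both modes (split v/2 + v/2, or v + 0)
  for (mode in c("share", "lottery")) {
    s <- colocated_setup(2, value = 0.6, graze_range_km = 0)
    s$params$share_mode <- mode
    out <- step_month(s$state, s$agents, s$env, 1, s$params)
    expect_equal(sum(out$gains), 0.6)
    if (mode == "lottery") expect_setequal(out$gains, c(0, 0.6))
  }
})

test_that("route updates are invariant to agent processing order", {
  env <- small_synth_env(16, 16, n_years = 1, seed = 12)
  p <- nomad_params(population = 4, scouting_range_km = 10)
  state <- new_sim_state(env$stack$grid, 4)
  state$streams <- nomadsim:::make_streams(33, 4)
  agents <- vector("list", 4)
  for (i in 1:4) {
    nomadsim:::put_rng(state$streams$agents[[i]])
    agents[[i]] <- init_nomad(env$stack$grid, i)
    state$streams$agents[[i]] <- nomadsim:::get_rng()
  }
  for (m in 1:12) {
    out <- step_month(state, agents, env, m, p)
    state <- out$state; agents <- out$agents
  }
  fwd <- step_year(state, agents, p, env$stack$grid, order = 1:4)
  rev <- step_year(state, agents, p, env$stack$grid, order = 4:1)
  for (i in 1:4)
    expect_identical(fwd$agents[[i]]$route, rev$agents[[i]]$route)
  expect_identical(fwd$state$streams, rev$state$streams)
})

test_that("identical seeds reproduce a run bit for bit", {
  env <- small_synth_env(16, 16, n_years = 1, seed = 2)
  cfg <- run_config(nomad_params(population = 3), env, n_years = 20,
                    burn_in_years = 4, seed = 77)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$gain_log, r2$gain_log)
  expect_identical(r1$intensity$values, r2$intensity$values)
  expect_identical(r1$route_ranges, r2$route_ranges)

  r3 <- run_simulation(run_config(nomad_params(population = 3), env,
                                  n_years = 20, burn_in_years = 4,
                                  seed = 78))
  expect_false(identical(r1$gain_log, r3$gain_log))
})

test_that("a lone agent on a constant uniform world banks the uniform value", {
  g <- grid_spec(6, 6)
  env <- list(stack = uniform_stack(0.37, g))
  p <- nomad_params(population = 1, carrying_capacity = 100L)
  cfg <- run_config(p, env, n_years = 10, burn_in_years = 0, seed = 5)
  r <- run_simulation(cfg)
  expect_equal(r$mean_resource_per_agent_month, 0.37)
  expect_equal(r$interannual_sd, 0)
})

test_that("run configuration inconsistencies fail before any compute", {
  env <- list(stack = uniform_stack(0.5, grid_spec(4, 4)))
  expect_error(run_config(nomad_params(), env, n_years = 10,
                          burn_in_years = 10), "must exceed")
  raw <- uniform_stack(0.5, grid_spec(4, 4), adjusted = FALSE)
  cfg <- run_config(nomad_params(population = 1), list(stack = raw),
                    n_years = 2, burn_in_years = 0)
  expect_error(run_simulation(cfg), "adjusted")
  cfg2 <- run_config(nomad_params(population = 1), env, n_years = 2,
                     burn_in_years = 0, use_tsetse = TRUE)
  expect_error(run_simulation(cfg2), "tsetse")
})

test_that("random baseline routes respect the step bound, including the wrap", {
  g <- grid_spec(40, 40)
  set.seed(6)
  for (i in 1:30) {
    route <- sample_random_route(g, move_range_km = 8)
    rc <- nomadsim:::site_rc(route, g)
    steps <- sqrt(diff(rc[c(1:12, 1), 1])^2 + diff(rc[c(1:12, 1), 2])^2)
    expect_true(all(steps <= 8 + 1e-9))
  }
})

test_that("random-route baseline: constant world and zero-mobility closed forms", {
  g <- grid_spec(10, 10)
  env <- list(stack = uniform_stack(0.42, g))
  p <- nomad_params(graze_range_km = 0)
  b <- random_route_baseline(env, 50, p, seed = 3)
  expect_equal(b$mean, 0.42)
  expect_equal(b$sd, 0)

  # move range 0: the route is 12 copies of one uniform site, so the
  # expected gain is the spatial mean of the site annual means
  env2 <- small_synth_env(12, 12, n_years = 1, seed = 14)
  p0 <- nomad_params(move_range_km = 0, graze_range_km = 0)
  b0 <- random_route_baseline(env2, 3000, p0, seed = 4)
  spatial_mean <- mean(apply(env2$stack$values, 1:2, mean))
  expect_equal(b0$mean, spatial_mean, tolerance = 0.02)
})

test_that("an ensemble of one equals its single run; SDs are non-negative", {
  env <- small_synth_env(16, 16, n_years = 1, seed = 9)
  cfg <- run_config(nomad_params(population = 2), env, n_years = 15,
                    burn_in_years = 3, seed = 50)
  ens <- run_ensemble(cfg, 1, base_seed = 50)
  single <- run_simulation(cfg)
  expect_equal(ens$mean_resource, single$mean_resource_per_agent_month)
  expect_identical(ens$intensity$values, single$intensity$values)
  expect_equal(ens$across_run_sd, 0)

  ens3 <- run_ensemble(cfg, 3, base_seed = 50)
  expect_gte(ens3$across_run_sd, 0)
  expect_identical(ens3$runs[[1]]$gain_log, single$gain_log)
})

test_that("tsetse encounters are remembered and the disruption term avoids them", {
  g <- grid_spec(10, 10)
  # two equally green halves; flies saturate the southern half
  env <- list(stack = uniform_stack(0.5, g),
              tsetse = tsetse_map(rbind(matrix(0, 5, 10),
                                        matrix(1, 5, 10)), g))
  p <- nomad_params(population = 2, disruption_effect = 1,
                    carrying_capacity = 1000L, scouting_range_km = 5)
  cfg <- run_config(p, env, n_years = 40, burn_in_years = 20, seed = 13,
                    use_tsetse = TRUE)
  r <- run_simulation(cfg)
  # with delta = 1 a remembered fly site carries a potential surcharge
  # equal to a full resource unit; adapted routes should sit in the north
  rows <- nomadsim:::site_rc(unlist(lapply(r$agents, `[[`, "route")), g)[, 1]
  expect_lt(mean(rows > 5), 0.25)
  # and encounter frequencies near 1 are on record for southern sites
  tse <- unlist(lapply(r$agents, function(a) unlist(a$memory$tse)))
  expect_true(length(tse) > 0)
})

test_that("a total cropland exclusion lowers obtained resources", {
  env <- small_synth_env(20, 20, n_years = 1, seed = 18)
  p <- nomad_params(population = 2)
  open <- run_config(p, env, n_years = 30, burn_in_years = 10, seed = 4)
  shut <- run_config(p, env, n_years = 30, burn_in_years = 10, seed = 4,
                     schedule = access_schedule(integer(0)))
  expect_lt(run_simulation(shut)$mean_resource_per_agent_month,
            run_simulation(open)$mean_resource_per_agent_month)
})
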