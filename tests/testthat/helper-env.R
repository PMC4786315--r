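# shared fixture builders: tiny environments constructed in code

uniform_stack <- function(value, grid, n_months = 12L,
                          adjusted = TRUE) {
  resource_stack(array(value, c(grid$height, grid$width, n_months)),
                 grid, adjusted = adjusted)
}

uniform_landcover <- function(grid, class = "grassland") {
  landcover_map(matrix(class, grid$height, grid$width), grid)
}

# three agents camped on one site of value 0.6, graze range 0
colocated_setup <- function(n_agents = 3L, value = 0.6,
                            graze_range_km = 0) {
  g <- grid_spec(4, 4)
  env <- list(stack = uniform_stack(value, g))
  agents <- lapply(seq_len(n_agents), function(i) {
    a <- init_nomad(g, i)
    a$route <- rep(6L, 12L)
    a
  })
  state <- new_sim_state(g, n_agents)
  state$streams <- nomadsim:::make_streams(1L, n_agents)
  params <- nomad_params(population = n_agents,
                         graze_range_km = graze_range_km,
                         scouting_frequency = 0)
  list(state = state, agents = agents, env = env, params = params,
       grid = g)
}

small_synth_env <- function(height = 24, width = 24, n_years = 2,
                            seed = 5) {
  generate_environment(synth_params(grid_spec(height, width),
                                    n_years = n_years, seed = seed))
}

# an agent parked on a chosen site (bypassing the random settling draw)
init_nomad_at <- function(grid, site, id = 1L) {
  structure(list(id = as.integer(id), route = rep(as.integer(site), 12L),
                 memory = new_memory()),
            class = "nomad")
}
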