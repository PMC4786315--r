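test_that("a new agent is settled: repeated route, empty memory", {
  g <- grid_spec(10, 10)
  set.seed(3)
  a <- init_nomad(g, id = 1)
  expect_length(a$route, 12)
  expect_length(unique(a$route), 1)
  expect_equal(route_range(a$route, g), 0)
  expect_equal(sum(lengths(a$memory$n)), 0)

  set.seed(3)
  b <- init_nomad(g, id = 2)
  expect_identical(a$route, b$route)   # reproducible placement
})

test_that("memory stores the running time-mean of observations", {
  mem <- new_memory()
  mem <- record_observation(mem, 5L, 3, 0.4)
  expect_equal(unname(mem$res[[3]]["5"]), 0.4)
  expect_equal(unname(mem$n[[3]]["5"]), 1L)
  mem <- record_observation(mem, 5L, 3, 0.6)
  expect_equal(unname(mem$res[[3]]["5"]), 0.5)
  mem <- record_observation(mem, 5L, 3, 0.2)
  expect_equal(unname(mem$res[[3]]["5"]), 0.4)  # mean(0.4, 0.6, 0.2)
  # other (site, month) cells untouched
  expect_length(mem$res[[4]], 0)
})

test_that("memory time-mean equals a replay oracle on random logs", {
  set.seed(7)
  for (rep in 1:40) {
    mem <- new_memory()
    log <- data.frame(site = sample(1:6, 30, replace = TRUE),
                      month = sample(1:4, 30, replace = TRUE),
                      value = runif(30),
                      hit = rbinom(30, 1, 0.3))
    for (i in 1:30)
      mem <- record_observation(mem, log$site[i], log$month[i],
                                log$value[i], tsetse_hit = log$hit[i])
    for (m in unique(log$month)) {
      sub <- log[log$month == m, ]
      for (s in unique(sub$site)) {
        expect_equal(unname(mem$res[[m]][as.character(s)]),
                     mean(sub$value[sub$site == s]))
        expect_equal(unname(mem$tse[[m]][as.character(s)]),
                     mean(sub$hit[sub$site == s]))
      }
    }
  }
})

test_that("area assessment is the window mean", {
  g <- grid_spec(5, 5)
  expect_equal(assess_area(matrix(0.42, 5, 5), c(3, 3), 4, g), 0.42)
  f <- matrix(0, 5, 5); f[3, 3] <- 1
  expect_equal(assess_area(f, c(3, 3), 1, g), 1 / 9)
  expect_equal(assess_area(f, c(3, 3), 0, g), 1)
  f2 <- matrix(runif(25), 5, 5)
  expect_equal(assess_area(f2, c(2, 4), 0, g), f2[2, 4])
})

test_that("movement cost: step threshold with penalty, or linear in distance", {
  g <- grid_spec(200, 5)
  p <- nomad_params(move_range_km = 100, penalty = 100)
  expect_equal(movement_cost(c(1, 1), c(51, 1), p, g), 0)     # 50 km
  expect_equal(movement_cost(c(1, 1), c(101, 1), p, g), 0)    # exactly 100
  expect_equal(movement_cost(c(1, 1), c(121, 1), p, g), 100)  # 120 km
  lin <- nomad_params(cost_mode = "linear", linear_slope = 0.001)
  expect_equal(movement_cost(c(1, 1), c(51, 1), lin, g), 0.05)
})

test_that("route potential reproduces the hand-computed battery", {
  g <- grid_spec(130, 5)
  p <- nomad_params()   # alpha 2, beta 1, move range 100, penalty 100
  site <- nomadsim:::site_index(60, 3, g)

  # no knowledge, no movement: H = beta = 1
  expect_equal(route_potential(rep(site, 12), new_memory(), p, g), 1.0,
               tolerance = 1e-12)

  # R_m = 0.3 every month, stationary: H = 2 * (-3.6) + 1 = -6.2
  mem <- new_memory()
  for (m in 1:12) mem <- record_observation(mem, site, m, 0.3)
  expect_equal(route_potential(rep(site, 12), mem, p, g), -6.2,
               tolerance = 1e-12)

  # same resources but one 120-km step: H = 2 * (-3.6 + 100) + 1 = 193.8
  rows <- c(1, 15, 29, 43, 57, 71, 85, 99, 113, 121, 121, 121)
  route <- nomadsim:::site_index(rows, 1, g)
  mem2 <- new_memory()
  for (m in 1:12) mem2 <- record_observation(mem2, route[m], m, 0.3)
  expect_equal(route_potential(route, mem2, p, g), 193.8,
               tolerance = 1e-12)
})

test_that("potential is monotone: better remembered resources lower H", {
  g <- grid_spec(10, 10)
  p <- nomad_params()
  set.seed(11)
  route <- sample.int(100, 12, replace = TRUE)
  mem <- new_memory()
  for (m in 1:12) mem <- record_observation(mem, route[m], m, runif(1))
  h0 <- route_potential(route, mem, p, g)
  mem2 <- record_observation(mem, route[4], 4, 1)   # pulls the mean up
  expect_lte(route_potential(route, mem2, p, g), h0)
})

test_that("annealing noise is linear between its clamped endpoints", {
  p <- nomad_params()
  expect_identical(noise_level(0, p), 1e-6)
  expect_identical(noise_level(1, p), 1e-2)
  expect_equal(noise_level(0.5, p), 5.0005e-3)
  expect_identical(noise_level(-3, p), 1e-6)   # clamped below
  expect_identical(noise_level(42, p), 1e-2)   # clamped above
})

test_that("candidate routes recombine remembered sites, current route first", {
  g <- grid_spec(10, 10)
  a <- structure(list(id = 1L, route = rep(55L, 12), memory = new_memory()),
                 class = "nomad")
  # an agent that never moved or scouted: all alternatives collapse
  alts <- generate_alternatives(a, nomad_params(n_alternatives = 4))
  expect_length(alts, 4)
  for (r in alts) expect_identical(r, a$route)

  # remembered sites per month bound the construction
  set.seed(5)
  for (m in 1:12)
    for (s in sample.int(100, 3))
      a$memory <- record_observation(a$memory, s, m, runif(1))
  p2 <- nomad_params(n_alternatives = 2)
  alts2 <- generate_alternatives(a, p2)
  expect_identical(alts2[[1]], a$route)
  known <- lapply(1:12, function(m) names(a$memory$res[[m]]))
  for (m in 1:12)
    expect_true(as.character(alts2[[2]][m]) %in% known[[m]] ||
                  alts2[[2]][m] == a$route[m])
})

test_that("softmax selection: closed form, normalization, shift invariance", {
  g <- grid_spec(10, 10)
  # fixed temperature so the closed form is exact: E = 0.01
  p <- nomad_params(noise_min = 0.01, noise_max = 0.01)
  e <- 0.01
  mem <- new_memory()
  r1_val <- 0.02                      # H1 = 1 - 24 * 0.02 = 0.52
  for (m in 1:12) mem <- record_observation(mem, 1L, m, r1_val)
  h1 <- 1 - 24 * r1_val
  h2 <- h1 + e * log(2)               # worse by E ln 2 -> probs (2/3, 1/3)
  r2_val <- (1 - h2) / 24
  for (m in 1:12) mem <- record_observation(mem, 2L, m, r2_val)

  set.seed(1)
  sel <- select_route(list(rep(1L, 12), rep(2L, 12)), mem, p, g)
  expect_equal(sel$h, c(h1, h2))
  expect_equal(sum(sel$prob), 1)
  expect_equal(sel$prob, c(2 / 3, 1 / 3), tolerance = 1e-9)

  # adding a constant to all H (via beta) leaves the probabilities alone
  p_shift <- nomad_params(noise_min = 0.01, noise_max = 0.01, beta = 7)
  sel2 <- select_route(list(rep(1L, 12), rep(2L, 12)), mem, p_shift, g)
  expect_equal(sel2$h - sel$h, c(6, 6))
  expect_equal(sel2$prob, sel$prob, tolerance = 1e-12)
})

test_that("at minimal noise the best route is effectively certain", {
  g <- grid_spec(10, 10)
  p <- nomad_params()
  mem <- new_memory()
  for (m in 1:12) mem <- record_observation(mem, 1L, m, 0.25)
  # current route: H = 2*(-3) + 1 = -5 -> E = noise_min = 1e-6;
  # the unknown-site alternative has H = 1, a gap >> 0.01
  routes <- list(rep(1L, 12), rep(2L, 12))
  set.seed(2)
  picks <- replicate(1e4, select_route(routes, mem, p, g)$chosen)
  expect_true(all(picks == 1L))
})

test_that("scouting frequency behaves binomially and records what it sees", {
  g <- grid_spec(8, 8)
  field <- matrix(runif(64), 8, 8)
  a <- init_nomad_at(g, 30L)

  p0 <- nomad_params(scouting_frequency = 0)
  set.seed(1)
  expect_null(maybe_scout(a, 30L, 1, field, p0, g)$site)

  # frequency 1, range 0: always scouts its own site
  p1 <- nomad_params(scouting_frequency = 1, scouting_range_km = 0,
                     graze_range_km = 0)
  out <- maybe_scout(a, 30L, 2, field, p1, g)
  expect_equal(out$site, 30L)
  expect_equal(unname(out$nomad$memory$res[[2]]["30"]), field[30])

  # binomial count at frequency 0.2 over 1e4 months
  p2 <- nomad_params(scouting_frequency = 0.2, scouting_range_km = 3)
  set.seed(9)
  n_scout <- sum(vapply(1:1e4, function(i)
    !is.null(maybe_scout(a, 30L, 1, field, p2, g)$site), logical(1)))
  expect_lt(abs(n_scout - 2000), 3 * sqrt(1e4 * 0.2 * 0.8))

  # scouted sites respect the Euclidean range
  p3 <- nomad_params(scouting_frequency = 1, scouting_range_km = 2)
  set.seed(10)
  sites <- vapply(1:200, function(i)
    maybe_scout(a, 30L, 1, field, p3, g)$site, integer(1))
  d <- vapply(sites, function(s) site_distance_km(s, 30L, g), numeric(1))
  expect_true(all(d <= 2 + 1e-9))
})
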