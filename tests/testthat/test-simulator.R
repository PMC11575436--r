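test_that("step probabilities are a normalized softmax with exclusions", {
  lp <- rep(0, 10)
  p <- step_probabilities(lp)
  expect_equal(p, rep(0.1, 10))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # one candidate at habitat 1 with beta = ln 3: 3x the odds of the others
  lp2 <- c(log(3), rep(0, 9))
  p2 <- step_probabilities(lp2)
  expect_equal(p2[1] / p2[2], 3, tolerance = 1e-12)
  expect_equal(sum(p2), 1, tolerance = 1e-12)

  p3 <- step_probabilities(rnorm(20), exclude = c(rep(TRUE, 5), rep(FALSE, 15)))
  expect_equal(p3[1:5], rep(0, 5))
  expect_equal(sum(p3), 1, tolerance = 1e-12)

  expect_error(step_probabilities(c(0, 0), exclude = c(TRUE, TRUE)), "zero")
})

test_that("simulations are bitwise reproducible from the seed", {
  cfg <- flat_sim_config(n_steps = 100, seed = 12)
  s1 <- simulate_track(cfg, start = c(0, 0))
  s2 <- simulate_track(cfg, start = c(0, 0))
  expect_identical(s1$track$x, s2$track$x)
  expect_identical(s1$track$y, s2$track$y)
  expect_identical(s1$diagnostics, s2$diagnostics)
})

test_that("simulator TSLV diagnostics equal a replayed lookup oracle", {
  spec <- grid_spec(0, 0, 2000, 30, 30)
  cfg <- sim_config(kernel = kernel_params(2, 700, 0.5),
                    beta_f = c(tslv = 0.018, tslv_sq = -5e-5),
                    memory_mode = "tslv", n_steps = 300,
                    n_candidates = 50, gridspec = spec, seed = 8)
  sim <- simulate_track(cfg, start = c(30000, 30000))
  trk <- sim$track
  st <- tslv_state(spec, default_tslv = 365, clock = 0)
  replay <- numeric(nrow(trk) - 1)
  for (i in seq_len(nrow(trk) - 1)) {
    st <- tslv_advance(st, trk$t[i], trk$x[i], trk$y[i])
    replay[i] <- tslv_lookup(st, trk$x[i + 1], trk$y[i + 1],
                             t_query = trk$t[i + 1])
  }
  expect_identical(sim$diagnostics$tslv, replay)
})

test_that("walkers never leave the domain", {
  spec <- grid_spec(0, 0, 500, 10, 10)  # tight 5 km box
  cfg <- sim_config(kernel = kernel_params(2, 400, 0.5),
                    memory_mode = "none", n_steps = 300,
                    n_candidates = 100, gridspec = spec, seed = 2)
  sim <- simulate_track(cfg, start = c(2500, 2500))
  expect_false(anyNA(cell_of(spec, sim$track$x, sim$track$y)))
  expect_gt(sum(sim$diagnostics$n_excluded), 0)  # boundary was active
})

test_that("null-model simulation reproduces the movement kernel", {
  cfg <- flat_sim_config(n_steps = 2000, seed = 5, kappa = 0.8,
                         shape = 2, scale = 300)
  sim <- simulate_track(cfg, start = c(0, 0))
  st <- steps_from_track(sim$track)
  expect_gt(ks.test(st$sl, function(q) pgamma(q, 2, scale = 300))$p.value,
            0.01)
  expect_gt(ks.test(st$ta[-1], function(q) pvonmises(q, 0.8))$p.value, 0.01)
})

test_that("kernel-sampled choice sets approximate the continuous normalizer", {
  # the expected habitat value of the chosen endpoint, estimated by
  # averaging softmax-weighted candidate values over repeated draws,
  # stabilizes as the choice-set size doubles
  spec <- grid_spec(0, 0, 100, 120, 120)
  hab <- gaussian_random_field(spec, 800, 1, seed = 40)
  kp <- kernel_params(2, 150, 0.5)
  expected_hab <- function(M, seed) {
    withr::with_seed(seed, {
      vals <- replicate(300, {
        sl <- rgamma(M, 2, scale = 150)
        ta <- rvonmises(M, 0.5)
        b <- wrap_angle(0.3 + ta)
        x <- 6000 + sl * cos(b); y <- 6000 + sl * sin(b)
        v <- raster_value_at(hab, x, y, outside = 0)
        sum(step_probabilities(0.8 * v) * v)
      })
      mean(vals)
    })
  }
  e200 <- expected_hab(200, 1)
  e400 <- expected_hab(400, 2)
  expect_lt(abs(e200 - e400), 0.02)
})

test_that("migration memory biases movement toward remembered structures", {
  spec <- grid_spec(0, 0, 500, 120, 120)
  path <- data.frame(x = seq(10000, 50000, length.out = 30),
                     y = seq(10000, 50000, length.out = 30))
  mk <- function(bf, s) sim_config(
    kernel = kernel_params(2, 400, 0.5), beta_f = bf,
    memory_mode = "migration", n_steps = 300, n_candidates = 100,
    fix_interval = 1 / 24, gridspec = spec, seed = s
  )
  # strong attraction to the previous path keeps the walker closer to it
  closer <- 0
  for (s in 1:10) {
    sim_a <- simulate_migration(mk(c(dist_path = -3), s), prev_path = path,
                                start = c(12000, 8000))
    sim_0 <- simulate_migration(mk(c(dist_path = 0), s), prev_path = path,
                                start = c(12000, 8000))
    d_a <- mean(min_distance_to_path(sim_a$track$x, sim_a$track$y, path))
    d_0 <- mean(min_distance_to_path(sim_0$track$x, sim_0$track$y, path))
    closer <- closer + (d_a < d_0)
  }
  expect_gte(closer, 8)

  # heading concentration toward the centroid grows with the bias coefficient
  centroid <- c(50000, 50000)
  spread <- vapply(c(0, 1, 3), function(b) {
    sim <- simulate_migration(mk(c(dir_bias = b), 99), centroid = centroid,
                              start = c(15000, 15000))
    st <- steps_from_track(sim$track)
    to_c <- atan2(centroid[2] - st$y1, centroid[1] - st$x1)
    1 - abs(mean(exp(1i * (st$bearing - to_c))))  # circular variance
  }, numeric(1))
  expect_true(all(diff(spread) < 0))

  # zero coefficients reduce to the plain kernel walk, draw for draw
  z <- simulate_migration(mk(c(dist_path = 0), 77), prev_path = path,
                          start = c(30000, 30000))
  cfg_none <- sim_config(kernel = kernel_params(2, 400, 0.5),
                         memory_mode = "none", n_steps = 300,
                         n_candidates = 100, fix_interval = 1 / 24,
                         gridspec = spec, seed = 77)
  n <- simulate_track(cfg_none, start = c(30000, 30000))
  expect_identical(z$track$x, n$track$x)
  expect_identical(z$track$y, n$track$y)
})

test_that("attraction to familiar space shrinks the home range", {
  spec <- grid_spec(0, 0, 100, 120, 120)
  mk <- function(beta, s) sim_config(
    kernel = kernel_params(2, 150, 0.5),
    beta_f = if (beta != 0) c(od = beta) else c(),
    memory_mode = "od_window", n_steps = 250, n_candidates = 100,
    fix_interval = 1 / 12, window = Inf, bandwidth = 200,
    gridspec = spec, seed = s
  )
  smaller <- 0
  for (s in 1:5) {
    a <- simulate_track(mk(4, s), start = c(6000, 6000))
    z <- simulate_track(mk(0, s), start = c(6000, 6000))
    smaller <- smaller + (mcp_area(a$track$x, a$track$y) <
                            mcp_area(z$track$x, z$track$y))
  }
  expect_gte(smaller, 4)
})

test_that("simulate -> covariates -> fit closes the loop on a bear scenario", {
  scn <- make_scenario("bear_like", seed = 14)
  scn$config$n_steps <- 1200L
  sim <- simulate_track(scn$config, landscape = scn$landscape,
                        start = scn$start)
  strata <- build_strata(sim$track, scn$config$kernel, n_avail = 20,
                         seed = 140) |>
    clip_strata_to_domain(scn$config$gridspec) |>
    add_habitat_covariate(scn$landscape$habitat, outside = 0) |>
    add_tslv_covariate(sim$track, scn$config$gridspec)
  fit <- fit_clogit(build_design(strata, terms = c("habitat", "tslv"),
                                 quadratic = "tslv"))
  truth <- c(habitat = 0.5, tslv = 0.018, tslv_sq = -5e-5)
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta - truth) <= 3 * fit$se))
})
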