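spec9 <- grid_spec(0, 0, res = 100, n_rows = 9, n_cols = 9)

test_that("occurrence distributions are normalized point processes", {
  # single fix at a cell center with tiny bandwidth: mass concentrates there
  trk <- as_track(data.frame(id = "a", t = 0, x = 450, y = 450))
  od <- occurrence_distribution(trk, c(-1, 1), spec9, bandwidth = 5)
  expect_equal(sum(od$values), 1, tolerance = 1e-12)
  expect_gte(od$values[cell_of(spec9, 450, 450)], 0.99)

  # normalization holds for arbitrary input
  trk2 <- make_rw_track(30, seed = 5, step_sd = 80, cx = 450, cy = 450)
  od2 <- occurrence_distribution(trk2, c(0, 100), spec9, bandwidth = 120)
  expect_equal(sum(od2$values), 1, tolerance = 1e-12)

  # mirror symmetry: reflecting the input reflects the OD
  tr <- as_track(data.frame(id = "a", t = c(0, 1),
                            x = c(300, 600), y = c(450, 450)))
  od3 <- occurrence_distribution(tr, c(-1, 2), spec9, bandwidth = 100)
  m <- matrix(od3$values, 9, 9)
  expect_equal(m, m[, 9:1], tolerance = 1e-12)  # reflect about x = 450

  expect_error(occurrence_distribution(trk, c(5, 6), spec9, 10), "window")
  expect_error(occurrence_distribution(trk, c(-1, 1), spec9, 0), "bandwidth")
})

test_that("contour indicators mark the smallest high-density set", {
  # uniform OD over k cells: ceil(level * k) cells are set
  k <- 81
  od <- raster_grid(spec9, rep(1 / k, k))
  ind <- od_contour_indicator(od, 0.95)
  expect_equal(sum(ind$values), ceiling(0.95 * k))
  expect_true(all(ind$values %in% c(0, 1)))

  # point mass: one cell at any level
  pm <- raster_grid(spec9, c(1, rep(0, k - 1)))
  expect_equal(sum(od_contour_indicator(pm, 0.5)$values), 1)
  expect_equal(sum(od_contour_indicator(pm, 1)$values), 1)

  # level 1 covers exactly the positive support
  half <- c(rep(2 / k, floor(k / 2)), rep(0, ceiling(k / 2)))
  ind1 <- od_contour_indicator(raster_grid(spec9, half / sum(half)), 1)
  expect_equal(ind1$values > 0, half > 0)

  expect_error(od_contour_indicator(od, 0), "level")
  expect_error(od_contour_indicator(od, 1.2), "level")
})

test_that("stratified ODs respect windows and diel phase", {
  # all history within the last 3 days: long == short
  trk <- make_rw_track(20, seed = 3, step_sd = 60, cx = 450, cy = 450,
                       fix_interval = 0.1)
  big <- grid_spec(-2000, -2000, 200, 45, 45)
  ods <- stratified_ods(trk, t_now = 2.5, spec = big, bandwidth = 150)
  expect_equal(ods$long_all$values, ods$short_all$values, tolerance = 1e-12)

  # day history in one corner, night history in another
  day_t <- 10 / 24 + 0:4            # hour 10
  night_t <- 22 / 24 + 0:4          # hour 22
  tr <- as_track(data.frame(
    id = "a", t = c(day_t, night_t),
    x = c(rep(500, 5), rep(4500, 5)),
    y = c(rep(500, 5), rep(4500, 5))
  ))
  noonish <- 5 + 12 / 24
  odsd <- stratified_ods(tr, t_now = noonish, spec = big, bandwidth = 100,
                         short_window = 10)
  expect_equal(odsd$phase, "day")
  # diel-matched memory concentrates on the daytime corner
  daycell <- cell_of(big, 500, 500)
  expect_gt(odsd$long_diel$values[daycell], 0.1)
  expect_lt(odsd$long_diel$values[cell_of(big, 4500, 4500)], 1e-6)

  # no nocturnal history: diel strata unavailable, others produced
  dayonly <- as_track(data.frame(id = "a", t = day_t,
                                 x = rep(500, 5), y = rep(500, 5)))
  odsn <- stratified_ods(dayonly, t_now = 5 + 23 / 24, spec = big,
                         bandwidth = 100, short_window = 10)
  expect_equal(odsn$phase, "night")
  expect_null(odsn$long_diel)
  expect_null(odsn$short_diel)
  expect_false(is.null(odsn$long_all))
})

test_that("TSLV state machine tracks visits at cell level", {
  st <- tslv_state(spec9, default_tslv = 365)
  st <- tslv_advance(st, 10, 50, 50)
  expect_equal(tslv_lookup(st, 50, 50, t_query = 12), 2)
  # two points in the same cell share the memory
  expect_equal(tslv_lookup(st, c(10, 90), c(10, 90), 12), c(2, 2))
  # revisit resets
  st <- tslv_advance(st, 12, 60, 60)
  expect_equal(tslv_lookup(st, 50, 50, t_query = 12), 0)
  # never-visited cells report the default at any query time
  expect_equal(tslv_lookup(st, 850, 850, t_query = 1000), 365)

  expect_error(tslv_advance(st, 11, 50, 50), "regression")
  expect_error(tslv_advance(st, 20, -50, 50), "outside")
  expect_error(tslv_lookup(st, 5000, 50, 20), "outside")

  # five visits to distinct cells at t = 0..4, queried at t = 10
  st2 <- tslv_state(spec9)
  xs <- 50 + 100 * (0:4)
  for (i in 0:4) st2 <- tslv_advance(st2, i, xs[i + 1], 50)
  expect_equal(tslv_lookup(st2, xs, rep(50, 5), t_query = 10), c(10, 9, 8, 7, 6))
})

test_that("TSLV along a track matches an event-log oracle", {
  trk <- make_rw_track(60, seed = 9, step_sd = 150, cx = 450, cy = 450,
                       fix_interval = 0.25)
  spec <- grid_spec(-5000, -5000, 300, 40, 40)
  st <- tslv_state(spec)
  visits <- list()  # per-cell visit log, the independent oracle
  for (i in seq_len(nrow(trk))) {
    cell <- as.character(cell_of(spec, trk$x[i], trk$y[i]))
    # before this visit, TSLV = time since the cell's last logged visit
    expected <- if (is.null(visits[[cell]])) 365 else trk$t[i] - visits[[cell]]
    expect_equal(tslv_lookup(st, trk$x[i], trk$y[i], t_query = trk$t[i]),
                 expected)
    st <- tslv_advance(st, trk$t[i], trk$x[i], trk$y[i])
    visits[[cell]] <- trk$t[i]
  }
})

test_that("burn-in primes the memory and returns the remainder", {
  trk <- make_rw_track(2 * 365, seed = 4, fix_interval = 1, step_sd = 100,
                       cx = 450, cy = 450)
  spec <- grid_spec(-20000, -20000, 500, 90, 90)
  b0 <- burn_in_initialize(trk, 0, spec)
  expect_equal(sum(!is.na(b0$state$last_visit)), 0)
  expect_equal(nrow(b0$remainder), nrow(trk))

  b1 <- burn_in_initialize(trk, 365, spec)
  expect_equal(max(b1$remainder$t) - min(b1$remainder$t), 364, tolerance = 1)
  expect_true(all(b1$remainder$t >= 365))

  # all burn-in fixes in one cell
  one <- as_track(data.frame(id = "a", t = 0:9, x = rep(450, 10),
                             y = c(rep(450, 5), rep(460, 5))))
  bo <- burn_in_initialize(one, 5, spec9)
  expect_equal(sum(!is.na(bo$state$last_visit)), 1)

  expect_error(burn_in_initialize(one, 100, spec9), "shorter")
})

test_that("distance-to-path matches exhaustive segment enumeration", {
  path <- data.frame(x = c(0, 2, 2), y = c(0, 0, 3))
  expect_equal(min_distance_to_path(1, 0, path), 0)
  expect_equal(min_distance_to_path(0, 1, data.frame(x = c(0, 2), y = c(0, 0))), 1)
  expect_error(min_distance_to_path(0, 0, data.frame(x = numeric(), y = numeric())),
               "vertex")

  withr::with_seed(10, {
    rp <- data.frame(x = cumsum(rnorm(50, 0, 100)), y = cumsum(rnorm(50, 0, 100)))
    qx <- rnorm(200, 0, 500); qy <- rnorm(200, 0, 500)
  })
  expect_lt(max(abs(min_distance_to_path(qx, qy, rp) -
                      brute_force_min_dist(qx, qy, rp))), 1e-9)

  # rigid-motion invariance (rotation + translation applied jointly)
  ang <- 0.77; dx <- 123; dy <- -321
  rot <- function(x, y) list(x = cos(ang) * x - sin(ang) * y + dx,
                             y = sin(ang) * x + cos(ang) * y + dy)
  q2 <- rot(qx, qy); p2 <- rot(rp$x, rp$y)
  expect_lt(max(abs(
    min_distance_to_path(q2$x, q2$y, data.frame(x = p2$x, y = p2$y)) -
      min_distance_to_path(qx, qy, rp))), 1e-9)
})

test_that("directional bias is the cosine toward the remembered centroid", {
  expect_equal(directional_bias(c(0, 0), 5, 0, c(10, 0)), 1)
  expect_equal(directional_bias(c(0, 0), -3, 0, c(10, 0)), -1)
  expect_lt(abs(directional_bias(c(0, 0), 0, 2, c(10, 0))), 1e-12)
  # magnitude-invariant
  expect_equal(directional_bias(c(0, 0), 1, 1, c(5, 2)),
               directional_bias(c(0, 0), 100, 100, c(5, 2)))
  expect_error(directional_bias(c(0, 0), 0, 0, c(1, 1)), "Zero-length")
  expect_error(directional_bias(c(0, 0), 1, 1, c(0, 0)), "centroid")
})
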