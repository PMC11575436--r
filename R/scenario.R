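#' Seeded stationary Gaussian random field
#'
#' White noise smoothed with an isotropic Gaussian filter by FFT on a torus,
#' then standardized to mean 0 and sample variance `sill`. The correlation
#' range is the Gaussian filter's length scale in meters. Deterministic
#' given the seed.
#'
#' @param spec A [grid_spec()].
#' @param correlation_range Filter length scale in meters, > 0.
#' @param sill Marginal variance; 0 yields the constant zero field.
#' @param seed Integer seed.
#' @return A [raster_grid()].
#' @export
gaussian_random_field <- function(spec, correlation_range, sill, seed) {
  if (correlation_range <= 0) abort("`correlation_range` must be > 0.")
  if (sill < 0) abort("`sill` must be >= 0.")
  if (sill == 0) return(raster_grid(spec, rep(0, n_cells(spec))))
  nr <- spec$n_rows; nc <- spec$n_cols
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(nr * nc), nr, nc)
    # periodic Gaussian filter in cell units
    s <- correlation_range / spec$res
    fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
    fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
    gr <- exp(-2 * (pi * s * fr)^2)
    gc <- exp(-2 * (pi * s * fc)^2)
    filt <- outer(gr, gc)
    sm <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (nr * nc)
    sm <- sm - mean(sm)
    sm <- sm / sd(sm) * sqrt(sill)
    raster_grid(spec, sm)
  })
}

#' Build a named synthetic study scenario
#'
#' Each scenario bundles a seeded landscape, true simulation parameters and
#' any previous-season structures, emulating the data structure of one of
#' four archetypal study designs:
#'
#' * `crane_like` — a multi-season resident: a previous summer's track
#'   yields a 95% occurrence-contour indicator used as a binary familiarity
#'   covariate for the current season.
#' * `hog_like` — a diel forager with a short-term (3-day) occurrence
#'   memory expressed as a continuously updated density covariate.
#' * `deer_like` — a two-range migrant carrying last year's migration path
#'   and the previous seasonal-range centroid.
#' * `bear_like` — a multi-year revisitor with a time-since-last-visit
#'   memory on 2 km cells, 365-day never-visited default, and
#'   linear-plus-quadratic selection peaking at an intermediate return time
#'   (180 days).
#'
#' Scenarios regenerate bit-exactly from `(name, seed)`.
#'
#' @param name One of `"crane_like"`, `"hog_like"`, `"deer_like"`,
#'   `"bear_like"`.
#' @param seed Integer seed.
#' @return An object of class `scenario`: `name`, `seed`, `landscape`
#'   (named list of rasters), `config` (a [sim_config()] holding the true
#'   parameters), plus scenario-specific elements (`indicator`,
#'   `prev_track`, `prev_path`, `centroid`, `start`).
#' @export
make_scenario <- function(name = c("crane_like", "hog_like", "deer_like",
                                   "bear_like"), seed = 1) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  out <- switch(name,
    bear_like = scenario_bear(seed),
    hog_like = scenario_hog(seed),
    crane_like = scenario_crane(seed),
    deer_like = scenario_deer(seed)
  )
  out$name <- name
  out$seed <- seed
  structure(out, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (seed %d): %d-step %s simulation\n",
              x$name, x$seed, x$config$n_steps, x$config$memory_mode))
  invisible(x)
}

# Multi-year TSLV revisitor: 2 km cells, 365-day default TSLV, 4-h fixes,
# selection over TSLV peaking at 180 days.
scenario_bear <- function(seed) {
  spec <- grid_spec(0, 0, res = 2000, n_rows = 30, n_cols = 30)
  habitat <- gaussian_random_field(spec, correlation_range = 5000, sill = 1,
                                  seed = seed + 1000L)
  vertex <- 180
  b_quad <- -5e-5
  b_lin <- -2 * b_quad * vertex
  config <- sim_config(
    kernel = kernel_params(shape = 2, scale = 700, kappa = 0.5),
    beta_w = c(habitat = 0.5),
    beta_f = c(tslv = b_lin, tslv_sq = b_quad),
    memory_mode = "tslv",
    n_steps = 3000, n_candidates = 200, fix_interval = 1 / 6,
    gridspec = spec, default_tslv = 365, seed = seed
  )
  list(landscape = list(habitat = habitat), config = config,
       start = c(30000, 30000), tslv_vertex = vertex)
}

# Diel forager: 3-day working-memory window, density-form OD covariate.
scenario_hog <- function(seed) {
  spec <- grid_spec(0, 0, res = 100, n_rows = 120, n_cols = 120)
  habitat <- gaussian_random_field(spec, correlation_range = 800, sill = 1,
                                  seed = seed + 2000L)
  config <- sim_config(
    kernel = kernel_params(shape = 2, scale = 150, kappa = 0.5),
    beta_w = c(habitat = 0.3),
    beta_f = c(od = 1.5),
    memory_mode = "od_window",
    n_steps = 1500, n_candidates = 200, fix_interval = 1 / 12,
    window = 3, bandwidth = 200, gridspec = spec, seed = seed
  )
  list(landscape = list(habitat = habitat), config = config,
       start = c(6000, 6000), day_hours = c(6, 18))
}

# Multi-season resident: previous summer's track -> 95% OD contour
# indicator as a binary familiarity covariate for the current season.
scenario_crane <- function(seed) {
  spec <- grid_spec(0, 0, res = 250, n_rows = 96, n_cols = 96)
  habitat <- gaussian_random_field(spec, correlation_range = 1500, sill = 1,
                                  seed = seed + 3000L)
  prev_config <- sim_config(
    kernel = kernel_params(shape = 2, scale = 200, kappa = 0.5),
    beta_w = c(habitat = 0.5),
    memory_mode = "none",
    n_steps = 1200, n_candidates = 100, fix_interval = 1 / 24,
    gridspec = spec, seed = seed + 1L
  )
  prev <- simulate_track(prev_config, landscape = list(habitat = habitat),
                         start = c(12000, 12000))
  prev_od <- occurrence_distribution(
    prev$track, window = c(0, max(prev$track$t) + 1), spec,
    bandwidth = 300
  )
  indicator <- od_contour_indicator(prev_od, level = 0.95)
  config <- sim_config(
    kernel = kernel_params(shape = 2, scale = 200, kappa = 0.5),
    beta_w = c(habitat = 0.5),
    beta_f = c(od_indicator = 1),
    memory_mode = "od_window",
    n_steps = 1200, n_candidates = 100, fix_interval = 1 / 24,
    gridspec = spec, seed = seed
  )
  list(landscape = list(habitat = habitat), config = config,
       prev_track = prev$track, prev_od = prev_od, indicator = indicator,
       start = c(12000, 12000))
}

# Two-range migrant: last year's migration path plus the previous
# seasonal-range centroid as navigation memory.
scenario_deer <- function(seed) {
  spec <- grid_spec(0, 0, res = 500, n_rows = 120, n_cols = 120)
  habitat <- gaussian_random_field(spec, correlation_range = 3000, sill = 1,
                                  seed = seed + 4000L)
  # previous year's path: south winter range to north summer range
  py <- seq(5000, 55000, length.out = 60)
  px <- withr::with_seed(seed + 5L,
    30000 + 4000 * sin(py / 8000) + cumsum(rnorm(60, 0, 300)))
  prev_path <- data.frame(x = px, y = py)
  centroid_winter <- c(prev_path$x[1], prev_path$y[1])
  centroid_summer <- c(prev_path$x[60], prev_path$y[60])
  config <- sim_config(
    kernel = kernel_params(shape = 2, scale = 400, kappa = 0.5),
    beta_w = c(habitat = 0.3),
    beta_f = c(dist_path = -0.8, dir_bias = 1.5),
    memory_mode = "migration",
    n_steps = 800, n_candidates = 200, fix_interval = 1 / 24,
    gridspec = spec, seed = seed
  )
  list(landscape = list(habitat = habitat), config = config,
       prev_path = prev_path, centroid = centroid_summer,
       centroid_winter = centroid_winter,
       start = c(prev_path$x[1], prev_path$y[1] + 1000))
}

#' Run a scenario's simulation
#'
#' Convenience wrapper dispatching on the scenario's memory mode and
#' passing through its previous-season structures.
#'
#' @param scn A [make_scenario()] object.
#' @param keep_candidates Keep the candidate log.
#' @return A `sim_track` list.
#' @export
run_scenario <- function(scn, keep_candidates = FALSE) {
  simulate_track(
    scn$config, landscape = scn$landscape, start = scn$start,
    indicator = scn$indicator, prev_path = scn$prev_path,
    centroid = scn$centroid, keep_candidates = keep_candidates
  )
}

#' Write a scenario fixture directory
#'
#' Emits the standard plain-text artifacts: landscape rasters as ESRI
#' ASCII grids, previous tracks/paths as CSV, and the resolved true
#' parameters as YAML.
#'
#' @param scn A [make_scenario()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scn$landscape)) {
    write_ascii_grid(scn$landscape[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  if (!is.null(scn$indicator)) {
    write_ascii_grid(scn$indicator, file.path(dir, "indicator.asc"))
  }
  if (!is.null(scn$prev_track)) {
    utils::write.csv(scn$prev_track, file.path(dir, "prev_track.csv"),
                     row.names = FALSE)
  }
  if (!is.null(scn$prev_path)) {
    utils::write.csv(scn$prev_path, file.path(dir, "prev_path.csv"),
                     row.names = FALSE)
  }
  cfg <- scn$config
  yaml::write_yaml(list(
    scenario = scn$name, seed = scn$seed,
    kernel = cfg$kernel[c("shape", "scale", "kappa")],
    beta_w = as.list(cfg$beta_w), beta_f = as.list(cfg$beta_f),
    memory_mode = cfg$memory_mode, n_steps = cfg$n_steps,
    n_candidates = cfg$n_candidates, fix_interval = cfg$fix_interval,
    window = cfg$window, bandwidth = cfg$bandwidth,
    default_tslv = cfg$default_tslv, stride = cfg$stride,
    grid = cfg$gridspec[c("x0", "y0", "res", "n_rows", "n_cols")],
    start = scn$start
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
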