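#' Simulation configuration
#'
#' Bundles everything the forward model needs: the selection-free kernel,
#' habitat and familiarity coefficients, the memory mode and its state
#' parameters, and the discretized choice-set size. At each step the walker
#' draws `n_candidates` endpoints from the kernel and picks one with
#' probability proportional to `exp(beta_w' r(s) + beta_f' f(s))`; because
#' candidates are kernel-sampled, the kernel factor of the model is
#' embodied in the proposal and the softmax needs only the selection and
#' familiarity weights.
#'
#' @param kernel A [kernel_params()].
#' @param beta_w Named numeric: habitat coefficients (names must match the
#'   `landscape` list).
#' @param beta_f Named numeric: familiarity coefficients; recognized names
#'   are `od` (density, km^-2), `od_indicator` (binary), `tslv` and
#'   `tslv_sq` (days), `dist_path` (km), `dir_bias` (cosine).
#' @param memory_mode One of `"none"`, `"od_window"`, `"tslv"`,
#'   `"migration"`.
#' @param n_steps Number of steps to simulate.
#' @param n_candidates Choice-set size per step (>= 10; default 200, an
#'   importance-sample approximation of the continuous normalizer).
#' @param fix_interval Time between fixes, decimal days.
#' @param window Occurrence-memory window in days for `od_window`
#'   (`Inf` = all history; default 3).
#' @param bandwidth Gaussian bandwidth (m), required when the `od` density
#'   coefficient is enabled.
#' @param gridspec [grid_spec()] for the TSLV grid and/or the spatial
#'   domain; defaults to the landscape's grid.
#' @param default_tslv Never-visited TSLV sentinel, days.
#' @param stride Recompute the OD memory every `stride` steps, reusing the
#'   previous surface in between (1 = every step).
#' @param seed Integer seed stamped into every simulated artifact.
#' @return A `sim_config` list.
#' @export
sim_config <- function(kernel, beta_w = c(), beta_f = c(),
                       memory_mode = c("none", "od_window", "tslv", "migration"),
                       n_steps = 1000, n_candidates = 200, fix_interval = 1 / 6,
                       window = 3, bandwidth = NULL, gridspec = NULL,
                       default_tslv = 365, stride = 1, seed = 1) {
  memory_mode <- match.arg(memory_mode)
  if (n_candidates < 10) abort("`n_candidates` must be >= 10.")
  known_f <- c("od", "od_indicator", "tslv", "tslv_sq", "dist_path", "dir_bias")
  if (length(beta_f) && !all(names(beta_f) %in% known_f)) {
    abort(sprintf("Unknown familiarity coefficient `%s`.",
                  setdiff(names(beta_f), known_f)[1]))
  }
  mode_terms <- switch(memory_mode,
    none = character(),
    od_window = c("od", "od_indicator"),
    tslv = c("tslv", "tslv_sq"),
    migration = c("dist_path", "dir_bias")
  )
  if (length(beta_f) && !all(names(beta_f) %in% mode_terms)) {
    abort(sprintf("Coefficient `%s` does not belong to memory mode `%s`.",
                  setdiff(names(beta_f), mode_terms)[1], memory_mode))
  }
  if ("od" %in% names(beta_f) && is.null(bandwidth)) {
    abort("The `od` density coefficient needs a `bandwidth`.")
  }
  structure(
    list(kernel = kernel, beta_w = beta_w, beta_f = beta_f,
         memory_mode = memory_mode, n_steps = as.integer(n_steps),
         n_candidates = as.integer(n_candidates),
         fix_interval = fix_interval, window = window, bandwidth = bandwidth,
         gridspec = gridspec, default_tslv = default_tslv,
         stride = as.integer(stride), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Selection probabilities over a candidate set
#'
#' Normalized softmax of the selection-plus-familiarity linear predictor
#' over candidate endpoints. For kernel-sampled candidates the movement
#' kernel is the proposal and needs no explicit factor; for a dense-grid
#' choice set supply `kernel_dens` to multiply the kernel density in
#' explicitly.
#'
#' @param lin_pred Numeric: `beta_w' r(s) + beta_f' f(s)` per candidate.
#' @param exclude Logical: candidates given zero weight (outside the
#'   domain).
#' @param kernel_dens Optional kernel densities for dense-grid candidates.
#' @return A probability vector summing to 1.
#' @export
step_probabilities <- function(lin_pred, exclude = NULL, kernel_dens = NULL) {
  w <- lin_pred - max(lin_pred[is.finite(lin_pred)])
  w <- exp(w)
  if (!is.null(kernel_dens)) w <- w * kernel_dens
  if (!is.null(exclude)) w[exclude] <- 0
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    abort("All candidate weights are zero or non-finite.")
  }
  w / total
}

sim_domain_spec <- function(config, landscape) {
  config$gridspec %||% (if (length(landscape)) landscape[[1]]$spec else
    abort("Need a `gridspec` or a landscape to define the domain."))
}

#' Simulate memory-informed movement
#'
#' Iterates the forward model: draw kernel candidates, weight them by the
#' habitat and familiarity terms, sample the next location, then advance
#' the memory state before the next decision. Occurrence memory at a
#' decision taken at time `t1` is built from the fixes in
#' `[t1 - window, t1)` (strictly past locations); the TSLV map includes
#' the visit at `t1` and candidates are queried at their arrival time.
#' Candidates falling outside the domain get zero weight; if every
#' candidate falls outside, the step is redrawn once before erroring.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param landscape Named list of [raster_grid()] habitat covariates (may
#'   be empty), or a single `raster_grid` taken as `habitat`.
#' @param start Length-2 numeric start position (defaults to the domain
#'   center).
#' @param start_bearing Initial heading, radians.
#' @param indicator Fixed binary [raster_grid()] for the `od_indicator`
#'   familiarity term (e.g. last season's contour).
#' @param prev_path,centroid Migration-memory inputs (see
#'   [simulate_migration()]).
#' @param keep_candidates Record the full candidate log with familiarity
#'   covariates (lets the fitter reuse the simulator's own choice sets).
#' @return A list of class `sim_track`: `track` (a track tibble),
#'   `diagnostics` (per-step tibble with the chosen candidate's familiarity
#'   values), `candidates` (optional log), `config`.
#' @export
simulate_track <- function(config, landscape = list(), start = NULL,
                           start_bearing = 0, indicator = NULL,
                           prev_path = NULL, centroid = NULL,
                           keep_candidates = FALSE) {
  if (inherits(landscape, "raster_grid")) landscape <- list(habitat = landscape)
  if (length(config$beta_w) &&
      !all(names(config$beta_w) %in% names(landscape))) {
    abort("Every `beta_w` name needs a matching landscape raster.")
  }
  if ("od_indicator" %in% names(config$beta_f) && is.null(indicator)) {
    abort("The `od_indicator` coefficient needs an `indicator` raster.")
  }
  if (config$memory_mode == "migration" &&
      is.null(prev_path) && is.null(centroid)) {
    abort("Migration memory needs `prev_path` and/or `centroid`.")
  }
  dom <- sim_domain_spec(config, landscape)
  if (is.null(start)) {
    start <- c(dom$x0 + dom$n_cols * dom$res / 2,
               dom$y0 + dom$n_rows * dom$res / 2)
  }
  if (is.na(cell_of(dom, start[1], start[2]))) {
    abort("Start position lies outside the domain.")
  }
  n <- config$n_steps
  xs <- numeric(n + 1); ys <- numeric(n + 1); ts <- numeric(n + 1)
  xs[1] <- start[1]; ys[1] <- start[2]; ts[1] <- 0
  tslv_mem <- NULL
  if (config$memory_mode == "tslv") {
    tslv_mem <- tslv_advance(
      tslv_state(dom, default_tslv = config$default_tslv, clock = 0),
      0, start[1], start[2])
  }
  bf <- config$beta_f
  od_hist <- NULL  # window subset feeding the occurrence memory
  fam_terms <- switch(config$memory_mode,
    none = character(),
    od_window = intersect(c("od", "od_indicator"), names(bf)),
    tslv = if ("tslv" %in% names(bf) || "tslv_sq" %in% names(bf)) "tslv"
           else character(),
    migration = intersect(c("dist_path", "dir_bias"), names(bf))
  )
  M <- config$n_candidates
  # per-step diagnostics, preallocated
  d_sl <- numeric(n); d_ta <- numeric(n); d_nexcl <- integer(n)
  d_fam <- matrix(NA_real_, n, length(fam_terms),
                  dimnames = list(NULL, fam_terms))
  cand_rows <- if (keep_candidates) vector("list", n) else NULL
  kp <- config$kernel

  lin_pred_for <- function(cx, cy, pos, t_next) {
    lp <- numeric(M)
    fam <- list()
    for (nm in names(config$beta_w)) {
      v <- raster_value_at(landscape[[nm]], cx, cy, outside = 0)
      lp <- lp + config$beta_w[[nm]] * v
    }
    if (config$memory_mode == "od_window") {
      if ("od" %in% names(bf)) {
        od_val <- if (is.null(od_hist)) numeric(M) else {
          kde_intensity(od_hist, cx, cy, config$bandwidth)
        }
        fam$od <- od_val
        lp <- lp + bf[["od"]] * od_val
      }
      if ("od_indicator" %in% names(bf)) {
        ind <- raster_value_at(indicator, cx, cy, outside = 0)
        fam$od_indicator <- ind
        lp <- lp + bf[["od_indicator"]] * ind
      }
    } else if (config$memory_mode == "tslv" && length(fam_terms)) {
      cells <- cell_of(dom, cx, cy)
      inside <- !is.na(cells)
      tslv <- numeric(M)
      if (any(inside)) {
        lv <- tslv_mem$last_visit[cells[inside]]
        tslv[inside] <- ifelse(is.na(lv), tslv_mem$default_tslv,
                               pmax(t_next - lv, 0))
      }
      fam$tslv <- tslv
      if ("tslv" %in% names(bf)) lp <- lp + bf[["tslv"]] * tslv
      if ("tslv_sq" %in% names(bf)) lp <- lp + bf[["tslv_sq"]] * tslv^2
    } else if (config$memory_mode == "migration") {
      if ("dist_path" %in% names(bf)) {
        dp <- min_distance_to_path(cx, cy, prev_path) / 1000
        fam$dist_path <- dp
        lp <- lp + bf[["dist_path"]] * dp
      }
      if ("dir_bias" %in% names(bf)) {
        db <- directional_bias(pos, cx, cy, centroid)
        fam$dir_bias <- db
        lp <- lp + bf[["dir_bias"]] * db
      }
    }
    list(lp = lp, fam = fam)
  }

  withr::with_seed(config$seed, {
    pos <- start; bearing <- start_bearing
    for (i in seq_len(n)) {
      t_next <- i * config$fix_interval
      if (config$memory_mode == "od_window" && "od" %in% names(bf) &&
          (i - 1) %% config$stride == 0) {
        # occurrence memory at a decision taken at ts[i]: strictly past
        # fixes within the window; stride > 1 reuses the last surface
        j <- which(ts[seq_len(i)] < ts[i] & ts[seq_len(i)] >= ts[i] - config$window)
        od_hist <- if (length(j)) data.frame(x = xs[j], y = ys[j]) else NULL
      }
      draw <- function() {
        sl <- rgamma(M, shape = kp$shape, scale = kp$scale)
        ta <- rvonmises(M, kp$kappa)
        brg <- wrap_angle(bearing + ta)
        list(sl = sl, ta = ta, bearing = brg,
             x = pos[1] + sl * cos(brg), y = pos[2] + sl * sin(brg))
      }
      cand <- draw()
      exclude <- is.na(cell_of(dom, cand$x, cand$y))
      if (all(exclude)) {  # one fresh redraw before giving up
        cand <- draw()
        exclude <- is.na(cell_of(dom, cand$x, cand$y))
        if (all(exclude)) {
          abort(sprintf("All candidates left the domain at step %d.", i))
        }
      }
      parts <- lin_pred_for(cand$x, cand$y, pos, t_next)
      prob <- step_probabilities(parts$lp, exclude = exclude)
      pick <- sample.int(M, 1, prob = prob)
      if (keep_candidates) {
        cand_rows[[i]] <- tibble::tibble(
          stratum = i, candidate = seq_len(M),
          used = as.integer(seq_len(M) == pick),
          t1 = ts[i], t2 = t_next,
          x1 = pos[1], y1 = pos[2], x2 = cand$x, y2 = cand$y,
          sl = cand$sl, ta = cand$ta, bearing = cand$bearing,
          excluded = exclude,
          !!!parts$fam
        )
      }
      d_sl[i] <- cand$sl[pick]; d_ta[i] <- cand$ta[pick]
      d_nexcl[i] <- sum(exclude)
      for (ft in fam_terms) d_fam[i, ft] <- parts$fam[[ft]][pick]
      pos <- c(cand$x[pick], cand$y[pick])
      bearing <- cand$bearing[pick]
      xs[i + 1] <- pos[1]; ys[i + 1] <- pos[2]; ts[i + 1] <- t_next
      if (config$memory_mode == "tslv") {
        tslv_mem$clock <- t_next
        tslv_mem$last_visit[cell_of(dom, pos[1], pos[2])] <- t_next
      }
    }
  })
  track <- new_track(tibble::tibble(id = sprintf("sim%d", config$seed),
                                    t = ts, x = xs, y = ys))
  diagnostics <- tibble::tibble(
    step = seq_len(n), t = ts[-1], x = xs[-1], y = ys[-1],
    sl = d_sl, ta = d_ta, n_excluded = d_nexcl
  )
  for (ft in fam_terms) diagnostics[[ft]] <- d_fam[, ft]
  structure(
    list(track = track,
         diagnostics = diagnostics,
         candidates = if (keep_candidates) dplyr::bind_rows(cand_rows),
         config = config),
    class = "sim_track"
  )
}

#' Simulate a memory-guided migration
#'
#' Forward model with the migratory familiarity terms enabled: a negative
#' `dist_path` coefficient pulls the walker toward the previous season's
#' path, a positive `dir_bias` coefficient biases headings toward the
#' remembered range centroid.
#'
#' @inheritParams simulate_track
#' @param prev_path Data frame (`x`, `y`): previous migration path.
#' @param centroid Length-2 numeric: previous seasonal-range centroid.
#' @return A `sim_track` list; its diagnostics record both covariates per
#'   step.
#' @export
simulate_migration <- function(config, prev_path = NULL, centroid = NULL,
                               landscape = list(), start = NULL,
                               start_bearing = 0, keep_candidates = FALSE) {
  if (config$memory_mode != "migration") {
    abort("`config$memory_mode` must be \"migration\".")
  }
  simulate_track(config, landscape = landscape, start = start,
                 start_bearing = start_bearing, prev_path = prev_path,
                 centroid = centroid, keep_candidates = keep_candidates)
}

#' @export
print.sim_track <- function(x, ...) {
  cat(sprintf("<sim_track> %d steps, memory mode '%s', seed %d\n",
              x$config$n_steps, x$config$memory_mode, x$config$seed))
  invisible(x)
}

#' Minimum-convex-polygon home-range area
#'
#' Area of the convex hull of the locations after discarding the
#' `1 - level` fraction farthest from the centroid; the classical quick
#' summary used here to detect emergent site fidelity (smaller ranges under
#' attraction to familiar space).
#'
#' @param x,y Location coordinates, meters.
#' @param level Fraction of locations retained (default 0.95).
#' @return Area in square kilometers.
#' @export
mcp_area <- function(x, y, level = 0.95) {
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  keep <- d <= quantile(d, level)
  hx <- x[keep]; hy <- y[keep]
  h <- grDevices::chull(hx, hy)
  px <- hx[h]; py <- hy[h]
  # shoelace
  area_m2 <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  area_m2 / 1e6
}
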