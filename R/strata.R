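#' Build used/available strata from a track
#'
#' Each movement decision with a defined turning angle becomes one stratum:
#' the observed step endpoint (used) plus `n_avail` matched available
#' endpoints drawn from the selection-free kernel, all sharing the start
#' location and time. The strata table discretizes the availability
#' integral of the step-selection likelihood.
#'
#' @param track A track tibble (>= 3 fixes).
#' @param params A [kernel_params()]; typically [fit_tentative()] output.
#' @param n_avail Available steps per stratum (default 20).
#' @param seed Optional integer for reproducible availability draws.
#' @return A tibble with one row per candidate: `stratum`, `candidate`
#'   (0 = used), `used`, `t1`, `t2`, `x1`, `y1`, `x2`, `y2`, `sl`, `ta`,
#'   `bearing`.
#' @export
build_strata <- function(track, params, n_avail = 20, seed = NULL) {
  steps <- steps_from_track(track)
  usable <- which(!is.na(steps$ta))
  if (length(usable) == 0) abort("No steps with a defined turning angle.")
  S <- length(usable)
  with_seed_or_not(seed, {
    # all availability draws at once; one row block per stratum
    sl_a <- matrix(rgamma(S * n_avail, shape = params$shape,
                          scale = params$scale), S, n_avail)
    ta_a <- matrix(rvonmises(S * n_avail, params$kappa), S, n_avail)
    prev_bearing <- steps$bearing[usable - 1]
    bear_a <- wrap_angle(prev_bearing + ta_a)
    x_a <- steps$x1[usable] + sl_a * cos(bear_a)
    y_a <- steps$y1[usable] + sl_a * sin(bear_a)
    # interleave: used candidate first within each stratum
    k <- n_avail + 1
    row_str <- rep(seq_len(S), each = k)
    is_used <- rep(c(TRUE, rep(FALSE, n_avail)), S)
    pick <- function(used_v, avail_m) {
      out <- numeric(S * k)
      out[is_used] <- used_v
      out[!is_used] <- as.numeric(t(avail_m))
      out
    }
    i <- usable
    tibble::tibble(
      stratum = row_str,
      candidate = rep(0:n_avail, S),
      used = as.integer(is_used),
      t1 = rep(steps$t1[i], each = k), t2 = rep(steps$t2[i], each = k),
      x1 = rep(steps$x1[i], each = k), y1 = rep(steps$y1[i], each = k),
      x2 = pick(steps$x2[i], x_a),
      y2 = pick(steps$y2[i], y_a),
      sl = pick(steps$sl[i], sl_a),
      ta = pick(steps$ta[i], ta_a),
      bearing = pick(steps$bearing[i], bear_a)
    )
  })
}

#' Attach covariates to a strata table
#'
#' Each helper adds one familiarity or habitat column, evaluated at every
#' candidate endpoint, so covariates chain with the pipe:
#' `add_habitat_covariate()` looks up a raster; `add_od_covariate()`
#' evaluates an updating occurrence-distribution memory (continuous density
#' in km^-2, or a binary contour indicator of a fixed previous-season OD);
#' `add_tslv_covariate()` replays the track through a time-since-last-visit
#' grid; `add_migration_covariates()` adds distance-to-previous-path (km)
#' and directional bias toward a remembered centroid.
#'
#' @param strata A strata tibble from [build_strata()].
#' @param grid A [raster_grid()] of a habitat covariate.
#' @param name Column name for the new covariate.
#' @param outside Value assigned to endpoints outside the grid.
#' @return The strata tibble with the new column(s).
#' @export
add_habitat_covariate <- function(strata, grid, name = "habitat",
                                  outside = NA_real_) {
  strata[[name]] <- raster_value_at(grid, strata$x2, strata$y2,
                                    outside = outside)
  strata
}

#' @rdname add_habitat_covariate
#' @param track The full track the memory is built from.
#' @param bandwidth Gaussian kernel bandwidth in meters.
#' @param window Memory window in days before each stratum time (`Inf` =
#'   all history, i.e. an updating never-forget memory; 3 = the last 3
#'   days, a short-term working memory).
#' @param diel `"all"`, or `"match"` to build each stratum's memory only
#'   from history in the same diel phase as the stratum time.
#' @param day_hours Daytime interval `[h0, h1)` in hours.
#' @export
add_od_covariate <- function(strata, track, bandwidth, window = Inf,
                             name = "od", diel = c("all", "match"),
                             day_hours = c(6, 18)) {
  diel <- match.arg(diel)
  vals <- numeric(nrow(strata))
  idx <- split(seq_len(nrow(strata)), strata$stratum)
  for (rows in idx) {
    t_now <- strata$t1[rows[1]]
    hist <- track[track$t < t_now & track$t >= t_now - window, , drop = FALSE]
    if (diel == "match") {
      phase_day <- is_day_hour(hour_of_day(t_now), day_hours)
      in_day <- is_day_hour(hour_of_day(hist$t), day_hours)
      hist <- hist[if (phase_day) in_day else !in_day, , drop = FALSE]
    }
    vals[rows] <- if (nrow(hist) == 0) 0 else {
      kde_intensity(hist, strata$x2[rows], strata$y2[rows], bandwidth)
    }
  }
  strata[[name]] <- vals
  strata
}

#' @rdname add_habitat_covariate
#' @param indicator A binary [raster_grid()] (e.g. from
#'   [od_contour_indicator()] of a previous season's OD).
#' @export
add_indicator_covariate <- function(strata, indicator, name = "od_indicator") {
  strata[[name]] <- raster_value_at(indicator, strata$x2, strata$y2,
                                    outside = 0)
  strata
}

#' @rdname add_habitat_covariate
#' @param spec A [grid_spec()] for the TSLV grid (2 km cells are the
#'   reference grain).
#' @param default_tslv Days reported for never-visited cells (default 365).
#' @param state Optional pre-primed [tslv_state()] (e.g. from
#'   [burn_in_initialize()]); defaults to an empty map starting at the first
#'   fix.
#' @export
add_tslv_covariate <- function(strata, track, spec, default_tslv = 365,
                               name = "tslv", state = NULL) {
  if (is.null(state)) {
    state <- tslv_state(spec, default_tslv = default_tslv,
                        clock = min(track$t))
  }
  vals <- numeric(nrow(strata))
  trk_i <- 1L
  # replay in time order; strata ids ordered by their decision time
  idx <- split(seq_len(nrow(strata)), strata$stratum)
  stratum_t <- vapply(idx, function(r) strata$t1[r[1]], numeric(1))
  for (s in names(sort(stratum_t))) {
    rows <- idx[[s]]
    t_decide <- strata$t1[rows[1]]
    t_arrive <- strata$t2[rows[1]]
    # advance memory through every fix up to and including the start
    while (trk_i <= nrow(track) && track$t[trk_i] <= t_decide) {
      state <- tslv_advance(state, track$t[trk_i], track$x[trk_i],
                            track$y[trk_i])
      trk_i <- trk_i + 1L
    }
    inside <- !is.na(cell_of(spec, strata$x2[rows], strata$y2[rows]))
    vals[rows[!inside]] <- NA_real_  # clip with clip_strata_to_domain()
    if (any(inside)) {
      vals[rows[inside]] <- tslv_lookup(state, strata$x2[rows[inside]],
                                        strata$y2[rows[inside]],
                                        t_query = t_arrive)
    }
  }
  strata[[name]] <- vals
  strata
}

#' @rdname add_habitat_covariate
#' @param path Previous-season path polyline (data frame with `x`, `y`).
#' @param centroid Length-2 numeric: remembered range centroid.
#' @export
add_migration_covariates <- function(strata, path = NULL, centroid = NULL) {
  if (!is.null(path)) {
    strata$dist_path <- min_distance_to_path(strata$x2, strata$y2, path) / 1000
  }
  if (!is.null(centroid)) {
    # the target vector is taken from each stratum's own start
    sx <- strata$x2 - strata$x1; sy <- strata$y2 - strata$y1
    cx <- centroid[1] - strata$x1; cy <- centroid[2] - strata$y1
    sn <- sqrt(sx^2 + sy^2); cn <- sqrt(cx^2 + cy^2)
    if (any(sn == 0) || any(cn == 0)) {
      abort("Zero-length step or coincident centroid; angle undefined.")
    }
    strata$dir_bias <- (sx * cx + sy * cy) / (sn * cn)
  }
  strata
}

#' Clip available candidates to the spatial domain
#'
#' Removes available candidates whose endpoints fall outside the grid,
#' mirroring the simulator's zero-weight truncation at the domain boundary
#' (used steps are inside by construction, so every stratum keeps its used
#' candidate).
#'
#' @param strata A strata tibble.
#' @param spec A [grid_spec()] defining the domain.
#' @return The clipped strata tibble.
#' @export
clip_strata_to_domain <- function(strata, spec) {
  inside <- !is.na(cell_of(spec, strata$x2, strata$y2))
  if (any(strata$used == 1 & !inside)) {
    abort("A used endpoint lies outside the domain grid.")
  }
  strata[inside, , drop = FALSE]
}

#' Expand a strata table into a model design
#'
#' Produces one row per candidate with the stratum id, used flag and the
#' requested term columns. Terms named in `quadratic` expand into the value
#' and its square (`<term>` and `<term>_sq`), the standard way to let
#' selection peak at an intermediate covariate value. With
#' `movement_adjust = TRUE` the integrated-SSA adjustment terms `log_sl`,
#' `sl_m` and `cos_ta` are appended to absorb tentative-kernel bias.
#'
#' @param strata A strata tibble with covariate columns attached.
#' @param terms Character vector of covariate column names to include.
#' @param quadratic Character vector (subset of `terms`) to expand
#'   quadratically.
#' @param movement_adjust Append `log_sl`, `sl_m`, `cos_ta` adjustment terms.
#' @return A design tibble: `stratum`, `used`, then one column per model
#'   term, with a `terms` attribute listing the term columns in order.
#' @export
build_design <- function(strata, terms, quadratic = character(),
                         movement_adjust = FALSE) {
  if (length(terms) == 0 && !movement_adjust) abort("Need at least one term.")
  missing_terms <- setdiff(terms, names(strata))
  if (length(missing_terms)) {
    abort(sprintf("Covariate `%s` not present in the strata table.",
                  missing_terms[1]))
  }
  bad_quad <- setdiff(quadratic, terms)
  if (length(bad_quad)) {
    abort(sprintf("Quadratic term `%s` is not among `terms`.", bad_quad[1]))
  }
  out <- tibble::tibble(stratum = strata$stratum, used = strata$used)
  cols <- character()
  for (tm in terms) {
    v <- strata[[tm]]
    if (anyNA(v) || any(!is.finite(v))) {
      s_bad <- strata$stratum[which(!is.finite(v))[1]]
      abort(sprintf("Missing covariate `%s` in stratum %s.", tm, s_bad))
    }
    out[[tm]] <- v
    cols <- c(cols, tm)
    if (tm %in% quadratic) {
      out[[paste0(tm, "_sq")]] <- v^2
      cols <- c(cols, paste0(tm, "_sq"))
    }
  }
  if (movement_adjust) {
    if (any(strata$sl <= 0)) abort("Nonpositive step length; cannot take log(sl).")
    out$log_sl <- log(strata$sl)
    out$sl_m <- strata$sl
    out$cos_ta <- cos(strata$ta)
    cols <- c(cols, "log_sl", "sl_m", "cos_ta")
  }
  # a term constant within every stratum carries no conditional information
  for (cn in cols) {
    within_var <- tapply(out[[cn]], out$stratum, function(v) diff(range(v)))
    if (all(within_var < 1e-12)) {
      abort(sprintf(
        "Term `%s` is constant within every stratum and is inestimable.", cn))
    }
  }
  attr(out, "terms") <- cols
  out
}

#' Write/read strata or design tables as CSV
#'
#' @param design A design or strata tibble.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` a
#'   tibble with its `terms` attribute restored from the non-key columns.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("stratum", "used") %in% names(out))) {
    abort("Design file must contain `stratum` and `used` columns.")
  }
  attr(out, "terms") <- setdiff(names(out), c("stratum", "used"))
  out
}
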