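#' Gaussian kernel intensity of past locations at query points
#'
#' Evaluates an isotropic Gaussian kernel density estimate of a set of
#' locations at arbitrary query points, in points per square kilometer.
#' This is the continuous form of the occurrence-distribution covariate:
#' [occurrence_distribution()] evaluates the same estimator at cell centers
#' and normalizes to a discrete probability surface.
#'
#' @param points A data frame with columns `x`, `y` (the history, meters).
#' @param x,y Query coordinates (meters).
#' @param bandwidth Kernel standard deviation in meters, > 0.
#' @return Numeric vector of densities (km^-2; the planar density integrates
#'   to 1, scaled by 1e6 m^2/km^2).
#' @export
kde_intensity <- function(points, x, y, bandwidth) {
  if (nrow(points) == 0) abort("Empty location history.")
  if (bandwidth <= 0) abort("`bandwidth` must be > 0.")
  out <- numeric(length(x))
  # O(n_points * n_query); both stay small in package use.
  for (i in seq_len(nrow(points))) {
    out <- out + dnorm(x, points$x[i], bandwidth) * dnorm(y, points$y[i], bandwidth)
  }
  out / nrow(points) * 1e6
}

#' Occurrence distribution over a time window
#'
#' Isotropic Gaussian kernel density of the fixes inside `[t_a, t_b)`
#' evaluated at grid-cell centers and normalized to sum exactly to 1: a
#' discrete surface of the relative intensity of past space use. An empty
#' window is an error, distinguishing "no information" from "zero intensity".
#'
#' @param track A track tibble.
#' @param window Length-2 numeric `(t_a, t_b)`: the half-open time window in
#'   decimal days.
#' @param spec A [grid_spec()].
#' @param bandwidth Kernel standard deviation in meters, > 0.
#' @return A [raster_grid()] whose values sum to 1.
#' @export
occurrence_distribution <- function(track, window, spec, bandwidth) {
  if (bandwidth <= 0) abort("`bandwidth` must be > 0.")
  pts <- track[track$t >= window[1] & track$t < window[2], , drop = FALSE]
  if (nrow(pts) == 0) {
    abort(sprintf("No locations in window [%g, %g).", window[1], window[2]))
  }
  cc <- cell_centers(spec)
  dens <- kde_intensity(pts, cc$x, cc$y, bandwidth)
  total <- sum(dens)
  if (total <= 0) {
    abort("All kernel mass falls outside the grid; enlarge the grid or bandwidth.")
  }
  raster_grid(spec, dens / total)
}

#' Binary contour indicator of an occurrence distribution
#'
#' Marks the smallest set of cells, taken in descending density order, whose
#' cumulative mass first reaches `level` (e.g. the 95% contour used to ask
#' whether a step endpoint falls inside last season's range). Density ties
#' are broken by linear cell index so output is deterministic.
#'
#' @param od A normalized occurrence distribution ([raster_grid()], values
#'   summing to 1).
#' @param level Mass fraction in (0, 1].
#' @return A binary [raster_grid()] (1 inside the contour set, 0 outside).
#' @export
od_contour_indicator <- function(od, level) {
  if (level <= 0 || level > 1) abort("`level` must be in (0, 1].")
  v <- od$values
  if (level == 1) {  # full support, immune to cumsum rounding
    return(raster_grid(od$spec, as.numeric(v > 0)))
  }
  ord <- order(-v, seq_along(v))  # descending density, ties by cell index
  csum <- cumsum(v[ord])
  k <- which(csum >= level - 1e-15)[1]
  if (is.na(k)) k <- length(v)
  ind <- numeric(length(v))
  ind[ord[seq_len(k)]] <- 1
  ind[v <= 0] <- 0  # never include zero-density cells
  raster_grid(od$spec, ind)
}

#' Short/long-term, diel-stratified occurrence distributions
#'
#' Builds the four memory surfaces used to separate working from reference
#' memory in diel foragers: a long-term OD from all history before `t_now`,
#' a short-term OD from the last `short_window` days, and diel-matched
#' versions of both restricted to fixes in the same diel phase as `t_now`
#' (movement steps taken at night are paired with surfaces built only from
#' nocturnal history, and vice versa). A stratum with no history is flagged
#' unavailable (`NULL`) rather than an error.
#'
#' @param track A track tibble.
#' @param t_now Decision time in decimal days; only fixes strictly before
#'   `t_now` are used.
#' @param spec A [grid_spec()].
#' @param bandwidth Kernel standard deviation in meters.
#' @param short_window Length of the short-term memory window in days
#'   (default 3).
#' @param day_hours Daytime interval `[h0, h1)` in hours (default 6-18).
#' @return A list with elements `long_all`, `short_all`, `long_diel`,
#'   `short_diel`; each a [raster_grid()] or `NULL` when that stratum has no
#'   history, plus `phase` ("day"/"night") of `t_now`.
#' @export
stratified_ods <- function(track, t_now, spec, bandwidth,
                           short_window = 3, day_hours = c(6, 18)) {
  phase <- if (is_day_hour(hour_of_day(t_now), day_hours)) "day" else "night"
  t_first <- if (nrow(track)) min(track$t) else t_now
  windows <- list(
    long_all  = c(t_first, t_now),
    short_all = c(t_now - short_window, t_now)
  )
  make_od <- function(trk, window) {
    n_in <- sum(trk$t >= window[1] & trk$t < window[2])
    if (n_in == 0) return(NULL)
    occurrence_distribution(trk, window, spec, bandwidth)
  }
  diel_track <- filter_track(track, diel = phase, day_hours = day_hours)
  out <- list(
    long_all   = make_od(track, windows$long_all),
    short_all  = make_od(track, windows$short_all),
    long_diel  = make_od(diel_track, windows$long_all),
    short_diel = make_od(diel_track, windows$short_all)
  )
  out$phase <- phase
  out
}
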