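#' Time-since-last-visit state
#'
#' A cell-level memory map: for each grid cell, the time of the most recent
#' visit (or a missing sentinel if never visited) plus the current clock.
#' "Revisitation" happens at the grain of a grid cell, so an animal in the
#' perceptual vicinity of a previous visit counts as returning without
#' needing exact coordinates. Never-visited cells report `default_tslv`
#' days (365 by default, i.e. treated as if visited just before tracking
#' began); visited cells carry uncapped elapsed time.
#'
#' @param spec A [grid_spec()]; a 2 km cell is the reference grain.
#' @param default_tslv Days reported for never-visited cells, > 0.
#' @param clock Initial clock time in decimal days.
#' @return An object of class `tslv_state`.
#' @export
tslv_state <- function(spec, default_tslv = 365, clock = 0) {
  if (default_tslv <= 0) abort("`default_tslv` must be > 0.")
  structure(
    list(spec = spec, last_visit = rep(NA_real_, n_cells(spec)),
         clock = clock, default_tslv = default_tslv),
    class = "tslv_state"
  )
}

#' @export
print.tslv_state <- function(x, ...) {
  cat(sprintf(
    "<tslv_state> %d/%d cells visited; clock %.3f d; default TSLV %g d\n",
    sum(!is.na(x$last_visit)), n_cells(x$spec), x$clock, x$default_tslv
  ))
  invisible(x)
}

#' Advance a TSLV state with one observed location
#'
#' Sets the clock to the location's time and records the visit in the cell
#' containing it; all other cells are unchanged (the map is updated at every
#' observation time).
#'
#' @param state A [tslv_state()].
#' @param t Time of the location, decimal days; must be >= the state clock.
#' @param x,y Planar coordinates of the location, meters; must fall inside
#'   the grid.
#' @return The updated `tslv_state`.
#' @export
tslv_advance <- function(state, t, x, y) {
  if (t < state$clock) {
    abort(sprintf("Time regression: location at t = %g before clock %g.",
                  t, state$clock))
  }
  cell <- cell_of(state$spec, x, y)
  if (is.na(cell)) {
    abort(sprintf("Location (%g, %g) falls outside the TSLV grid.", x, y))
  }
  state$clock <- t
  state$last_visit[cell] <- t
  state
}

#' Look up TSLV values at points
#'
#' Read-only: for each point, `t_query - last_visit(cell)` if the cell has
#' been visited, else `default_tslv`; clamped at 0 so a same-time visit
#' reads 0.
#'
#' @param state A [tslv_state()].
#' @param x,y Point coordinates, meters (must be inside the grid).
#' @param t_query Query time in decimal days.
#' @return Numeric vector of TSLV values in days.
#' @export
tslv_lookup <- function(state, x, y, t_query) {
  cell <- cell_of(state$spec, x, y)
  if (anyNA(cell)) {
    bad <- which(is.na(cell))[1]
    abort(sprintf("Point (%g, %g) falls outside the TSLV grid.",
                  x[bad], y[bad]))
  }
  lv <- state$last_visit[cell]
  out <- ifelse(is.na(lv), state$default_tslv, pmax(t_query - lv, 0))
  as.numeric(out)
}

#' Initialize a TSLV state from a burn-in period
#'
#' Sacrifices the first `burn_in` days of a track to build the memory map,
#' returning the primed state and the post-burn-in remainder used for model
#' fitting. Cells untouched during burn-in keep never-visited semantics
#' (they report `default_tslv`).
#'
#' @param track A track tibble.
#' @param burn_in Burn-in duration in days; must be shorter than the track.
#' @param spec A [grid_spec()].
#' @param default_tslv Days reported for never-visited cells.
#' @return A list with `state` (a [tslv_state()]) and `remainder` (track
#'   tibble of fixes at or after `t_first + burn_in`).
#' @export
burn_in_initialize <- function(track, burn_in, spec, default_tslv = 365) {
  duration <- max(track$t) - min(track$t)
  if (burn_in >= duration) {
    abort(sprintf("Burn-in (%g d) must be shorter than the track (%g d).",
                  burn_in, duration))
  }
  cutoff <- min(track$t) + burn_in
  state <- tslv_state(spec, default_tslv = default_tslv, clock = min(track$t))
  pre <- track[track$t < cutoff, , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    state <- tslv_advance(state, pre$t[i], pre$x[i], pre$y[i])
  }
  list(state = state,
       remainder = new_track(tibble::as_tibble(track)[track$t >= cutoff, ,
                                                      drop = FALSE]))
}
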