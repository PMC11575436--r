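#' Coerce a telemetry table to a track
#'
#' A track is a time-ordered tibble of planar telemetry fixes for one
#' individual, with columns `id`, `t` (decimal days since the first fix of
#' the track), `x`, `y` (projected planar meters). Coordinates must already
#' be projected; no geographic support is provided.
#'
#' @param data A data frame of fixes.
#' @param id,t,x,y Column names in `data` holding the individual label,
#'   timestamp, and planar coordinates. Timestamps may be numeric (decimal
#'   days) or parseable date-times (ISO-8601); date-times are converted to
#'   decimal days since the first fix.
#' @return A tibble of class `track` with columns `id`, `t`, `x`, `y`,
#'   sorted by time, plus a `fix_interval` attribute (median time gap, days).
#' @examples
#' trk <- as_track(data.frame(id = "a", t = c(0, 0.25, 0.5),
#'                            x = c(0, 10, 20), y = c(0, 0, 5)))
#' @export
as_track <- function(data, id = "id", t = "t", x = "x", y = "y") {
  for (col in c(id, t, x, y)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  tv <- data[[t]]
  if (inherits(tv, c("POSIXct", "Date"))) {
    tv <- as.numeric(tv)
    tv <- (tv - min(tv)) / if (inherits(data[[t]], "Date")) 1 else 86400
  } else if (is.character(tv)) {
    parsed <- suppressWarnings(as.POSIXct(tv, tz = "UTC"))
    if (anyNA(parsed)) {
      parsed_num <- suppressWarnings(as.numeric(tv))
      if (anyNA(parsed_num)) {
        abort(sprintf("Timestamp not parseable at row %d.",
                      which(is.na(parsed) & is.na(parsed_num))[1]))
      }
      tv <- parsed_num
    } else {
      tv <- as.numeric(parsed - min(parsed), units = "days")
    }
  }
  xv <- data[[x]]; yv <- data[[y]]
  if (!is.numeric(xv) || !is.numeric(yv)) {
    bad <- which(is.na(suppressWarnings(as.numeric(xv))) |
                   is.na(suppressWarnings(as.numeric(yv))))[1]
    abort(sprintf("Non-numeric coordinates at row %d.", bad %||% 1L))
  }
  if (!all(is.finite(tv)) || !all(is.finite(xv)) || !all(is.finite(yv))) {
    abort(sprintf("Non-finite fix at row %d.",
                  which(!is.finite(tv) | !is.finite(xv) | !is.finite(yv))[1]))
  }
  out <- tibble::tibble(id = as.character(data[[id]]), t = tv, x = xv, y = yv)
  out <- dplyr::arrange(out, .data$t)
  dup <- duplicated(paste(out$id, out$t))
  if (any(dup)) {
    abort(sprintf("Duplicate timestamp for id '%s' at t = %g days.",
                  out$id[dup][1], out$t[dup][1]))
  }
  new_track(out)
}

new_track <- function(tbl) {
  fix <- if (nrow(tbl) > 1) median(diff(tbl$t)) else NA_real_
  structure(tbl, class = c("track", class(tibble::tibble())),
            fix_interval = fix)
}

#' Read a track from a delimited file
#'
#' @param path Path to a CSV file of telemetry fixes.
#' @param column_map Named character vector mapping the track fields to the
#'   file's column names, e.g. `c(id = "animal", t = "timestamp", x = "utm_x",
#'   y = "utm_y")`. Missing entries default to `id`, `t`, `x`, `y`.
#' @inherit as_track return
#' @export
read_track <- function(path, column_map = c()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cm <- c(id = "id", t = "t", x = "x", y = "y")
  cm[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_track(raw, id = cm[["id"]], t = cm[["t"]], x = cm[["x"]], y = cm[["y"]])
}

#' Decompose a track into steps
#'
#' Each pair of consecutive fixes yields a step with its Euclidean length
#' `sl` (m), absolute heading `bearing` (radians, counterclockwise from the
#' +x axis), and turning angle `ta` (radians in (-pi, pi], counterclockwise
#' positive). A turning angle needs the two previous fixes, so it is `NA` on
#' the first step of a track. Steps spanning irregular sampling gaps are kept
#' and flagged via `gap_days`; no interpolation is performed.
#'
#' @param track A [as_track()] tibble with at least 2 fixes.
#' @return A tibble with one row per step: `id`, `t1`, `t2`, `x1`, `y1`,
#'   `x2`, `y2`, `sl`, `ta`, `bearing`, `gap_days`.
#' @export
steps_from_track <- function(track) {
  if (nrow(track) < 2) abort("Need at least 2 locations to form steps.")
  n <- nrow(track)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  dx <- track$x[i2] - track$x[i1]
  dy <- track$y[i2] - track$y[i1]
  bearing <- atan2(dy, dx)
  ta <- c(NA_real_, wrap_angle(diff(bearing)))
  tibble::tibble(
    id = track$id[i1],
    t1 = track$t[i1], t2 = track$t[i2],
    x1 = track$x[i1], y1 = track$y[i1],
    x2 = track$x[i2], y2 = track$y[i2],
    sl = sqrt(dx^2 + dy^2),
    ta = ta,
    bearing = bearing,
    gap_days = track$t[i2] - track$t[i1]
  )
}

#' Filter a track by time window and diel phase
#'
#' Retains fixes with `t` in `[t_start, t_end)` and, for `diel = "day"` or
#' `"night"`, with hour-of-day inside (day) or outside (night) the half-open
#' interval `day_hours = [h0, h1)`. An empty result is a valid empty track.
#'
#' @param track A track tibble.
#' @param t_start,t_end Window bounds in decimal days (`t_start <= t_end`).
#' @param diel One of `"all"`, `"day"`, `"night"`.
#' @param day_hours Length-2 numeric: daytime hours `[h0, h1)`.
#' @return A filtered track tibble (possibly empty).
#' @export
filter_track <- function(track, t_start = -Inf, t_end = Inf,
                         diel = c("all", "day", "night"),
                         day_hours = c(6, 18)) {
  diel <- match.arg(diel)
  if (t_start > t_end) abort("`t_start` must be <= `t_end`.")
  keep <- track$t >= t_start & track$t < t_end
  if (diel != "all") {
    h <- hour_of_day(track$t)
    day <- is_day_hour(h, day_hours)
    keep <- keep & if (diel == "day") day else !day
  }
  new_track(tibble::as_tibble(track)[keep, , drop = FALSE])
}

#' Write a steps table to CSV
#'
#' @param steps A steps tibble from [steps_from_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_steps <- function(steps, path) {
  utils::write.csv(steps, path, row.names = FALSE)
  invisible(path)
}
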