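#' Minimum distance from points to a remembered path
#'
#' For each point, the minimum Euclidean distance to any segment of a
#' polyline (point-to-vertex when the path has a single vertex). Used as the
#' migratory familiarity covariate "distance between current and past
#' migratory paths".
#'
#' @param x,y Point coordinates, meters.
#' @param path A data frame with columns `x`, `y`: the ordered vertices of
#'   the previous-season path (>= 1 vertex).
#' @return Numeric vector of distances in meters.
#' @export
min_distance_to_path <- function(x, y, path) {
  if (nrow(path) == 0) abort("`path` must have at least one vertex.")
  if (nrow(path) == 1) {
    return(sqrt((x - path$x[1])^2 + (y - path$y[1])^2))
  }
  px1 <- path$x[-nrow(path)]; py1 <- path$y[-nrow(path)]
  px2 <- path$x[-1];          py2 <- path$y[-1]
  dx <- px2 - px1; dy <- py2 - py1
  len2 <- dx^2 + dy^2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    # projection parameter clamped to the segment
    tt <- ((x[i] - px1) * dx + (y[i] - py1) * dy) / ifelse(len2 > 0, len2, 1)
    tt <- pmin(pmax(tt, 0), 1)
    qx <- px1 + tt * dx; qy <- py1 + tt * dy
    out[i] <- sqrt(min((x[i] - qx)^2 + (y[i] - qy)^2))
  }
  out
}

#' Directional bias toward a remembered range centroid
#'
#' Cosine of the angle between a candidate step vector (start to candidate
#' endpoint) and the vector from the start to a target centroid (e.g. the
#' centroid of the previous year's winter range): +1 for a step directly
#' toward the target, -1 directly away, 0 perpendicular. Depends only on
#' direction, not step length.
#'
#' @param start Length-2 numeric `(x, y)`: the step start.
#' @param end_x,end_y Candidate endpoint coordinates (vectors).
#' @param centroid Length-2 numeric `(x, y)`: the remembered target.
#' @return Numeric vector of cosines in `[-1, 1]`.
#' @export
directional_bias <- function(start, end_x, end_y, centroid) {
  sx <- end_x - start[1]; sy <- end_y - start[2]
  cx <- centroid[1] - start[1]; cy <- centroid[2] - start[2]
  if (cx == 0 && cy == 0) {
    abort("Target centroid coincides with the step start; angle undefined.")
  }
  sn <- sqrt(sx^2 + sy^2)
  if (any(sn == 0)) abort("Zero-length step; angle undefined.")
  (sx * cx + sy * cy) / (sn * sqrt(cx^2 + cy^2))
}

#' Centroid of a set of locations
#'
#' Arithmetic mean of the coordinates; the package's definition of the
#' centroid of a previous seasonal range.
#'
#' @param track A data frame with columns `x`, `y`.
#' @return Length-2 numeric `(x, y)`.
#' @export
range_centroid <- function(track) {
  if (nrow(track) == 0) abort("Cannot take the centroid of an empty range.")
  c(mean(track$x), mean(track$y))
}
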