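#' @importFrom rlang %||% abort warn .data
#' @importFrom stats dgamma dnorm pgamma qgamma rgamma runif rnorm sd var
#'   median optim uniroot setNames complete.cases ks.test quantile
#' @importFrom utils head tail read.csv write.csv
NULL

# Wrap angles into (-pi, pi]. Counterclockwise positive throughout.
wrap_angle <- function(theta) {
  w <- ((theta + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

# Hour of day from decimal days; day 0 starts at hour 0.
hour_of_day <- function(t) (t %% 1) * 24

is_day_hour <- function(h, day_hours) h >= day_hours[1] & h < day_hours[2]

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream,
# or as-is when seed is NULL (caller manages reproducibility).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
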