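#' Selection-free movement kernel parameters
#'
#' The selection-free kernel factors into a gamma distribution on step
#' lengths and a von Mises distribution on turning angles with mean
#' direction fixed at 0 (straight ahead). These are the exponential-family
#' choices that let the selection model be fitted by conditional logistic
#' regression.
#'
#' @param shape,scale Gamma shape (dimensionless) and scale (meters), both > 0.
#' @param kappa von Mises concentration, >= 0 (0 = uniform turning angles).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(shape, scale, kappa) {
  stopifnot_scalar_number(shape, "shape")
  stopifnot_scalar_number(scale, "scale")
  stopifnot_scalar_number(kappa, "kappa")
  if (shape <= 0 || scale <= 0) abort("Gamma shape and scale must be > 0.")
  if (kappa < 0) abort("`kappa` must be >= 0.")
  structure(list(shape = shape, scale = scale, kappa = kappa),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "<kernel_params> gamma(shape %.4g, scale %.4g m), von Mises(mu 0, kappa %.4g)\n",
    x$shape, x$scale, x$kappa
  ))
  invisible(x)
}

# Cap keeping besselI and the Best-Fisher sampler numerically safe.
KAPPA_MAX <- 700

#' von Mises density, CDF and sampler (mean direction 0)
#'
#' Density uses exponentially scaled Bessel functions so large
#' concentrations stay finite; the sampler is the Best-Fisher (1979)
#' wrapped-Cauchy rejection algorithm; the CDF integrates the density
#' from -pi on a fine grid.
#'
#' @param theta Angles in radians.
#' @param kappa Concentration >= 0.
#' @param n Number of draws.
#' @return `dvonmises()` and `pvonmises()` return numeric vectors;
#'   `rvonmises()` returns `n` angles in (-pi, pi].
#' @export
dvonmises <- function(theta, kappa) {
  if (kappa < 0) abort("`kappa` must be >= 0.")
  # exp(kappa cos) / (2 pi I0(kappa)) = exp(kappa (cos - 1)) / (2 pi I0e(kappa))
  exp(kappa * (cos(theta) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname dvonmises
#' @export
pvonmises <- function(theta, kappa) {
  grid <- seq(-pi, pi, length.out = 4096)
  dens <- dvonmises(grid, kappa)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(grid, cdf, xout = theta, rule = 2)$y
}

#' @rdname dvonmises
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) abort("`kappa` must be >= 0.")
  if (kappa < 1e-10) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- ifelse(u3[ok] >= 0.5, 1, -1) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out)
}

# MLE of von Mises concentration with mean direction fixed at 0:
# solve A1(kappa) = I1/I0 = mean(cos(theta)).
fit_kappa <- function(ta, kappa_max = KAPPA_MAX) {
  rbar <- mean(cos(ta))
  if (rbar <= 0) return(0)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (a1(kappa_max) <= rbar) {
    warn(sprintf(
      "Turning-angle concentration estimate diverges; capped at kappa = %g.",
      kappa_max
    ))
    return(kappa_max)
  }
  uniroot(function(k) a1(k) - rbar, c(1e-8, kappa_max), tol = 1e-10)$root
}

#' Fit tentative movement-kernel parameters from observed steps
#'
#' Maximum-likelihood gamma fit to step lengths and von Mises concentration
#' (mean 0) to turning angles. Zero step lengths are replaced by half the
#' smallest positive step length so strata stay aligned; the number replaced
#' is reported as the `n_zero_replaced` attribute. Fitted once from the
#' observed steps and then reused for all strata (the tentative-kernel
#' convention of integrated step-selection analysis).
#'
#' @param steps A steps tibble from [steps_from_track()].
#' @param kappa_max Cap on the concentration estimate (guards Bessel
#'   overflow for near-degenerate turning angles).
#' @return A [kernel_params()] object with attribute `n_zero_replaced`.
#' @export
fit_tentative <- function(steps, kappa_max = KAPPA_MAX) {
  sl <- steps$sl
  ta <- steps$ta[!is.na(steps$ta)]
  if (sum(sl > 0) < 5) abort("Need at least 5 steps with positive length.")
  if (length(ta) < 5) abort("Need at least 5 defined turning angles.")
  n_zero <- sum(sl == 0)
  if (n_zero > 0) sl[sl == 0] <- min(sl[sl > 0]) / 2
  if (length(unique(sl)) == 1) {
    abort("All step lengths identical; gamma likelihood is degenerate.")
  }
  fit <- fitdistrplus::fitdist(sl, "gamma", method = "mle")
  shape <- unname(fit$estimate["shape"])
  scale <- 1 / unname(fit$estimate["rate"])
  kappa <- fit_kappa(ta, kappa_max)
  out <- kernel_params(shape, scale, kappa)
  attr(out, "n_zero_replaced") <- n_zero
  attr(out, "se") <- c(shape = unname(fit$sd["shape"]),
                       rate = unname(fit$sd["rate"]))
  if (n_zero > 0) {
    message(sprintf("%d zero step length(s) replaced by half the smallest positive step.",
                    n_zero))
  }
  out
}

#' Kernel density of a step
#'
#' Product of the gamma density at the step length and the von Mises density
#' at the turning angle; the selection-free movement kernel evaluated for one
#' candidate step.
#'
#' @param sl Step lengths in meters, > 0.
#' @param ta Turning angles in radians.
#' @param params A [kernel_params()].
#' @return Nonnegative densities (units 1/(m rad)).
#' @export
kernel_density <- function(sl, ta, params) {
  if (any(sl <= 0)) abort("`sl` must be > 0.")
  dgamma(sl, shape = params$shape, scale = params$scale) *
    dvonmises(ta, params$kappa)
}

#' Sample matched available steps
#'
#' Draws candidate step endpoints from the selection-free kernel: lengths
#' from the fitted gamma, turning angles from the fitted von Mises applied
#' to the previous bearing. These discretize the availability integral in
#' the step-selection likelihood.
#'
#' @param start Length-2 numeric `(x, y)` of the step start, meters.
#' @param prev_bearing Bearing of the previous step, radians.
#' @param params A [kernel_params()].
#' @param n_avail Number of candidates (>= 1).
#' @param seed Optional integer; when supplied the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return A tibble with one row per candidate: `x`, `y`, `sl`, `ta`,
#'   `bearing`.
#' @export
sample_available <- function(start, prev_bearing, params, n_avail, seed = NULL) {
  if (n_avail < 1) abort("`n_avail` must be >= 1.")
  if (!is.finite(prev_bearing)) abort("Previous bearing must be defined.")
  with_seed_or_not(seed, {
    sl <- rgamma(n_avail, shape = params$shape, scale = params$scale)
    ta <- rvonmises(n_avail, params$kappa)
    bearing <- wrap_angle(prev_bearing + ta)
    tibble::tibble(
      x = start[1] + sl * cos(bearing),
      y = start[2] + sl * sin(bearing),
      sl = sl, ta = ta, bearing = bearing
    )
  })
}
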