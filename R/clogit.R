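design_matrix <- function(design, terms = NULL) {
  terms <- terms %||% attr(design, "terms")
  if (is.null(terms)) {
    terms <- setdiff(names(design), c("stratum", "used"))
  }
  missing_terms <- setdiff(terms, names(design))
  if (length(missing_terms)) {
    abort(sprintf("Term `%s` not found in the design.", missing_terms[1]))
  }
  X <- as.matrix(design[, terms, drop = FALSE])
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("Design contains non-finite covariate values.")
  }
  list(X = X, stratum = as.integer(factor(design$stratum,
                                          levels = unique(design$stratum))),
       used = design$used == 1, terms = terms)
}

# log-sum-exp pieces per stratum, shared by loglik/gradient/Hessian
clogit_parts <- function(beta, dm) {
  eta <- drop(dm$X %*% beta)
  emax <- stats::ave(eta, dm$stratum, FUN = max)
  w <- exp(eta - emax)
  denom <- rowsum(w, dm$stratum)                 # S x 1
  p <- w / denom[dm$stratum, 1]
  loglik <- sum(eta[dm$used] - emax[dm$used] - log(denom[dm$stratum[dm$used], 1]))
  list(p = p, loglik = loglik)
}

#' Conditional-logistic (stratified softmax) log-likelihood
#'
#' For each stratum, the probability that the used candidate is chosen from
#' the candidate set is `exp(eta_used) / sum(exp(eta))` with `eta = X beta`;
#' the log-likelihood is the sum of these log-probabilities, computed with
#' log-sum-exp stabilization. Because the denominator is shared within a
#' stratum, adding any stratum-constant to the linear predictor leaves the
#' likelihood unchanged: only within-stratum contrasts are informative.
#'
#' @param beta Coefficient vector, one entry per term column.
#' @param design A design tibble from [build_design()] (columns `stratum`,
#'   `used`, then terms).
#' @param terms Optional explicit term columns (defaults to the design's
#'   `terms` attribute, else all non-key columns).
#' @return The scalar log-likelihood.
#' @export
clogit_loglik <- function(beta, design, terms = NULL) {
  dm <- design_matrix(design, terms)
  if (length(beta) != ncol(dm$X)) {
    abort(sprintf("`beta` has length %d but the design has %d terms.",
                  length(beta), ncol(dm$X)))
  }
  clogit_parts(beta, dm)$loglik
}

#' Fit a step-selection model by conditional logistic regression
#'
#' Newton-Raphson maximization of [clogit_loglik()] with step halving. The
#' likelihood is concave, so from any start the iteration converges to the
#' unique maximum on non-degenerate data; the coefficient covariance is the
#' inverse observed information at the optimum. Perfect separation (a
#' coefficient escaping to infinity) is flagged via a diverging-coefficient
#' diagnostic rather than reported as a converged fit.
#'
#' @param design A design tibble from [build_design()] or [read_design()].
#' @param terms Optional explicit term columns.
#' @param start Starting coefficients (default all 0).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @param beta_bound Coefficient magnitude (in within-design standard
#'   deviations of the covariate) beyond which separation is diagnosed; a
#'   standardized coefficient this large means the term's observed range
#'   spans astronomically large odds ratios, the footprint of a term whose
#'   used value is always extreme.
#' @return An object of class `ssf_fit`: `beta` (named), `se`, `vcov`,
#'   `loglik`, `converged`, `n_strata`, `n_iter`, `separation`.
#' @export
fit_clogit <- function(design, terms = NULL, start = NULL, tol = 1e-8,
                       max_iter = 50, beta_bound = 10) {
  dm <- design_matrix(design, terms)
  p <- ncol(dm$X)
  n_strata <- length(unique(dm$stratum))
  if (sum(dm$used) != n_strata) {
    abort("Each stratum must contain exactly one used candidate.")
  }
  # scale columns to unit sd for a well-conditioned Newton step
  sds <- apply(dm$X, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  Xs <- sweep(dm$X, 2, sds, "/")
  dms <- dm; dms$X <- Xs
  beta <- if (is.null(start)) rep(0, p) else start * sds
  parts <- clogit_parts(beta, dms)
  separation <- FALSE
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    pvec <- parts$p
    G <- colSums(Xs[dm$used, , drop = FALSE]) - colSums(Xs * pvec)
    M <- rowsum(Xs * pvec, dm$stratum)           # per-stratum mean covariates
    H <- -(crossprod(Xs, Xs * pvec) - crossprod(M))
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-H, G), error = function(e) NULL)
    if (is.null(step)) {
      abort("Singular information matrix; terms may be collinear within strata.")
    }
    # step halving keeps the likelihood monotone
    lam <- 1
    repeat {
      cand <- beta + lam * step
      cand_parts <- clogit_parts(cand, dms)
      if (cand_parts$loglik >= parts$loglik - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    beta <- beta + lam * step
    parts <- cand_parts
    if (max(abs(beta)) > 2 * beta_bound) break  # clearly escaping
  }
  if (max(abs(beta)) > beta_bound) {
    separation <- TRUE
    warn(paste("Diverging coefficient detected: a term may perfectly",
               "separate used from available candidates."))
  }
  # information and covariance on the original covariate scale
  pvec <- parts$p
  M <- rowsum(dm$X * pvec, dm$stratum)
  H <- -(crossprod(dm$X, dm$X * pvec) - crossprod(M))
  vcov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  beta_out <- beta / sds
  names(beta_out) <- dm$terms
  dimnames(vcov) <- list(dm$terms, dm$terms)
  structure(
    list(
      beta = beta_out,
      se = sqrt(pmax(diag(vcov), 0)),
      vcov = vcov,
      loglik = parts$loglik,
      converged = converged && !separation,
      separation = separation,
      n_strata = n_strata,
      n_iter = iter,
      terms = dm$terms
    ),
    class = "ssf_fit"
  )
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("Step-selection fit: %d strata, log-likelihood %.4f%s\n",
              x$n_strata, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  if (x$separation) cat("  [separation diagnostic triggered]\n")
  df <- data.frame(estimate = x$beta, std.error = x$se)
  print(round(df, 6))
  invisible(x)
}

#' Tidy and glance methods for step-selection fits
#'
#' `tidy()` returns one row per coefficient with Wald statistics and
#' (optionally) confidence limits; `glance()` returns a one-row model
#' summary.
#'
#' @param x An `ssf_fit`.
#' @param conf.int Add Wald confidence limits.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ssf_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = x$terms,
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = 2 * stats::pnorm(-abs(unname(x$beta / x$se)))
  )
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @rdname tidy.ssf_fit
#' @export
glance.ssf_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_strata = x$n_strata,
    n_terms = length(x$beta),
    converged = x$converged,
    separation = x$separation,
    AIC = -2 * x$loglik + 2 * length(x$beta)
  )
}

#' Relative selection strength between two locations
#'
#' `exp(beta' (x1 - x2))`: how many times more likely a step to a location
#' with covariates `x1` is than to an otherwise identical, equally
#' accessible location with covariates `x2`. Multiplicative in chains:
#' `rss(x1, x2) * rss(x2, x3) = rss(x1, x3)`.
#'
#' @param fit An `ssf_fit`.
#' @param x1,x2 Named numeric vectors conforming to the fit's terms (missing
#'   terms default to 0, i.e. "all else equal").
#' @param conf.level If non-`NULL`, adds a Wald interval on the log scale
#'   propagated through the fit covariance.
#' @return A one-row tibble with `rss` (and `conf.low`/`conf.high`).
#' @export
rss <- function(fit, x1, x2, conf.level = NULL) {
  full <- function(v) {
    out <- setNames(rep(0, length(fit$terms)), fit$terms)
    if (is.null(names(v))) {
      if (length(v) != length(fit$terms)) {
        abort("Unnamed covariate vectors must match the fit's term count.")
      }
      out[] <- v
    } else {
      bad <- setdiff(names(v), fit$terms)
      if (length(bad)) abort(sprintf("Unknown term `%s`.", bad[1]))
      out[names(v)] <- v
    }
    out
  }
  d <- full(x1) - full(x2)
  log_rss <- sum(fit$beta * d)
  out <- tibble::tibble(rss = exp(log_rss))
  if (!is.null(conf.level)) {
    se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- exp(log_rss - z * se)
    out$conf.high <- exp(log_rss + z * se)
  }
  out
}

#' Relative-selection-strength curve over a covariate sweep
#'
#' Sweeps one covariate (optionally with its quadratic companion
#' `<term>_sq`) against a reference value, holding everything else equal.
#' The standard display for a time-since-last-visit response: selection
#' strength as a function of days since the last visit.
#'
#' @param fit An `ssf_fit`.
#' @param term Covariate to sweep.
#' @param from,to,by Sweep grid.
#' @param reference Reference covariate value (default 0).
#' @param conf.level Optional Wald interval level.
#' @return A tibble with columns `value`, `rss` (and interval columns).
#' @export
rss_curve <- function(fit, term, from, to, by = 1, reference = 0,
                      conf.level = NULL) {
  if (!term %in% fit$terms) abort(sprintf("Term `%s` not in the fit.", term))
  sq <- paste0(term, "_sq")
  has_sq <- sq %in% fit$terms
  values <- seq(from, to, by = by)
  rows <- lapply(values, function(v) {
    x1 <- setNames(v, term)
    x2 <- setNames(reference, term)
    if (has_sq) {
      x1 <- c(x1, setNames(v^2, sq))
      x2 <- c(x2, setNames(reference^2, sq))
    }
    rss(fit, x1, x2, conf.level = conf.level)
  })
  out <- dplyr::bind_rows(rows)
  out$value <- values
  dplyr::relocate(out, "value")
}

#' Optimal time since last visit implied by a quadratic fit
#'
#' With linear and quadratic TSLV terms, selection peaks at
#' `-beta_lin / (2 beta_quad)` when the quadratic coefficient is negative;
#' the return time at which previously visited cells are most attractive.
#'
#' @param fit An `ssf_fit` containing `tslv` and `tslv_sq`.
#' @param term Base term name (default `"tslv"`).
#' @return The optimum in the covariate's units (days for TSLV).
#' @export
tslv_optimum <- function(fit, term = "tslv") {
  sq <- paste0(term, "_sq")
  if (!all(c(term, sq) %in% fit$terms)) {
    abort(sprintf("Fit must contain `%s` and `%s`.", term, sq))
  }
  b1 <- fit$beta[[term]]; b2 <- fit$beta[[sq]]
  if (b2 >= 0) {
    abort("Quadratic coefficient is nonnegative: no interior maximum.")
  }
  -b1 / (2 * b2)
}

#' Simulate strata directly from the conditional choice model
#'
#' Generates strata with independent standard-normal covariates and picks
#' the used candidate by the stratified softmax with the supplied
#' coefficients: the minimal generative model matched exactly by
#' [fit_clogit()]. Used for parameter-recovery and interval-coverage
#' checks of the fitter itself, free of any movement structure.
#'
#' @param n_strata Number of strata.
#' @param n_avail Available candidates per stratum (choice sets have
#'   `n_avail + 1` candidates).
#' @param beta Named coefficient vector (names become term columns;
#'   unnamed vectors get `x1`, `x2`, ...).
#' @param seed Optional seed.
#' @return A design tibble ready for [fit_clogit()].
#' @export
simulate_choice_design <- function(n_strata, n_avail, beta, seed = NULL) {
  p <- length(beta)
  nm <- names(beta) %||% paste0("x", seq_len(p))
  k <- n_avail + 1
  with_seed_or_not(seed, {
    X <- matrix(rnorm(n_strata * k * p), n_strata * k, p)
    eta <- drop(X %*% beta)
    used <- integer(n_strata * k)
    for (s in seq_len(n_strata)) {
      rows <- ((s - 1) * k + 1):(s * k)
      w <- exp(eta[rows] - max(eta[rows]))
      used[rows[sample.int(k, 1, prob = w)]] <- 1L
    }
    out <- tibble::tibble(stratum = rep(seq_len(n_strata), each = k),
                          used = used)
    for (j in seq_len(p)) out[[nm[j]]] <- X[, j]
    attr(out, "terms") <- nm
    out
  })
}

#' Serialize a fit to JSON
#'
#' @param fit An `ssf_fit`.
#' @param path Output path.
#' @return `path` invisibly; `read_fit_json()` returns the restored
#'   `ssf_fit`.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    terms = fit$terms,
    beta = unname(fit$beta),
    se = unname(fit$se),
    vcov = unname(fit$vcov),
    loglik = fit$loglik,
    converged = fit$converged,
    separation = fit$separation,
    n_strata = fit$n_strata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vcov <- matrix(unlist(obj$vcov), length(obj$terms), length(obj$terms))
  dimnames(vcov) <- list(obj$terms, obj$terms)
  structure(
    list(
      beta = setNames(obj$beta, obj$terms),
      se = setNames(obj$se, obj$terms),
      vcov = vcov,
      loglik = obj$loglik,
      converged = obj$converged,
      separation = obj$separation,
      n_strata = obj$n_strata,
      n_iter = NA_integer_,
      terms = obj$terms
    ),
    class = "ssf_fit"
  )
}
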