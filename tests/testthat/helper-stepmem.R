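# Shared fixture builders; everything is generated in code under fixed seeds.

# A simple correlated random-walk track centered on (cx, cy).
make_rw_track <- function(n = 50, seed = 1, step_sd = 300,
                          fix_interval = 1 / 6, cx = 30000, cy = 30000,
                          id = "a") {
  withr::with_seed(seed, {
    as_track(data.frame(
      id = id,
      t = seq(0, by = fix_interval, length.out = n),
      x = cx + cumsum(rnorm(n, 0, step_sd)),
      y = cy + cumsum(rnorm(n, 0, step_sd))
    ))
  })
}

# Hand-rolled per-stratum softmax enumeration: the independent likelihood
# oracle against which the vectorized implementation is checked.
brute_force_clogit_loglik <- function(beta, design, terms) {
  total <- 0
  for (s in unique(design$stratum)) {
    rows <- design[design$stratum == s, , drop = FALSE]
    eta <- as.matrix(rows[, terms, drop = FALSE]) %*% beta
    p <- exp(eta) / sum(exp(eta))
    total <- total + log(p[rows$used == 1])
  }
  total
}

# Exhaustive point-to-segment distance: the geometry oracle.
brute_force_min_dist <- function(px, py, path) {
  seg_dist <- function(x, y, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    if (dx == 0 && dy == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
    tt <- ((x - x1) * dx + (y - y1) * dy) / (dx^2 + dy^2)
    tt <- min(max(tt, 0), 1)
    sqrt((x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2)
  }
  vapply(seq_along(px), function(i) {
    if (nrow(path) == 1) return(sqrt((px[i] - path$x)^2 + (py[i] - path$y)^2))
    min(vapply(seq_len(nrow(path) - 1), function(j) {
      seg_dist(px[i], py[i], path$x[j], path$y[j],
               path$x[j + 1], path$y[j + 1])
    }, numeric(1)))
  }, numeric(1))
}

# Small flat-domain config for simulator tests.
flat_sim_config <- function(n_steps = 500, seed = 1, kappa = 0.5,
                            shape = 2, scale = 300) {
  sim_config(
    kernel = kernel_params(shape, scale, kappa),
    memory_mode = "none", n_steps = n_steps, n_candidates = 100,
    gridspec = grid_spec(-1e5, -1e5, 1000, 200, 200), seed = seed
  )
}
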