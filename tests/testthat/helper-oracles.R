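# Independent numerical oracles used to validate the closed-form kernels and
# fitters. These deliberately share no code with the package internals.

# Monte-Carlo random walk in an absorbing unit sphere (D = 1, r = 1):
# remaining airborne fraction after dimensionless time x = D t / r^2.
# Wall crossings between steps are handled with the Brownian-bridge
# crossing probability, which removes the O(sqrt(dt)) absorption bias.
mc_sphere_remaining <- function(x_target, n_walkers = 1e5, dt = 1e-4,
                                seed = 1) {
  set.seed(seed)
  pos <- matrix(stats::rnorm(3 * n_walkers), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) * stats::runif(n_walkers)^(1 / 3)
  steps <- ceiling(x_target / dt)
  dt <- x_target / steps
  sigma <- sqrt(2 * dt)
  alive <- nrow(pos)
  for (k in seq_len(steps)) {
    d0 <- 1 - sqrt(rowSums(pos^2))
    pos2 <- pos + matrix(stats::rnorm(3 * alive, 0, sigma), ncol = 3)
    d1 <- 1 - sqrt(rowSums(pos2^2))
    p_cross <- ifelse(d1 <= 0, 1, exp(-pmax(d0, 0) * pmax(d1, 0) / dt))
    keep <- stats::runif(alive) > p_cross
    pos <- pos2[keep, , drop = FALSE]
    alive <- nrow(pos)
    if (alive == 0) break
  }
  list(frac = alive / n_walkers,
       se = max(sqrt(alive), 1) / n_walkers)
}

# Numerical solution of the Graetz convection-diffusion problem in a tube:
# fully developed laminar flow, uniform inlet concentration, perfectly
# absorbing wall. Crank-Nicolson marching in the axial coordinate
# z = D x / (U R^2) from 0 to mu = pi D L / Q; returns the flow-weighted
# mean outlet concentration (penetration).
graetz_penetration <- function(mu, ns = 400, nz = 4000) {
  h <- 1 / ns
  s  <- (seq_len(ns) - 0.5) * h
  sp <- seq_len(ns) * h
  sm <- sp - h
  u <- 2 * (1 - s^2)
  zg <- mu * seq(0, 1, length.out = nz + 1)^2   # clustered at the inlet
  c_now <- rep(1, ns)
  lo <- sm / (s * h^2)
  up <- sp / (s * h^2)
  for (k in seq_len(nz)) {
    a <- (zg[k + 1] - zg[k]) / (2 * u)
    diag_main <- 1 + a * (lo + up)
    diag_main[ns] <- 1 + a[ns] * (lo[ns] + 2 * up[ns])  # Dirichlet wall
    dl <- -a[2:ns] * lo[2:ns]
    du <- -a[1:(ns - 1)] * up[1:(ns - 1)]
    cm <- c(0, c_now[1:(ns - 1)])
    cp <- c(c_now[2:ns], 0)
    Lc <- lo * (cm - c_now) + up * (cp - c_now)
    Lc[1] <- up[1] * (c_now[2] - c_now[1])
    Lc[ns] <- lo[ns] * (c_now[ns - 1] - c_now[ns]) + 2 * up[ns] * (0 - c_now[ns])
    rhs <- c_now + a * Lc
    cpv <- numeric(ns); dpv <- numeric(ns)
    cpv[1] <- du[1] / diag_main[1]
    dpv[1] <- rhs[1] / diag_main[1]
    for (i in 2:ns) {
      m <- diag_main[i] - dl[i - 1] * cpv[i - 1]
      if (i < ns) cpv[i] <- du[i] / m
      dpv[i] <- (rhs[i] - dl[i - 1] * dpv[i - 1]) / m
    }
    c_now[ns] <- dpv[ns]
    for (i in (ns - 1):1) c_now[i] <- dpv[i] - cpv[i] * c_now[i + 1]
  }
  sum(2 * (1 - s^2) * c_now * 2 * s * h)
}

# Brute-force grid search minimizing the SSE of A * exp(-b * u) over a
# (A, b) grid; independent check on the nonlinear least-squares fitter.
grid_search_loss_fit <- function(u, R, A_range = c(0.8, 1.2),
                                 b_range = c(1e7, 5e7), n_grid = 201) {
  A_grid <- seq(A_range[1], A_range[2], length.out = n_grid)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (A in A_grid) {
    for (b in b_grid) {
      sse <- sum((R - A * exp(-b * u))^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(A, b) }
    }
  }
  list(A = best[1], b = best[2], sse = best_sse)
}

# Same idea for R(t) = R0 * exp(-t / tau).
grid_search_exp_fit <- function(t, R, R0_range, tau_range, n_grid = 201) {
  R0_grid <- seq(R0_range[1], R0_range[2], length.out = n_grid)
  tau_grid <- seq(tau_range[1], tau_range[2], length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (R0 in R0_grid) {
    for (tau in tau_grid) {
      sse <- sum((R - R0 * exp(-t / tau))^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(R0, tau) }
    }
  }
  list(R0 = best[1], tau = best[2], sse = best_sse)
}
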