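# Independent numeric oracles used across the suite.

# Fixed-step fourth-order Runge-Kutta integration of the one-compartment
# ODE, independent of the package's closed-form solver. Integration is
# restarted at exposure breakpoints (and requested output times) so the
# classical-order accuracy is retained under discontinuous forcing.
rk4_trajectory <- function(ku, ke, cw_fun, cint0, times, step = 0.01,
                           breaks = numeric(0)) {
  deriv <- function(t, y) ku * cw_fun(t) - ke * y
  knots <- sort(unique(c(times, breaks[breaks <= max(times)])))
  y <- cint0
  vals <- stats::setNames(numeric(length(knots)), knots)
  t_cur <- knots[1]
  vals[1] <- if (knots[1] == 0) cint0 else NA
  for (k in seq_along(knots)[-1]) {
    t1 <- knots[k]
    # left-continuous forcing within the interval, so the k4 stage at the
    # right endpoint does not sample the next segment of a step input
    dseg <- function(t, y) ku * cw_fun(min(t, t1 - 1e-9)) - ke * y
    n <- max(1L, ceiling((t1 - t_cur) / step))
    h <- (t1 - t_cur) / n
    for (j in seq_len(n)) {
      t0 <- t_cur + (j - 1) * h
      k1 <- dseg(t0, y)
      k2 <- dseg(t0 + h / 2, y + h / 2 * k1)
      k3 <- dseg(t0 + h / 2, y + h / 2 * k2)
      k4 <- dseg(t0 + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    vals[k] <- y
    t_cur <- t1
  }
  unname(vals[as.character(times)])
}

# Numeric cumulative hazard by adaptive quadrature on a Cint function.
# The integrand max(Cint - c_it, 0) has kinks at trajectory knots and at
# threshold crossings; integration is split there so each piece is smooth
# (plain adaptive quadrature does not reach tight tolerances across kinks).
quad_hazard <- function(c_it, kk, h0, cint_fun, t, knots = numeric(0)) {
  g <- function(s) cint_fun(s) - c_it
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    pts <- sort(unique(c(0, knots[knots > 0 & knots < tt], tt)))
    cross <- numeric(0)
    for (k in seq_len(length(pts) - 1L)) {
      probe <- seq(pts[k], pts[k + 1L], length.out = 9)
      sg <- sign(g(probe))
      flip <- which(sg[-1] * sg[-length(sg)] < 0)
      for (j in flip)
        cross <- c(cross, stats::uniroot(g, c(probe[j], probe[j + 1]),
                                         tol = 1e-13)$root)
    }
    pts <- sort(unique(c(pts, cross)))
    area <- 0
    for (k in seq_len(length(pts) - 1L)) {
      area <- area + stats::integrate(function(s) pmax(g(s), 0),
                                      pts[k], pts[k + 1L], abs.tol = 1e-12,
                                      subdivisions = 200L)$value
    }
    h0 * tt + kk * area
  }, 0)
}

# Random exposure profile draw (all three modes).
random_profile <- function() {
  mode <- sample(c("constant", "piecewise_constant", "piecewise_linear"), 1)
  if (mode == "constant") return(exposure_profile(0, runif(1, 0, 300)))
  k <- sample(2:4, 1)
  b <- c(0, sort(runif(k - 1, 1, 40)))
  exposure_profile(b, runif(k, 0, 300), mode = mode)
}

# Noise-free pooled survival fractions at given times for a treatment.
survival_fractions <- function(tk, td, cw, times, n0 = 1e6) {
  sol_S <- survival_prob(td, simulate_trajectory(tk, exposure_profile(0, cw),
                                                 0, range(times)), times)
  alive <- rev(cummax(rev(round(sol_S * n0))))
  data.frame(time_h = times, n_alive = alive, replicate = 1L)
}

table1_truth <- ground_truth()
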