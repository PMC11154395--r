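# Threshold-hazard (stochastic-death) toxicodynamics:
#   dH/dt = kk * max(Cint(t) - C_IT, 0) + h0,   S(t) = exp(-H(t))
# Hazard accrues in proportion to the tissue concentration in excess of the
# internal threshold C_IT. Integration is exact (piecewise analytic) for
# trajectories produced by the toxicokinetic solver and for sampled
# piecewise-linear trajectories; arbitrary Cint functions fall back to
# adaptive quadrature.

#' Toxicodynamic parameters
#'
#' @param c_it Internal threshold concentration, ug/g dry weight (>= 0).
#'   No hazard accrues while the tissue concentration is below it.
#' @param kk Killing rate: hazard per unit of above-threshold tissue
#'   concentration per hour, (ug/g)^-1 h^-1 (>= 0).
#' @param h0 Background hazard rate, h^-1 (default 0: no control mortality).
#' @return An object of class `"td_params"`.
#' @export
td_params <- function(c_it, kk, h0 = 0) {
  stopifnot(is.numeric(c_it), is.numeric(kk), is.numeric(h0),
            length(c_it) == 1L, length(kk) == 1L, length(h0) == 1L)
  if (c_it < 0 || is.na(c_it)) stop("c_it must be >= 0")
  if (!is.finite(kk) || kk < 0) stop("kk must be finite and >= 0")
  if (!is.finite(h0) || h0 < 0) stop("h0 must be finite and >= 0")
  structure(list(c_it = c_it, kk = kk, h0 = h0), class = "td_params")
}

#' @export
print.td_params <- function(x, ...) {
  cat(sprintf("TD parameters: C_IT = %g ug/g, kk = %g (ug/g)^-1 h^-1, h0 = %g /h\n",
              x$c_it, x$kk, x$h0))
  invisible(x)
}

# --- exact integrals of max(f(tau) - cit, 0) on [0, L] ---------------------

# f(tau) = P + Q*tau + R*exp(-ke*tau), ke > 0.
excess_integral_exp <- function(P, Q, R, ke, cit, L) {
  if (L <= 0) return(0)
  f <- function(tau) P + Q * tau + R * exp(-ke * tau) - cit
  FF <- function(tau) (P - cit) * tau + Q * tau^2 / 2 - (R / ke) * exp(-ke * tau)
  # at most one interior stationary point of f
  crit <- numeric(0)
  if (R != 0 && Q != 0 && Q / (ke * R) > 0) {
    tc <- -log(Q / (ke * R)) / ke
    if (tc > 0 && tc < L) crit <- tc
  }
  pts <- c(0, crit, L)
  roots <- numeric(0)
  for (k in seq_len(length(pts) - 1L)) {
    a <- pts[k]; b <- pts[k + 1L]
    fa <- f(a); fb <- f(b)
    if (is.na(fa) || is.na(fb)) next
    if (fa == 0) roots <- c(roots, a)
    if (fa * fb < 0) {
      if (Q == 0) {
        # constant-exposure segment: crossing has a closed form
        arg <- (cit - P) / R
        r <- -log(arg) / ke
      } else {
        r <- stats::uniroot(f, c(a, b), tol = 1e-13)$root
      }
      roots <- c(roots, r)
    }
  }
  pts <- sort(unique(c(pts, roots)))
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    a <- pts[k]; b <- pts[k + 1L]
    if (f((a + b) / 2) > 0) total <- total + (FF(b) - FF(a))
  }
  max(total, 0)
}

# f(tau) = a0 + a1*tau + a2*tau^2 (covers ke = 0 solutions and sampled
# piecewise-linear trajectories with a2 = 0).
excess_integral_poly <- function(a0, a1, a2, cit, L) {
  if (L <= 0) return(0)
  f <- function(tau) a0 + a1 * tau + a2 * tau^2 - cit
  FF <- function(tau) (a0 - cit) * tau + a1 * tau^2 / 2 + a2 * tau^3 / 3
  c0 <- a0 - cit
  roots <- if (a2 != 0) {
    disc <- a1^2 - 4 * a2 * c0
    if (disc < 0) numeric(0) else (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  } else if (a1 != 0) {
    -c0 / a1
  } else numeric(0)
  roots <- roots[roots > 0 & roots < L]
  pts <- sort(unique(c(0, roots, L)))
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    a <- pts[k]; b <- pts[k + 1L]
    if (f((a + b) / 2) > 0) total <- total + (FF(b) - FF(a))
  }
  max(total, 0)
}

# Integral of max(Cint(s) - cit, 0) over [0, t] for a compiled tk_solution.
excess_integral_solution <- function(sol, cit, t) {
  seg <- sol$segments
  ke <- sol$params$ke
  total <- 0
  for (i in seq_len(nrow(seg))) {
    if (seg$t0[i] >= t) break
    L <- min(seg$t1[i], t) - seg$t0[i]
    total <- total + if (ke > 0) {
      excess_integral_exp(seg$P[i], seg$Q[i], seg$R[i], ke, cit, L)
    } else {
      excess_integral_poly(seg$a0[i], seg$a1[i], seg$a2[i], cit, L)
    }
  }
  total
}

# Integral for a sampled trajectory interpreted as piecewise linear in time.
excess_integral_sampled <- function(times, cint, cit, t) {
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    if (times[i] >= t) break
    L <- min(times[i + 1L], t) - times[i]
    slope <- (cint[i + 1L] - cint[i]) / (times[i + 1L] - times[i])
    total <- total + excess_integral_poly(cint[i], slope, 0, cit, L)
  }
  total
}

#' Cumulative hazard from copper exposure
#'
#' Computes `H(t) = h0*t + kk * integral of max(Cint(s) - c_it, 0) ds` over
#' `[0, t]`.
#'
#' @param td A [td_params()] object.
#' @param trajectory A `"tissue_trajectory"` from [simulate_trajectory()]
#'   (integrated exactly via its piecewise-analytic solution), a plain
#'   data.frame/list with `times` and `cint` (interpreted as piecewise
#'   linear; `t` must lie within the sampled range), or a function of time
#'   (integrated by adaptive quadrature, absolute tolerance 1e-8).
#' @param t Time(s) in hours at which to evaluate the hazard.
#' @return Dimensionless cumulative hazard H(t), vectorised over `t`.
#' @export
hazard <- function(td, trajectory, t) {
  stopifnot(inherits(td, "td_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  excess <- if (inherits(trajectory, "tissue_trajectory")) {
    vapply(t, function(tt) excess_integral_solution(trajectory$solution,
                                                    td$c_it, tt), 0)
  } else if (inherits(trajectory, "tk_solution")) {
    vapply(t, function(tt) excess_integral_solution(trajectory, td$c_it, tt), 0)
  } else if (is.function(trajectory)) {
    vapply(t, function(tt) {
      if (tt == 0) return(0)
      stats::integrate(function(s) pmax(trajectory(s) - td$c_it, 0), 0, tt,
                       abs.tol = 1e-8, subdivisions = 500L)$value
    }, 0)
  } else if (!is.null(trajectory$times) && !is.null(trajectory$cint)) {
    if (any(t > max(trajectory$times)))
      stop("t outside the support of the sampled trajectory")
    vapply(t, function(tt) excess_integral_sampled(trajectory$times,
                                                   trajectory$cint,
                                                   td$c_it, tt), 0)
  } else {
    stop("unsupported trajectory representation")
  }
  td$h0 * t + td$kk * excess
}

#' Survival probability under the threshold-hazard model
#'
#' `S(t) = exp(-H(t))` with H the cumulative hazard of [hazard()].
#'
#' @inheritParams hazard
#' @return Survival probability in (0, 1], vectorised over `t`.
#' @export
survival_prob <- function(td, trajectory, t) {
  exp(-hazard(td, trajectory, t))
}

#' Control-group survival
#'
#' Survival in unexposed controls, `S0(t) = exp(-h0*t)`. With the default
#' background hazard of zero (no control mortality) this is identically 1.
#'
#' @param h0 Background hazard rate, h^-1.
#' @param t Time(s), hours, >= 0.
#' @return Survival probability.
#' @export
control_survival <- function(h0, t) {
  stopifnot(is.numeric(h0), is.numeric(t))
  if (h0 < 0) stop("h0 must be >= 0")
  if (any(t < 0)) stop("t must be non-negative")
  exp(-h0 * t)
}
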