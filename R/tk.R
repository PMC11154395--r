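# One-compartment toxicokinetics:
#   dCint/dt = ku * Cw(t) - ke * Cint(t),  Jint(t) = ku * Cw(t)
# with Cint the tissue concentration (ug/g dry weight), ku the uptake rate
# constant (L/g/h) and ke the first-order elimination rate constant (1/h).
# All solutions are closed-form, composed segment by segment over intervals
# on which Cw is affine in time.

#' Toxicokinetic parameters
#'
#' @param ku Uptake rate constant, L g^-1 h^-1 (must be > 0).
#' @param ke Elimination rate constant, h^-1 (>= 0; the `ke = 0` limit is
#'   handled analytically throughout).
#' @return An object of class `"tk_params"`.
#' @export
tk_params <- function(ku, ke) {
  stopifnot(is.numeric(ku), is.numeric(ke), length(ku) == 1L, length(ke) == 1L)
  if (!is.finite(ku) || ku <= 0) stop("ku must be finite and > 0")
  if (!is.finite(ke) || ke < 0) stop("ke must be finite and >= 0")
  structure(list(ku = ku, ke = ke), class = "tk_params")
}

#' @export
print.tk_params <- function(x, ...) {
  cat(sprintf("TK parameters: ku = %g L/g/h, ke = %g /h (%g /d)\n",
              x$ku, x$ke, x$ke * 24))
  invisible(x)
}

#' Tissue concentration under constant exposure
#'
#' Closed-form solution of the one-compartment model for a constant water
#' concentration: `(ku*cw/ke) * (1 - exp(-ke*t)) + cint0 * exp(-ke*t)`,
#' with the linear-accumulation limit `cint0 + ku*cw*t` when `ke = 0`.
#'
#' @param params A [tk_params()] object.
#' @param cw Constant water concentration, ug/L.
#' @param cint0 Initial tissue concentration, ug/g (default 0; the tracer
#'   has no background after correction).
#' @param t Time(s) in hours, >= 0 (vectorised).
#' @return Tissue concentration(s), ug/g dry weight.
#' @export
cint_constant_cw <- function(params, cw, cint0 = 0, t) {
  stopifnot(inherits(params, "tk_params"), is.numeric(cw), is.numeric(t))
  if (cw < 0) stop("cw must be non-negative")
  if (any(t < 0)) stop("t must be non-negative")
  ku <- params$ku; ke <- params$ke
  if (ke == 0) return(cint0 + ku * cw * t)
  ss <- ku * cw / ke
  ss + (cint0 - ss) * exp(-ke * t)
}

#' Instantaneous uptake rate
#'
#' `Jint = ku * Cw`: the influx of Cu into tissue per unit dry weight.
#'
#' @inheritParams cint_constant_cw
#' @return Uptake rate, ug g^-1 h^-1.
#' @export
uptake_rate <- function(params, cw) {
  stopifnot(inherits(params, "tk_params"), is.numeric(cw))
  if (any(cw < 0)) stop("cw must be non-negative")
  params$ku * cw
}

#' Tissue concentration during depuration in clean water
#'
#' With `Cw = 0` the model reduces to pure first-order elimination,
#' `cint0 * exp(-ke*t)`.
#'
#' @inheritParams cint_constant_cw
#' @param t Time since transfer to clean water, hours.
#' @return Tissue concentration(s), ug/g.
#' @export
depuration <- function(params, cint0, t) {
  stopifnot(inherits(params, "tk_params"), is.numeric(cint0), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  cint0 * exp(-params$ke * t)
}

# Internal: compile the piecewise-analytic solution for an exposure profile.
# On each segment Cw(tau) = c + m*tau (tau = t - t0) and, propagating the
# initial condition across boundaries,
#   ke > 0: Cint(tau) = P + Q*tau + R*exp(-ke*tau)
#           P = ku*c/ke - ku*m/ke^2, Q = ku*m/ke, R = Cint(t0) - P
#   ke = 0: Cint(tau) = a0 + a1*tau + a2*tau^2
#           a0 = Cint(t0), a1 = ku*c, a2 = ku*m/2
# The trajectory is continuous at segment boundaries by construction.
tk_solution <- function(params, exposure, cint0 = 0) {
  stopifnot(inherits(params, "tk_params"), inherits(exposure, "exposure_profile"))
  if (!is.finite(cint0) || cint0 < 0) stop("cint0 must be finite and >= 0")
  seg <- cw_segments(exposure)
  ku <- params$ku; ke <- params$ke
  n <- nrow(seg)
  cint_a <- numeric(n)
  cint_a[1] <- cint0
  if (ke > 0) {
    P <- ku * seg$c / ke - ku * seg$m / ke^2
    Q <- ku * seg$m / ke
    R <- numeric(n)
    for (i in seq_len(n)) {
      R[i] <- cint_a[i] - P[i]
      if (i < n) {
        L <- seg$t1[i] - seg$t0[i]
        cint_a[i + 1] <- P[i] + Q[i] * L + R[i] * exp(-ke * L)
      }
    }
    seg$P <- P; seg$Q <- Q; seg$R <- R
  } else {
    a1 <- ku * seg$c
    a2 <- ku * seg$m / 2
    for (i in seq_len(n)) {
      if (i < n) {
        L <- seg$t1[i] - seg$t0[i]
        cint_a[i + 1] <- cint_a[i] + a1[i] * L + a2[i] * L^2
      }
    }
    seg$a0 <- cint_a; seg$a1 <- a1; seg$a2 <- a2
  }
  seg$cint_a <- cint_a
  structure(list(segments = seg, params = params, exposure = exposure,
                 cint0 = cint0), class = "tk_solution")
}

# Internal: evaluate a compiled solution at arbitrary times (vectorised).
cint_at <- function(sol, t) {
  stopifnot(inherits(sol, "tk_solution"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  seg <- sol$segments
  ke <- sol$params$ke
  i <- pmin(findInterval(t, seg$t0), nrow(seg))
  tau <- t - seg$t0[i]
  if (ke > 0) {
    seg$P[i] + seg$Q[i] * tau + seg$R[i] * exp(-ke * tau)
  } else {
    seg$a0[i] + seg$a1[i] * tau + seg$a2[i] * tau^2
  }
}

#' Simulate a tissue-concentration trajectory
#'
#' Composes the closed-form one-compartment solution across the affine
#' segments of an exposure profile and evaluates it at the requested times.
#'
#' @inheritParams cint_constant_cw
#' @param exposure An [exposure_profile()].
#' @param times Ascending observation times, hours.
#' @return An object of class `"tissue_trajectory"`: a list with `times`,
#'   `cint` (ug/g), `params`, and the compiled piecewise-analytic solution
#'   in `solution` (used downstream for exact hazard integration).
#' @examples
#' p <- tk_params(ku = 0.307, ke = 0.0582 / 24)
#' uptake_then_depuration <- exposure_profile(c(0, 12), c(15, 0),
#'                                            mode = "piecewise_constant")
#' tr <- simulate_trajectory(p, uptake_then_depuration,
#'                           times = c(0, 3, 6, 9, 12, 24, 48, 96, 180))
#' plot(tr)
#' @export
simulate_trajectory <- function(params, exposure, cint0 = 0, times) {
  stopifnot(is.numeric(times))
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = FALSE)) stop("times must be ascending")
  sol <- tk_solution(params, exposure, cint0)
  structure(list(times = times, cint = cint_at(sol, times),
                 params = params, solution = sol),
            class = "tissue_trajectory")
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  cat(sprintf("Tissue trajectory: %d time points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  print(x$params)
  invisible(x)
}

#' @export
plot.tissue_trajectory <- function(x, ...,
                                   xlab = "time (h)",
                                   ylab = expression(C[int] ~ (mu * g ~ g^-1)),
                                   type = "l") {
  tt <- seq(min(x$times), max(x$times), length.out = 400)
  graphics::plot(tt, cint_at(x$solution, tt), type = type,
                 xlab = xlab, ylab = ylab, ...)
  graphics::points(x$times, x$cint)
  invisible(x)
}

#' @export
as.data.frame.tissue_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, cint_ug_per_g = x$cint)
}
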