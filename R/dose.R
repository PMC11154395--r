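# Derived dose-response quantities: Michaelis-Menten saturation of the
# uptake rate versus dissolved Cu, and LC50 estimation (model-implied from
# fitted TK-TD parameters, and generic probit regression on mortality
# counts).

#' Michaelis-Menten uptake parameters
#'
#' @param jmax Maximal uptake rate, ug g^-1 h^-1 (> 0).
#' @param km Half-saturation water concentration, ug/L (> 0).
#' @return An object of class `"mm_params"`.
#' @export
mm_params <- function(jmax, km) {
  stopifnot(is.numeric(jmax), is.numeric(km))
  if (jmax <= 0 || km <= 0) stop("jmax and km must be > 0")
  structure(list(jmax = jmax, km = km), class = "mm_params")
}

#' Evaluate the Michaelis-Menten uptake curve
#'
#' `Jint(cw) = jmax * cw / (km + cw)`.
#'
#' @param mm An [mm_params()] object.
#' @param cw Water concentration(s), ug/L (>= 0).
#' @return Uptake rate(s), ug g^-1 h^-1.
#' @export
mm_evaluate <- function(mm, cw) {
  stopifnot(inherits(mm, "mm_params"), is.numeric(cw))
  if (any(cw < 0)) stop("cw must be non-negative")
  mm$jmax * cw / (mm$km + cw)
}

#' Fit the Michaelis-Menten uptake curve
#'
#' Nonlinear least squares of measured uptake rates against dissolved Cu.
#'
#' @param cw Water concentrations, ug/L (at least 3 distinct values).
#' @param jint Measured uptake rates, ug g^-1 h^-1.
#' @return A `"tktd_fit"` with estimates `jmax` and `km`. If the data show
#'   no curvature (effectively linear in `cw`), `km` is unbounded from the
#'   data; the fit is flagged via attribute `non_saturating` and a warning.
#' @export
fit_mm <- function(cw, jint) {
  stopifnot(is.numeric(cw), is.numeric(jint), length(cw) == length(jint))
  if (length(unique(cw)) < 3)
    stop("underdetermined fit: need >= 3 distinct water concentrations")
  init <- c(jmax = 1.2 * max(jint), km = stats::median(cw))
  fit <- lm_fit(function(par) par[["jmax"]] * cw / (par[["km"]] + cw) - jint,
                init, lower = 1e-12)
  non_sat <- fit$estimates[["km"]] > 100 * max(cw)
  if (non_sat)
    warning("uptake is effectively linear in cw over the observed range; ",
            "km is not bounded by the data")
  attr(fit, "non_saturating") <- non_sat
  fit
}

#' Model-implied LC50 from fitted TK-TD parameters
#'
#' Finds the constant water concentration at which model survival after
#' `duration` hours equals 0.5, by bisection on
#' `Cw -> S(duration | constant Cw)` with the tissue trajectory started at
#' zero. A declining-exposure variant is obtained by passing a `profile`
#' whose values are scaled multiplicatively by the candidate Cw.
#'
#' @param tk A [tk_params()] object.
#' @param td A [td_params()] object.
#' @param duration Test duration, hours (96 for the standard acute test).
#' @param bracket Length-2 vector `[lo, hi]` of water concentrations, ug/L,
#'   that must straddle 50% survival.
#' @param profile Optional unit [exposure_profile()]; candidate exposures
#'   are `value * profile`. Default: constant exposure.
#' @param tol Bisection tolerance on Cw, ug/L.
#' @return LC50 in ug/L.
#' @export
lc50_model <- function(tk, td, duration = 96, bracket, profile = NULL,
                       tol = 1e-3) {
  stopifnot(inherits(tk, "tk_params"), inherits(td, "td_params"),
            is.numeric(bracket), length(bracket) == 2L, bracket[1] < bracket[2],
            duration > 0)
  surv_at <- function(cw) {
    expo <- if (is.null(profile)) {
      exposure_profile(0, cw)
    } else {
      exposure_profile(profile$breakpoints, profile$values * cw,
                       mode = profile$mode)
    }
    survival_prob(td, tk_solution(tk, expo, 0), duration)
  }
  s_lo <- surv_at(bracket[1])
  s_hi <- surv_at(bracket[2])
  if (!(s_lo >= 0.5 && s_hi <= 0.5))
    stop(sprintf(paste0("bracket does not straddle 50%% survival: ",
                        "S(%g) = %.4g, S(%g) = %.4g"),
                 bracket[1], s_lo, bracket[2], s_hi))
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (surv_at(mid) >= 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Probit LC50 from mortality counts
#'
#' Maximum-likelihood probit regression of the mortality fraction on
#' log10(dose), the convention of standard acute-toxicity software.
#' `LC50 = 10^(-intercept/slope)`; the 95% confidence interval is obtained
#' by the delta method on the log10 scale.
#'
#' @param doses Water concentrations, ug/L (> 0).
#' @param n_dead Dead counts per dose at test end.
#' @param n_total Exposed counts per dose.
#' @return A list with `lc50`, `ci95` (length-2 vector), `slope`,
#'   `intercept` and the underlying `glm` fit.
#' @export
lc50_probit <- function(doses, n_dead, n_total) {
  stopifnot(is.numeric(doses), length(doses) == length(n_dead),
            length(n_dead) == length(n_total))
  if (any(doses <= 0)) stop("doses must be > 0")
  if (any(n_dead < 0) || any(n_dead > n_total)) stop("need 0 <= n_dead <= n_total")
  frac <- n_dead / n_total
  interior <- frac > 0 & frac < 1
  if (!any(interior))
    stop(errorCondition(
      paste("complete separation: every dose shows 0% or 100% mortality;",
            "an exact or adjusted method is required"),
      class = c("tktd_separation", "error", "condition")))
  ldose <- log10(doses)
  fit <- stats::glm(cbind(n_dead, n_total - n_dead) ~ ldose,
                    family = stats::binomial(link = "probit"))
  b <- stats::coef(fit)
  slope <- b[["ldose"]]; intercept <- b[["(Intercept)"]]
  log_lc50 <- -intercept / slope
  # delta method: grad of -b0/b1 wrt (b0, b1)
  g <- c(-1 / slope, intercept / slope^2)
  se <- sqrt(drop(t(g) %*% stats::vcov(fit) %*% g))
  list(lc50 = 10^log_lc50,
       ci95 = 10^(log_lc50 + c(-1, 1) * stats::qnorm(0.975) * se),
       slope = slope, intercept = intercept, fit = fit)
}
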