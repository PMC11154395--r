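# Toxicodynamic estimation: internal threshold and killing rate from
# survival counts, given the treatment's toxicokinetics.

#' Fit threshold-hazard toxicodynamic parameters
#'
#' Fits `(c_it, kk)` to observed survival against model survival computed
#' from the one-compartment tissue trajectory under the dataset's exposure.
#'
#' @param dataset A [treatment_dataset()] with non-empty survival counts.
#' @param tk A [tk_params()] object (typically this treatment's fitted `ku`
#'   with the shared `ke`).
#' @param h0_fixed Background hazard held fixed, h^-1 (default 0: no
#'   control mortality). Set `estimate_h0 = TRUE` to free it.
#' @param objective `"least_squares"` (default) fits pooled survival
#'   fractions `n_alive(t)/n0` by Levenberg-Marquardt; observed deaths are
#'   assigned to the right endpoint of their recording interval.
#'   `"multinomial_likelihood"` maximises the interval-censored death-count
#'   likelihood instead (statistically exact for count data).
#' @param estimate_h0 Also estimate the background hazard (default FALSE).
#'
#' @details If no deaths were observed the threshold is unidentifiable
#'   (only a lower bound exists); the error condition (class
#'   `"tktd_unidentifiable"`) carries that bound — the maximum tissue
#'   concentration reached over the observation window — as field
#'   `c_it_lower`.
#'
#' @return A `"tktd_fit"` with estimates `c_it` (ug/g) and `kk`
#'   ((ug/g)^-1 h^-1), plus `h0` when estimated.
#' @export
fit_td <- function(dataset, tk, h0_fixed = 0,
                   objective = c("least_squares", "multinomial_likelihood"),
                   estimate_h0 = FALSE) {
  objective <- match.arg(objective)
  stopifnot(inherits(dataset, "treatment_dataset"), inherits(tk, "tk_params"),
            is.numeric(h0_fixed), h0_fixed >= 0)
  if (!nrow(dataset$survival)) stop("dataset has no survival observations")
  surv <- pooled_survival(dataset$survival)
  sol <- tk_solution(tk, dataset$exposure, 0)
  t_max <- max(surv$time_h)
  if (all(surv$n_alive == surv$n0)) {
    cmax <- max(cint_at(sol, seq(0, t_max, length.out = 512L)))
    stop(errorCondition(
      paste0("no deaths observed: c_it is unidentifiable ",
             "(only the lower bound c_it >= ", signif(cmax, 6),
             " ug/g is supported by the data)"),
      class = c("tktd_unidentifiable", "error", "condition"),
      c_it_lower = cmax))
  }
  # initialisation: threshold at the tissue concentration when the first
  # death was recorded; a small generic killing rate
  t_first_death <- min(surv$time_h[surv$n_alive < surv$n0])
  c_it0 <- max(cint_at(sol, t_first_death), 1e-6)
  init <- c(c_it = c_it0, kk = 0.01)
  if (estimate_h0) init <- c(init, h0 = max(h0_fixed, 1e-6))
  td_of <- function(par) {
    td_params(par[["c_it"]], par[["kk"]],
              if (estimate_h0) par[["h0"]] else h0_fixed)
  }
  if (objective == "least_squares") {
    resid_fn <- function(par) {
      survival_prob(td_of(par), sol, surv$time_h) - surv$frac
    }
    fit <- lm_fit(resid_fn, init, lower = 0)
  } else {
    # interval-censored multinomial likelihood on pooled death counts
    tt <- surv$time_h
    deaths <- -diff(surv$n_alive)
    n_end <- surv$n_alive[length(tt)]
    negll <- function(par) {
      names(par) <- names(init)
      if (any(par < 0)) return(1e10)
      S <- survival_prob(td_of(par), sol, tt)
      pdie <- pmax(-diff(S), 1e-300)
      -(sum(deaths * log(pdie)) + n_end * log(max(S[length(S)], 1e-300)))
    }
    opt <- stats::optim(init, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12),
                        hessian = TRUE)
    covariance <- tryCatch(solve(opt$hessian), error = function(e) {
      matrix(NA_real_, length(init), length(init))
    })
    dimnames(covariance) <- list(names(init), names(init))
    S_hat <- survival_prob(td_of(opt$par), sol, tt)
    fit <- new_tktd_fit(
      estimates = opt$par, sds = sqrt(pmax(diag(covariance), 0)),
      rss = sum((S_hat - surv$frac)^2), n_obs = length(tt),
      n_iter = opt$counts[["function"]], converged = opt$convergence == 0,
      covariance = covariance, residuals = S_hat - surv$frac,
      message = "multinomial likelihood (Nelder-Mead)",
      extra = list(logLik = -opt$value))
  }
  attr(fit, "objective") <- objective
  fit
}
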