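# Two-stage toxicokinetic estimation: a single elimination rate constant is
# identified from all depuration series jointly (elimination is a property
# of the organism, not the treatment), then the uptake rate constant is
# fitted per treatment with ke held fixed.

#' Fit a shared elimination rate constant from depuration series
#'
#' Fits one `ke` jointly to every non-empty depuration series in `datasets`;
#' each series retains its own initial concentration at the start of
#' depuration as a nuisance parameter (`c0_<i>`).
#'
#' @param datasets A list of [treatment_dataset()] objects (a single dataset
#'   is accepted).
#' @return A `"tktd_fit"` whose estimates contain `ke` (h^-1) and one `c0`
#'   per series; the per-day value is exposed as attribute `ke_per_day`.
#' @export
fit_ke_shared <- function(datasets) {
  if (inherits(datasets, "treatment_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "treatment_dataset")))
  series <- Filter(function(d) nrow(d$depuration) > 0, datasets)
  if (!length(series))
    stop("no depuration observations in any dataset; ke is not identifiable")
  obs <- lapply(series, function(d) d$depuration)
  # log-linear initialisation from the pooled positive observations
  slopes <- vapply(obs, function(o) {
    pos <- o$cint_ug_g > 0
    if (sum(pos) < 2) return(NA_real_)
    -stats::coef(stats::lm(log(cint_ug_g) ~ time_h, data = o[pos, ]))[["time_h"]]
  }, 0)
  ke0 <- max(mean(slopes, na.rm = TRUE), 1e-5)
  if (!is.finite(ke0)) ke0 <- 1e-3
  c00 <- vapply(obs, function(o) max(mean(o$cint_ug_g[o$time_h == min(o$time_h)]),
                                     1e-12), 0)
  init <- c(ke = ke0, stats::setNames(c00, paste0("c0_", seq_along(obs))))
  resid_fn <- function(par) {
    unlist(lapply(seq_along(obs), function(j) {
      par[[paste0("c0_", j)]] * exp(-par[["ke"]] * obs[[j]]$time_h) -
        obs[[j]]$cint_ug_g
    }), use.names = FALSE)
  }
  fit <- lm_fit(resid_fn, init, lower = 0)
  attr(fit, "ke_per_day") <- ke_per_hour_to_per_day(fit$estimates[["ke"]])
  fit
}

#' Fit the uptake rate constant for one treatment
#'
#' Single-parameter least-squares fit of `ku` to the uptake-phase tissue
#' series, with the elimination rate fixed, a zero initial tissue
#' concentration (background-corrected tracer), and the treatment's
#' exposure profile.
#'
#' @param dataset A [treatment_dataset()] with non-empty uptake data.
#' @param ke_fixed Elimination rate constant held fixed, h^-1.
#' @return A `"tktd_fit"` with estimate `ku` (L/g/h).
#' @export
fit_ku <- function(dataset, ke_fixed) {
  stopifnot(inherits(dataset, "treatment_dataset"),
            is.numeric(ke_fixed), ke_fixed >= 0)
  obs <- dataset$uptake
  if (!nrow(obs)) stop("dataset has no uptake observations")
  if (all(obs$cint_ug_g == 0))
    stop("degenerate fit: all uptake observations are zero")
  t_last <- max(obs$time_h)
  cw_bar <- mean(cw_at(dataset$exposure, obs$time_h[obs$time_h > 0]))
  ku0 <- max(mean(obs$cint_ug_g[obs$time_h == t_last]) / (cw_bar * t_last),
             1e-6)
  resid_fn <- function(par) {
    sol <- tk_solution(tk_params(par[["ku"]], ke_fixed), dataset$exposure, 0)
    cint_at(sol, obs$time_h) - obs$cint_ug_g
  }
  lm_fit(resid_fn, c(ku = ku0), lower = 1e-12)
}
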