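# Whole-study model fit: the user-facing estimator tying the modules
# together. Stage 1 fits one shared elimination rate constant from all
# depuration series; stage 2 fits an uptake rate constant per treatment
# with ke fixed; stage 3 fits threshold-hazard toxicodynamics per HA level
# from the toxicity-test survival counts (using that HA level's uptake
# kinetics at the test concentration); stage 4 summarises uptake
# saturation with a Michaelis-Menten curve per HA level.

#' Fit the full toxicokinetic-toxicodynamic study model
#'
#' @param datasets List of [treatment_dataset()] objects with uptake (and,
#'   where available, depuration) observations.
#' @param tox_datasets Optional list of [treatment_dataset()] objects with
#'   survival counts (the toxicity test). Survival data found in
#'   `datasets` are used as well.
#' @param objective Objective for the toxicodynamic fits, see [fit_td()].
#' @param joint_tk If `TRUE`, refit `ku` and `ke` jointly per treatment
#'   (weakly identified unless every treatment has depuration data);
#'   default is the two-stage scheme with a shared `ke`.
#' @param lc50_duration Duration for the model-implied LC50, hours.
#'
#' @return An object of class `"tktd_study"` with components `ke_fit`,
#'   `ku_fits`, `td_fits`, `mm_fits`, `lc50`, `params_table`,
#'   `kinetics_table` and the input data; supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `plot()`, `residuals()` and `simulate()`.
#' @examples
#' des <- experiment_design(noise_cv = 0, seed = 42)
#' truth <- ground_truth()
#' fit <- fit_study(generate_uptake_depuration(des, truth))
#' coef(fit)["ke"] * 24   # shared elimination rate, per day
#' @export
fit_study <- function(datasets, tox_datasets = NULL,
                      objective = c("least_squares", "multinomial_likelihood"),
                      joint_tk = FALSE, lc50_duration = 96) {
  objective <- match.arg(objective)
  if (inherits(datasets, "treatment_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, TRUE, "treatment_dataset")))
  all_tox <- c(Filter(function(d) nrow(d$survival) > 0, datasets),
               tox_datasets)

  ke_fit <- fit_ke_shared(datasets)
  ke_h <- ke_fit$estimates[["ke"]]

  ku_fits <- list()
  for (d in datasets) {
    if (!nrow(d$uptake)) next
    key <- sprintf("ha%g_cu%g", d$ha_mg_l, d$cu_ug_l)
    ku_fits[[key]] <- if (joint_tk && nrow(d$depuration)) {
      fit_tk_joint(d)
    } else {
      fit_ku(d, ke_h)
    }
    attr(ku_fits[[key]], "ha") <- d$ha_mg_l
    attr(ku_fits[[key]], "cu") <- d$cu_ug_l
  }

  td_fits <- list()
  for (d in all_tox) {
    key <- sprintf("ha%g", d$ha_mg_l)
    ku_key <- sprintf("ha%g_cu%g", d$ha_mg_l, d$cu_ug_l)
    ku_here <- if (ku_key %in% names(ku_fits)) {
      ku_fits[[ku_key]]$estimates[["ku"]]
    } else {
      ha_keys <- names(ku_fits)[vapply(ku_fits, attr, 0, "ha") == d$ha_mg_l]
      if (!length(ha_keys))
        stop("no uptake kinetics available for the toxicity treatment HA = ",
             d$ha_mg_l)
      ku_fits[[ha_keys[length(ha_keys)]]]$estimates[["ku"]]
    }
    tk_here <- tk_params(ku_here, ke_h)
    td_fits[[key]] <- tryCatch(
      fit_td(d, tk_here, objective = objective),
      tktd_unidentifiable = function(e) e)
    attr(td_fits[[key]], "tk") <- tk_here
    attr(td_fits[[key]], "dataset") <- d
  }

  # Michaelis-Menten saturation per HA level, from Jint = ku * Cw at the
  # nominal treatment concentrations
  mm_fits <- list()
  for (ha in unique(vapply(ku_fits, attr, 0, "ha"))) {
    keys <- names(ku_fits)[vapply(ku_fits, attr, 0, "ha") == ha]
    if (length(keys) < 3) next
    cw <- vapply(ku_fits[keys], attr, 0, "cu")
    jint <- vapply(ku_fits[keys], function(f) f$estimates[["ku"]], 0) * cw
    mm_fits[[sprintf("ha%g", ha)]] <-
      tryCatch(fit_mm(cw, jint), error = function(e) e)
  }

  lc50 <- vapply(names(td_fits), function(key) {
    f <- td_fits[[key]]
    if (inherits(f, "condition")) return(NA_real_)
    td_hat <- td_params(f$estimates[["c_it"]], f$estimates[["kk"]])
    tryCatch(lc50_model(attr(f, "tk"), td_hat, duration = lc50_duration,
                        bracket = c(1e-3, 1e5)),
             error = function(e) NA_real_)
  }, 0)

  out <- structure(list(ke_fit = ke_fit, ku_fits = ku_fits,
                        td_fits = td_fits, mm_fits = mm_fits, lc50 = lc50,
                        objective = objective, datasets = datasets,
                        tox_datasets = all_tox,
                        lc50_duration = lc50_duration),
                   class = "tktd_study")
  out$params_table <- params_table(out)
  out$kinetics_table <- kinetics_table(out)
  out
}

# joint (ku, ke) fit for a single treatment with both phases observed
fit_tk_joint <- function(dataset) {
  up <- dataset$uptake
  dep <- dataset$depuration
  t_up_end <- max(up$time_h)
  resid_fn <- function(par) {
    p <- tk_params(par[["ku"]], par[["ke"]])
    sol <- tk_solution(p, dataset$exposure, 0)
    c_dep0 <- cint_at(sol, t_up_end)
    c(cint_at(sol, up$time_h) - up$cint_ug_g,
      depuration(p, c_dep0, dep$time_h) - dep$cint_ug_g)
  }
  cw_bar <- mean(cw_at(dataset$exposure, up$time_h[up$time_h > 0]))
  ku0 <- max(mean(up$cint_ug_g[up$time_h == t_up_end]) / (cw_bar * t_up_end),
             1e-6)
  lm_fit(resid_fn, c(ku = ku0, ke = 1e-3), lower = c(1e-12, 0))
}

# Table of fitted parameters: rows = HA level; columns = ku at each Cu
# level, c_it, kk (each "estimate +/- sd"); ke reported once.
params_table <- function(x) {
  has <- sort(unique(vapply(x$ku_fits, attr, 0, "ha")))
  cus <- sort(unique(vapply(x$ku_fits, attr, 0, "cu")))
  rows <- lapply(has, function(ha) {
    row <- list(ha_mg_l = ha)
    for (cu in cus) {
      key <- sprintf("ha%g_cu%g", ha, cu)
      row[[sprintf("ku_%g", cu)]] <- if (key %in% names(x$ku_fits)) {
        f <- x$ku_fits[[key]]
        fmt_pm(f$estimates[["ku"]], f$sds[["ku"]])
      } else NA_character_
    }
    tkey <- sprintf("ha%g", ha)
    f <- x$td_fits[[tkey]]
    if (!is.null(f) && !inherits(f, "condition")) {
      row$c_it <- fmt_pm(f$estimates[["c_it"]], f$sds[["c_it"]])
      row$kk <- fmt_pm(f$estimates[["kk"]], f$sds[["kk"]])
    } else {
      row$c_it <- NA_character_
      row$kk <- NA_character_
    }
    as.data.frame(row, check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "ke") <- fmt_pm(x$ke_fit$estimates[["ke"]] * 24,
                            x$ke_fit$sds[["ke"]] * 24)
  tab
}

# Table of dose metrics: rows = HA level; model LC50 and the rendered
# Michaelis-Menten curve.
kinetics_table <- function(x) {
  has <- sort(unique(c(vapply(x$ku_fits, attr, 0, "ha"))))
  rows <- lapply(has, function(ha) {
    key <- sprintf("ha%g", ha)
    mm <- x$mm_fits[[key]]
    mm_str <- jmax <- km <- NA
    if (!is.null(mm) && !inherits(mm, "condition")) {
      jmax <- mm$estimates[["jmax"]]; km <- mm$estimates[["km"]]
      mm_str <- sprintf("%s × [Cu]/(%s + [Cu])", signif(jmax, 3), signif(km, 3))
    }
    data.frame(ha_mg_l = ha,
               lc50_96h = if (key %in% names(x$lc50)) x$lc50[[key]] else NA,
               jmax = jmax, km = km, jint_curve = mm_str)
  })
  do.call(rbind, rows)
}

#' @export
print.tktd_study <- function(x, ...) {
  cat("Toxicokinetic-toxicodynamic study fit\n")
  cat(sprintf("  shared ke: %s /d\n", attr(x$params_table, "ke")))
  cat(sprintf("  %d uptake fits, %d toxicodynamic fits (%s objective)\n",
              length(x$ku_fits),
              sum(!vapply(x$td_fits, inherits, TRUE, "condition")),
              x$objective))
  print(x$params_table, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tktd_study <- function(object, ...) {
  structure(list(study = object), class = "summary.tktd_study")
}

#' @export
print.summary.tktd_study <- function(x, ...) {
  print(x$study)
  cat("\nDose metrics:\n")
  print(x$study$kinetics_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tktd_study <- function(object, ...) {
  out <- c(ke = object$ke_fit$estimates[["ke"]])
  for (key in names(object$ku_fits))
    out[[paste0("ku_", key)]] <- object$ku_fits[[key]]$estimates[["ku"]]
  for (key in names(object$td_fits)) {
    f <- object$td_fits[[key]]
    if (inherits(f, "condition")) next
    out[[paste0("c_it_", key)]] <- f$estimates[["c_it"]]
    out[[paste0("kk_", key)]] <- f$estimates[["kk"]]
  }
  out
}

#' @export
residuals.tktd_study <- function(object, ...) {
  unlist(c(list(ke = object$ke_fit$residuals),
           lapply(object$ku_fits, residuals),
           lapply(Filter(function(f) !inherits(f, "condition"),
                         object$td_fits), residuals)))
}

#' Predict tissue concentration or survival from a fitted study
#'
#' @param object A `"tktd_study"`.
#' @param ha,cu Treatment to predict for.
#' @param times Prediction times, hours.
#' @param type `"cint"` (tissue concentration from the fitted kinetics) or
#'   `"survival"` (model survival from the fitted TD parameters of that HA
#'   level).
#' @param ... Unused.
#' @return data.frame with `time_h` and the predicted quantity.
#' @export
predict.tktd_study <- function(object, ha, cu, times,
                               type = c("cint", "survival"), ...) {
  type <- match.arg(type)
  key <- sprintf("ha%g_cu%g", ha, cu)
  if (!key %in% names(object$ku_fits))
    stop("no fitted kinetics for treatment ", key)
  kf <- object$ku_fits[[key]]
  ke_h <- if ("ke" %in% names(kf$estimates)) kf$estimates[["ke"]] else
    object$ke_fit$estimates[["ke"]]
  tk <- tk_params(kf$estimates[["ku"]], ke_h)
  sol <- tk_solution(tk, exposure_profile(0, cu), 0)
  if (type == "cint")
    return(data.frame(time_h = times, cint_ug_g = cint_at(sol, times)))
  tf <- object$td_fits[[sprintf("ha%g", ha)]]
  if (is.null(tf) || inherits(tf, "condition"))
    stop("no toxicodynamic fit for HA = ", ha)
  td <- td_params(tf$estimates[["c_it"]], tf$estimates[["kk"]])
  data.frame(time_h = times,
             survival_prob = survival_prob(td, sol, times))
}

#' @export
plot.tktd_study <- function(x, which = c("uptake", "survival"), ...) {
  which <- match.arg(which)
  if (which == "uptake") {
    d <- x$datasets[[1]]
    key <- sprintf("ha%g_cu%g", d$ha_mg_l, d$cu_ug_l)
    tk <- tk_params(x$ku_fits[[key]]$estimates[["ku"]],
                    x$ke_fit$estimates[["ke"]])
    tr <- simulate_trajectory(tk, d$exposure, 0,
                              seq(0, max(d$uptake$time_h), length.out = 200))
    graphics::plot(d$uptake$time_h, d$uptake$cint_ug_g,
                   xlab = "time (h)",
                   ylab = expression(C[int] ~ (mu * g ~ g^-1)), ...)
    graphics::lines(tr$times, tr$cint)
  } else {
    fs <- Filter(function(f) !inherits(f, "condition"), x$td_fits)
    if (!length(fs)) stop("no toxicodynamic fits to plot")
    f <- fs[[1]]
    d <- attr(f, "dataset")
    surv <- pooled_survival(d$survival)
    td <- td_params(f$estimates[["c_it"]], f$estimates[["kk"]])
    sol <- tk_solution(attr(f, "tk"), d$exposure, 0)
    tt <- seq(0, max(surv$time_h), length.out = 200)
    graphics::plot(surv$time_h, surv$frac, ylim = c(0, 1),
                   xlab = "time (h)", ylab = "survival", ...)
    graphics::lines(tt, survival_prob(td, sol, tt))
  }
  invisible(x)
}

#' Simulate virtual experiments from a fitted study
#'
#' Re-generates uptake/depuration and toxicity datasets using the fitted
#' parameters as ground truth (a parametric-bootstrap building block).
#'
#' @param object A `"tktd_study"`.
#' @param nsim Number of replicate virtual studies.
#' @param seed Integer seed.
#' @param design An [experiment_design()] giving schedules and noise; its
#'   seed is advanced per replicate.
#' @param ... Unused.
#' @return A list of length `nsim`; each element has `uptake` and
#'   `toxicity` dataset lists.
#' @export
simulate.tktd_study <- function(object, nsim = 1, seed = 1L,
                                design = experiment_design(), ...) {
  truth <- as_ground_truth(object, design)
  lapply(seq_len(nsim), function(i) {
    des <- design
    des$seed <- as.integer(seed + (i - 1L))
    list(uptake = generate_uptake_depuration(des, truth),
         toxicity = generate_toxicity(des, truth))
  })
}

# Convert fitted estimates into a ground_truth object on the design's grid
# (fills treatments missing a fit with NA-safe fallbacks).
as_ground_truth <- function(x, design) {
  has <- design$ha_levels; cus <- design$cu_levels
  ku <- matrix(NA_real_, length(has), length(cus),
               dimnames = list(as.character(has), as.character(cus)))
  for (key in names(x$ku_fits)) {
    ha <- attr(x$ku_fits[[key]], "ha"); cu <- attr(x$ku_fits[[key]], "cu")
    if (as.character(ha) %in% rownames(ku) && as.character(cu) %in% colnames(ku))
      ku[as.character(ha), as.character(cu)] <- x$ku_fits[[key]]$estimates[["ku"]]
  }
  if (any(is.na(ku))) stop("fitted study does not cover the design grid")
  td <- do.call(rbind, lapply(has, function(ha) {
    f <- x$td_fits[[sprintf("ha%g", ha)]]
    if (is.null(f) || inherits(f, "condition"))
      stop("no toxicodynamic fit for HA = ", ha)
    data.frame(ha_mg_l = ha, c_it = f$estimates[["c_it"]],
               kk = f$estimates[["kk"]], h0 = 0)
  }))
  ground_truth(ku = ku, ke_h = x$ke_fit$estimates[["ke"]], td = td)
}
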