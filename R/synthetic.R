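# Seeded generator of virtual uptake/depuration and toxicity experiments
# with the study design used throughout the package: 4 humic-acid levels,
# 3 tracer Cu levels, 12-h uptake sampled every 3 h (n = 6 tissue
# measurements per point), 168-h depuration for the lowest Cu level, and a
# 96-h toxicity test with 3 x 20 individuals at the highest Cu level.
# Concentration measurements carry multiplicative unit-mean lognormal
# noise; deaths are binomial draws from the model's conditional interval
# mortality.

#' Experimental design of a virtual exposure study
#'
#' @param ha_levels Nominal humic-acid levels, mg/L.
#' @param doc_map Measured dissolved-organic-carbon level (mg/L) for each
#'   nominal HA level.
#' @param cu_levels Nominal dissolved 65Cu levels, ug/L.
#' @param uptake_times Tissue sampling times during the exposure phase, h.
#' @param depuration_times Sampling times after transfer to clean water, h
#'   (applied to the lowest Cu level only, matching the study design).
#' @param depuration_cu Cu level(s) whose groups enter depuration.
#' @param tissue_n Tissue measurements per time point (2 individuals x 3
#'   replicate tanks by default).
#' @param tox_cu Cu level of the toxicity test, ug/L.
#' @param tox_n0 Individuals per replicate at the start of the toxicity test.
#' @param tox_replicates Number of replicate tanks in the toxicity test.
#' @param tox_duration Toxicity-test duration, h.
#' @param tox_check_interval Mortality recording interval, h (the study
#'   recorded every 6-8 h; 8 h is the deterministic default).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise on concentrations.
#' @param cw_loss_rate Optional first-order loss rate of dissolved Cu from
#'   the unreplaced medium, h^-1 (0 = constant exposure).
#' @param seed Integer seed making every generated dataset reproducible.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(ha_levels = c(0, 5, 10, 20),
                              doc_map = c(`0` = 0.58, `5` = 3.05,
                                          `10` = 5.61, `20` = 8.98),
                              cu_levels = c(15, 150, 300),
                              uptake_times = c(0, 3, 6, 9, 12),
                              depuration_times = c(12, 24, 48, 72, 120, 168),
                              depuration_cu = 15,
                              tissue_n = 6L,
                              tox_cu = 300,
                              tox_n0 = 20L,
                              tox_replicates = 3L,
                              tox_duration = 96,
                              tox_check_interval = 8,
                              noise_cv = 0.15,
                              cw_loss_rate = 0,
                              seed = 1L) {
  stopifnot(is.numeric(ha_levels), is.numeric(cu_levels),
            tissue_n >= 1L, noise_cv >= 0, cw_loss_rate >= 0,
            tox_n0 >= 1L, tox_replicates >= 1L,
            tox_check_interval > 0, tox_duration > 0)
  if (is.unsorted(uptake_times, strictly = TRUE) ||
      is.unsorted(depuration_times, strictly = TRUE))
    stop("sampling schedules must be strictly ascending")
  if (!all(as.character(ha_levels) %in% names(doc_map)))
    stop("doc_map must cover every HA level")
  structure(list(ha_levels = ha_levels, doc_map = doc_map,
                 cu_levels = cu_levels, uptake_times = uptake_times,
                 depuration_times = depuration_times,
                 depuration_cu = depuration_cu,
                 tissue_n = as.integer(tissue_n), tox_cu = tox_cu,
                 tox_n0 = as.integer(tox_n0),
                 tox_replicates = as.integer(tox_replicates),
                 tox_duration = tox_duration,
                 tox_check_interval = tox_check_interval,
                 noise_cv = noise_cv, cw_loss_rate = cw_loss_rate,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Ground-truth parameters of a virtual study
#'
#' Defaults are the package's reference best-fit parameter set for copper
#' in the razor clam: per-treatment uptake rate constants `ku` (rows = HA
#' level, columns = Cu level, L/g/h), a shared elimination rate constant
#' (0.0582/d stored as h^-1), and per-HA-level toxicodynamic parameters.
#'
#' @param ku Numeric matrix of uptake rate constants with rownames the HA
#'   levels and colnames the Cu levels.
#' @param ke_h Shared elimination rate constant, h^-1.
#' @param td data.frame with columns `ha_mg_l`, `c_it`, `kk`, `h0`.
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(ku = NULL, ke_h = 0.0582 / 24, td = NULL) {
  if (is.null(ku)) {
    ku <- matrix(c(0.307, 0.625, 0.481,
                   0.276, 0.611, 0.469,
                   0.269, 0.599, 0.406,
                   0.274, 0.578, 0.424),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("0", "5", "10", "20"),
                                 c("15", "150", "300")))
  }
  if (is.null(td)) {
    td <- data.frame(ha_mg_l = c(0, 5, 10, 20),
                     c_it = c(104, 117, 130, 140),
                     kk = c(10.6, 8.31, 8.32, 5.68),
                     h0 = 0)
  }
  stopifnot(is.matrix(ku), is.numeric(ke_h), ke_h >= 0,
            all(c("ha_mg_l", "c_it", "kk", "h0") %in% names(td)))
  structure(list(ku = ku, ke_h = ke_h, td = td), class = "ground_truth")
}

#' Look up ground-truth parameters for one treatment
#'
#' @param truth A [ground_truth()] object.
#' @param ha,cu Nominal HA (mg/L) and Cu (ug/L) levels.
#' @return `truth_tk`: a [tk_params()]; `truth_td`: a [td_params()].
#' @export
truth_tk <- function(truth, ha, cu) {
  tk_params(truth$ku[as.character(ha), as.character(cu)], truth$ke_h)
}

#' @rdname truth_tk
#' @export
truth_td <- function(truth, ha) {
  row <- truth$td[truth$td$ha_mg_l == ha, ]
  if (nrow(row) != 1L) stop("no TD truth for HA = ", ha)
  td_params(row$c_it, row$kk, row$h0)
}

# unit-mean multiplicative lognormal factors; sigma^2 = log(1 + cv^2)
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

# exposure profile for a nominal concentration under optional first-order
# loss from the unreplaced medium, discretised on the water-sampling grid
treatment_exposure <- function(cw_nominal, loss_rate, t_end) {
  if (loss_rate == 0) return(exposure_profile(0, cw_nominal))
  grid <- seq(0, t_end, by = 3)
  exposure_profile(grid, cw_nominal * exp(-loss_rate * grid),
                   mode = "piecewise_linear")
}

#' Generate virtual uptake/depuration experiments
#'
#' For every (HA, Cu) treatment, draws tissue observations around the
#' noise-free one-compartment trajectory with unit-mean lognormal noise,
#' plus water samples every 3 h; groups at `design$depuration_cu` also get
#' a depuration series. Fully reproducible from `design$seed`.
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()].
#' @return A list of [treatment_dataset()] objects, one per treatment, each
#'   carrying its water samples in attribute `"water"`.
#' @export
generate_uptake_depuration <- function(design, truth) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "ground_truth"))
  set.seed(design$seed)
  out <- list()
  reps <- rep_len(seq_len(3L), design$tissue_n)
  for (ha in design$ha_levels) {
    for (cu in design$cu_levels) {
      tk <- truth_tk(truth, ha, cu)
      expo <- treatment_exposure(cu, design$cw_loss_rate,
                                 max(design$uptake_times))
      sol <- tk_solution(tk, expo, 0)
      up <- do.call(rbind, lapply(design$uptake_times, function(tt) {
        mu <- cint_at(sol, tt)
        data.frame(time_h = tt,
                   cint_ug_g = mu * lognormal_factors(design$tissue_n,
                                                      design$noise_cv),
                   replicate = reps)
      }))
      dep <- empty_obs()
      if (cu %in% design$depuration_cu) {
        c_dep0 <- cint_at(sol, max(design$uptake_times))
        dep <- do.call(rbind, lapply(design$depuration_times, function(tt) {
          mu <- depuration(tk, c_dep0, tt)
          data.frame(time_h = tt,
                     cint_ug_g = mu * lognormal_factors(design$tissue_n,
                                                        design$noise_cv),
                     replicate = reps)
        }))
      }
      wgrid <- seq(0, max(design$uptake_times), by = 3)
      water <- data.frame(time_h = wgrid,
                          cw_ug_l = cw_at(expo, wgrid) *
                            lognormal_factors(length(wgrid), design$noise_cv))
      ds <- treatment_dataset(ha, cu, uptake = up, depuration = dep,
                              exposure = expo,
                              doc_mg_l = design$doc_map[[as.character(ha)]])
      attr(ds, "water") <- water
      out[[sprintf("ha%g_cu%g", ha, cu)]] <- ds
    }
  }
  out
}

#' Generate virtual toxicity tests
#'
#' Per HA level (at the toxicity-test Cu concentration) and per replicate
#' tank, deaths in each recording interval are binomial draws from the
#' conditional mortality `1 - S(t2)/S(t1)` of survivors at `t1`, with the
#' survival curve computed from the threshold-hazard model over the
#' treatment's tissue trajectory.
#'
#' @inheritParams generate_uptake_depuration
#' @return A list of [treatment_dataset()] objects with survival counts.
#' @export
generate_toxicity <- function(design, truth) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "ground_truth"))
  set.seed(design$seed + 1L)
  checks <- unique(c(seq(0, design$tox_duration,
                         by = design$tox_check_interval),
                     design$tox_duration))
  out <- list()
  for (ha in design$ha_levels) {
    tk <- truth_tk(truth, ha, design$tox_cu)
    td <- truth_td(truth, ha)
    expo <- treatment_exposure(design$tox_cu, design$cw_loss_rate,
                               design$tox_duration)
    sol <- tk_solution(tk, expo, 0)
    S <- survival_prob(td, sol, checks)
    surv <- do.call(rbind, lapply(seq_len(design$tox_replicates), function(r) {
      alive <- integer(length(checks))
      alive[1] <- design$tox_n0
      for (i in seq_along(checks)[-1]) {
        p_die <- if (S[i - 1] > 0) max(min(1 - S[i] / S[i - 1], 1), 0) else 1
        alive[i] <- alive[i - 1] - stats::rbinom(1L, alive[i - 1], p_die)
      }
      data.frame(time_h = checks, n_alive = alive, replicate = r)
    }))
    ds <- treatment_dataset(ha, design$tox_cu, exposure = expo,
                            survival = surv,
                            doc_mg_l = design$doc_map[[as.character(ha)]])
    out[[sprintf("ha%g_cu%g", ha, design$tox_cu)]] <- ds
  }
  out
}
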