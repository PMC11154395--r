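# End-to-end orchestration: CSV schemas in and report bundle out, plus the
# simulate -> refit -> compare ("recover") workflow used for validating the
# estimation machinery. A thin command-line wrapper over these functions
# ships in inst/cli/tktd.R.

# ---- CSV schemas ----------------------------------------------------------

#' Read tidy study tables into treatment datasets
#'
#' @param tissue Path to a tissue CSV with columns `ha_mg_l`, `cu_ug_l`,
#'   `phase` (`uptake`/`depuration`), `time_h`, `replicate`, `cint_ug_g`.
#'   Depuration `time_h` is hours since transfer to clean water.
#' @param water Optional path to a water CSV (`ha_mg_l`, `cu_ug_l`,
#'   `time_h`, `cw_ug_l`); when present, each treatment's exposure profile
#'   is the piecewise-linear interpolation of the measured means per time,
#'   otherwise the nominal `cu_ug_l` is used as a constant exposure.
#' @param survival Optional path to a survival CSV (`ha_mg_l`, `cu_ug_l`,
#'   `time_h`, `replicate`, `n_alive`).
#' @return A list of [treatment_dataset()] objects.
#' @export
read_datasets <- function(tissue, water = NULL, survival = NULL) {
  td <- read_schema(tissue, c("ha_mg_l", "cu_ug_l", "phase", "time_h",
                              "replicate", "cint_ug_g"))
  if (!all(td$phase %in% c("uptake", "depuration")))
    stop("tissue CSV `phase` must be 'uptake' or 'depuration'")
  wd <- if (!is.null(water))
    read_schema(water, c("ha_mg_l", "cu_ug_l", "time_h", "cw_ug_l"))
  sd <- if (!is.null(survival))
    read_schema(survival, c("ha_mg_l", "cu_ug_l", "time_h", "replicate",
                            "n_alive"))
  keys <- unique(rbind(td[c("ha_mg_l", "cu_ug_l")],
                       if (!is.null(sd)) sd[c("ha_mg_l", "cu_ug_l")]))
  keys <- keys[order(keys$ha_mg_l, keys$cu_ug_l), ]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    ha <- keys$ha_mg_l[i]; cu <- keys$cu_ug_l[i]
    sel <- function(d) d[d$ha_mg_l == ha & d$cu_ug_l == cu, , drop = FALSE]
    tt <- sel(td)
    expo <- exposure_profile(0, cu)
    if (!is.null(wd)) {
      ww <- sel(wd)
      if (nrow(ww)) {
        agg <- stats::aggregate(cw_ug_l ~ time_h, data = ww, FUN = mean)
        agg <- agg[order(agg$time_h), ]
        expo <- if (nrow(agg) > 1) {
          exposure_profile(agg$time_h, agg$cw_ug_l, mode = "piecewise_linear")
        } else {
          exposure_profile(0, agg$cw_ug_l)
        }
      }
    }
    surv <- empty_survival()
    if (!is.null(sd)) {
      ss <- sel(sd)
      if (nrow(ss)) surv <- ss[c("time_h", "n_alive", "replicate")]
    }
    up <- tt[tt$phase == "uptake", c("time_h", "cint_ug_g", "replicate")]
    dep <- tt[tt$phase == "depuration", c("time_h", "cint_ug_g", "replicate")]
    out[[sprintf("ha%g_cu%g", ha, cu)]] <-
      treatment_dataset(ha, cu, uptake = up, depuration = dep,
                        exposure = expo, survival = surv)
  }
  out
}

read_schema <- function(path, need) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(basename(path), " is missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Write treatment datasets to the package's CSV schemas
#'
#' Emits `tissue.csv`, `water.csv` and `survival.csv` (the schemas read by
#' [read_datasets()]) so that simulated studies round-trip through the
#' fitting pipeline unchanged.
#'
#' @param datasets List of [treatment_dataset()] objects (e.g. from
#'   [generate_uptake_depuration()] and [generate_toxicity()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_datasets <- function(datasets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tissue <- list(); water <- list(); surv <- list()
  for (d in datasets) {
    base <- data.frame(ha_mg_l = d$ha_mg_l, cu_ug_l = d$cu_ug_l)
    if (nrow(d$uptake))
      tissue[[length(tissue) + 1L]] <- cbind(base, phase = "uptake", d$uptake)
    if (nrow(d$depuration))
      tissue[[length(tissue) + 1L]] <- cbind(base, phase = "depuration",
                                             d$depuration)
    w <- attr(d, "water")
    if (!is.null(w)) water[[length(water) + 1L]] <- cbind(base, w)
    if (nrow(d$survival))
      surv[[length(surv) + 1L]] <- cbind(base, d$survival)
  }
  paths <- character(0)
  wr <- function(lst, name) {
    if (!length(lst)) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.csv(do.call(rbind, lst), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(tissue, "tissue.csv"); wr(water, "water.csv"); wr(surv, "survival.csv")
  invisible(paths)
}

# ---- analysis driver ------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Reads raw tables (or simulates a virtual study), runs the staged TK-TD
#' fits and dose metrics, and writes a report bundle: `params_table.csv`
#' (per-HA parameter estimates with the shared elimination rate as a
#' footnote row), `kinetics_table.csv` (Michaelis-Menten curves and
#' model-implied LC50s), `survival_curves.csv`, `fit_diagnostics.csv` and
#' `run.log`. Deterministic given the configuration and seed.
#'
#' @param config A configuration list, or path to a YAML file holding one.
#'   Exactly one of `inputs` (named paths `tissue`, optionally `water`,
#'   `survival`) or `simulate` (fields passed to [experiment_design()])
#'   must be present. Optional fields: `objective`, `seed`,
#'   `output_dir`, `lc50_duration`.
#' @param output_dir Overrides `config$output_dir`.
#' @return The fitted `"tktd_study"`, invisibly, with attribute
#'   `"output_dir"`.
#' @export
run_analysis <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_inputs == has_sim)
    stop("configuration must contain exactly one of `inputs` or `simulate`")
  out_dir <- output_dir %||% config$output_dir %||%
    stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  objective <- config$objective %||% "least_squares"

  if (has_sim) {
    des_args <- config$simulate
    des_args$seed <- des_args$seed %||% seed
    design <- do.call(experiment_design, des_args)
    truth <- ground_truth()
    datasets <- generate_uptake_depuration(design, truth)
    tox <- generate_toxicity(design, truth)
  } else {
    inp <- config$inputs
    if (is.null(inp$tissue)) stop("`inputs$tissue` is required")
    if (!is.null(config$td) && isTRUE(config$td) && is.null(inp$survival))
      stop("toxicodynamic fitting requested but no survival file configured")
    datasets <- read_datasets(inp$tissue, inp$water, inp$survival)
    tox <- NULL
  }

  study <- fit_study(datasets, tox_datasets = tox, objective = objective,
                     lc50_duration = config$lc50_duration %||% 96)

  # params table with ke footnote row
  pt <- study$params_table
  foot <- pt[1, ]; foot[1, ] <- NA
  foot$ha_mg_l <- "ke (1/d)"
  foot[[2]] <- attr(pt, "ke")
  pt$ha_mg_l <- as.character(pt$ha_mg_l)
  utils::write.csv(rbind(pt, foot), file.path(out_dir, "params_table.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(study$kinetics_table,
                   file.path(out_dir, "kinetics_table.csv"),
                   row.names = FALSE, na = "")

  curves <- list()
  for (key in names(study$td_fits)) {
    f <- study$td_fits[[key]]
    if (inherits(f, "condition")) next
    d <- attr(f, "dataset")
    tt <- seq(0, max(d$survival$time_h), length.out = 97)
    td_hat <- td_params(f$estimates[["c_it"]], f$estimates[["kk"]])
    curves[[key]] <- data.frame(
      treatment = key, time_h = tt,
      survival_prob = survival_prob(td_hat,
                                    tk_solution(attr(f, "tk"), d$exposure, 0),
                                    tt))
  }
  if (length(curves))
    utils::write.csv(do.call(rbind, curves),
                     file.path(out_dir, "survival_curves.csv"),
                     row.names = FALSE)

  diag_rows <- lapply(c(list(ke = study$ke_fit), study$ku_fits,
                        Filter(function(f) !inherits(f, "condition"),
                               study$td_fits)),
                      function(f) data.frame(rss = f$rss, n_obs = f$n_obs,
                                             n_iter = f$n_iter,
                                             converged = f$converged))
  diags <- do.call(rbind, diag_rows)
  diags <- cbind(fit = rownames(diags), diags)
  utils::write.csv(diags, file.path(out_dir, "fit_diagnostics.csv"),
                   row.names = FALSE)

  writeLines(c(sprintf("tktdcu %s on R %s.%s",
                       as.character(utils::packageVersion("tktdcu")),
                       R.version$major, R.version$minor),
               sprintf("seed: %d", seed),
               sprintf("objective: %s", objective),
               sprintf("config sha: %s", config_hash(config))),
             file.path(out_dir, "run.log"))
  attr(study, "output_dir") <- out_dir
  invisible(study)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- simulate + refit + compare ------------------------------------------

#' Parameter-recovery check: simulate, refit, compare to truth
#'
#' Generates a virtual study from known parameters, refits it, and reports
#' each estimate against its generating value. Toxicodynamic parameters
#' are included only when the design's recording schedule makes them
#' identifiable (interior survival fractions exist).
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()].
#' @param sd_tol Pass criterion: `|estimate - truth| <= sd_tol * sd` for
#'   noisy runs; noise-free runs additionally require relative agreement
#'   to `rel_tol`.
#' @param rel_tol Relative tolerance applied when `design$noise_cv == 0`.
#' @return data.frame with columns `parameter`, `truth`, `estimate`, `sd`,
#'   `pass`; attribute `"all_pass"`.
#' @export
recover_study <- function(design = experiment_design(),
                          truth = ground_truth(),
                          sd_tol = 3, rel_tol = 1e-4) {
  datasets <- generate_uptake_depuration(design, truth)
  tox <- generate_toxicity(design, truth)
  study <- fit_study(datasets, tox_datasets = tox)
  rows <- list()
  add <- function(parameter, tr, est, sd) {
    pass <- is.finite(est) && abs(est - tr) <= sd_tol * max(sd, 0)
    if (design$noise_cv == 0 && grepl("^k[ue]", parameter))
      pass <- is.finite(est) && abs(est - tr) <= rel_tol * abs(tr)
    rows[[length(rows) + 1L]] <<- data.frame(parameter = parameter,
                                             truth = tr, estimate = est,
                                             sd = sd, pass = pass)
  }
  add("ke", truth$ke_h, study$ke_fit$estimates[["ke"]],
      study$ke_fit$sds[["ke"]])
  for (key in names(study$ku_fits)) {
    f <- study$ku_fits[[key]]
    tr <- truth$ku[as.character(attr(f, "ha")), as.character(attr(f, "cu"))]
    add(paste0("ku_", key), tr, f$estimates[["ku"]], f$sds[["ku"]])
  }
  for (key in names(study$td_fits)) {
    f <- study$td_fits[[key]]
    if (inherits(f, "condition")) next
    d <- attr(f, "dataset")
    surv <- pooled_survival(d$survival)
    if (!any(surv$frac > 0 & surv$frac < 1)) next  # no interior information
    tdt <- truth_td(truth, d$ha_mg_l)
    add(paste0("c_it_", key), tdt$c_it, f$estimates[["c_it"]],
        f$sds[["c_it"]])
    add(paste0("kk_", key), tdt$kk, f$estimates[["kk"]], f$sds[["kk"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}
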