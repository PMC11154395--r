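# Treatment-level data container consumed by all fitting functions.

#' Assemble one treatment's observations
#'
#' Bundles the tissue time series, depuration series, exposure profile and
#' survival counts for one (humic-acid level, Cu level) treatment.
#'
#' @param ha_mg_l Nominal humic-acid level of the treatment, mg/L.
#' @param cu_ug_l Nominal dissolved Cu level, ug/L.
#' @param uptake data.frame with columns `time_h`, `cint_ug_g`, `replicate`:
#'   tissue concentrations during the exposure phase. May be empty.
#' @param depuration data.frame with the same columns; `time_h` is hours
#'   since transfer to clean water. May be empty.
#' @param exposure An [exposure_profile()] for the exposure phase.
#' @param survival data.frame with columns `time_h`, `n_alive`, `replicate`
#'   from the toxicity test (may be empty). Counts must be non-increasing
#'   in time within each replicate.
#' @param doc_mg_l Measured dissolved organic carbon, mg/L (optional
#'   covariate carried through to reports).
#'
#' @return An object of class `"treatment_dataset"`.
#' @export
treatment_dataset <- function(ha_mg_l, cu_ug_l,
                              uptake = empty_obs(),
                              depuration = empty_obs(),
                              exposure = exposure_profile(0, cu_ug_l),
                              survival = empty_survival(),
                              doc_mg_l = NA_real_) {
  stopifnot(is.numeric(ha_mg_l), is.numeric(cu_ug_l),
            inherits(exposure, "exposure_profile"))
  for (d in list(uptake, depuration)) {
    if (nrow(d)) {
      stopifnot(all(c("time_h", "cint_ug_g", "replicate") %in% names(d)))
      if (any(d$time_h < 0)) stop("observation times must be non-negative")
      if (any(!is.finite(d$cint_ug_g)) || any(d$cint_ug_g < 0))
        stop("tissue concentrations must be finite and non-negative")
    }
  }
  if (nrow(survival)) {
    stopifnot(all(c("time_h", "n_alive", "replicate") %in% names(survival)))
    if (any(survival$time_h < 0)) stop("survival times must be non-negative")
    if (any(survival$n_alive < 0)) stop("n_alive must be non-negative")
    for (r in unique(survival$replicate)) {
      s <- survival[survival$replicate == r, ]
      s <- s[order(s$time_h), ]
      if (is.unsorted(rev(s$n_alive)))
        stop("n_alive must be non-increasing in time (replicate ", r, ")")
    }
  }
  structure(list(ha_mg_l = ha_mg_l, cu_ug_l = cu_ug_l, uptake = uptake,
                 depuration = depuration, exposure = exposure,
                 survival = survival, doc_mg_l = doc_mg_l),
            class = "treatment_dataset")
}

empty_obs <- function() {
  data.frame(time_h = numeric(0), cint_ug_g = numeric(0),
             replicate = integer(0))
}

empty_survival <- function() {
  data.frame(time_h = numeric(0), n_alive = integer(0), replicate = integer(0))
}

#' @export
print.treatment_dataset <- function(x, ...) {
  cat(sprintf("Treatment HA = %g mg/L, Cu = %g ug/L:\n", x$ha_mg_l, x$cu_ug_l))
  cat(sprintf("  %d uptake obs, %d depuration obs, %d survival records\n",
              nrow(x$uptake), nrow(x$depuration), nrow(x$survival)))
  invisible(x)
}

# Pooled survival fractions across replicates: S_obs(t) = alive(t) / n0.
pooled_survival <- function(survival) {
  agg <- stats::aggregate(n_alive ~ time_h, data = survival, FUN = sum)
  agg <- agg[order(agg$time_h), ]
  n0 <- agg$n_alive[agg$time_h == min(agg$time_h)]
  data.frame(time_h = agg$time_h, n_alive = agg$n_alive,
             frac = agg$n_alive / n0, n0 = n0)
}
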