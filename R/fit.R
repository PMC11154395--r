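# Nonlinear least-squares machinery. All model fits in the package go
# through lm_fit(), a thin contract over Levenberg-Marquardt damping
# (minpack.lm::nls.lm) that standardises initialisation, box constraints,
# convergence metadata and the classical covariance estimate
#   cov = rss/(n - p) * (J'J)^-1.

#' Levenberg-Marquardt least squares
#'
#' Minimises `sum(residual_fn(par)^2)` from a named starting point, with
#' optional box constraints.
#'
#' @param residual_fn Function mapping a named parameter vector to a
#'   numeric residual vector. Must be finite at `init`.
#' @param init Named numeric vector of starting values (within bounds).
#' @param lower,upper Optional named/unnamed bounds, recycled to the number
#'   of parameters. Defaults: unbounded.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults to
#'   `ftol = gtol = ptol = 1e-10`, `maxiter = 500`.
#'
#' @return An object of class `"tktd_fit"`: a list with `estimates`, `sds`,
#'   `rss`, `n_obs`, `n_iter`, `converged`, `covariance`, `residuals` and
#'   `message`.
#' @export
lm_fit <- function(residual_fn, init, lower = NULL, upper = NULL,
                   control = NULL) {
  stopifnot(is.function(residual_fn), is.numeric(init), length(init) >= 1L)
  if (is.null(names(init)) || any(!nzchar(names(init))))
    stop("`init` must be a fully named numeric vector")
  p <- length(init)
  lo <- if (is.null(lower)) rep(-Inf, p) else rep_len(lower, p)
  hi <- if (is.null(upper)) rep(Inf, p) else rep_len(upper, p)
  if (any(init < lo) || any(init > hi))
    stop("`init` must lie within the bounds")
  r0 <- residual_fn(init)
  if (!is.numeric(r0) || any(!is.finite(r0)))
    stop("residual_fn must return finite residuals at `init`")
  n <- length(r0)
  if (n <= p)
    stop("underdetermined fit: ", n, " observation(s) for ", p, " parameter(s)")
  if (is.null(control))
    control <- minpack.lm::nls.lm.control(ftol = 1e-10, gtol = 1e-10,
                                          ptol = 1e-10, maxiter = 500L)
  wrapped <- function(par) {
    names(par) <- names(init)
    r <- residual_fn(par)
    if (any(!is.finite(r)))
      stop("non-finite residuals at parameter vector (",
           paste(sprintf("%s = %g", names(par), par), collapse = ", "), ")")
    r
  }
  ans <- minpack.lm::nls.lm(par = init, lower = lo, upper = hi,
                            fn = wrapped, control = control)
  est <- ans$par
  names(est) <- names(init)
  rss <- ans$deviance
  covariance <- tryCatch({
    s2 <- rss / (n - p)
    s2 * solve(ans$hessian)
  }, error = function(e) {
    # singular J'J (flat directions): pseudo-inverse via SVD
    s2 <- rss / (n - p)
    sv <- svd(ans$hessian)
    pos <- sv$d > max(sv$d) * 1e-12
    inv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    s2 * inv
  })
  dimnames(covariance) <- list(names(init), names(init))
  sds <- sqrt(pmax(diag(covariance), 0))
  new_tktd_fit(estimates = est, sds = sds, rss = rss, n_obs = n,
               n_iter = ans$niter,
               converged = ans$info %in% 1:4,
               covariance = covariance,
               residuals = ans$fvec,
               message = ans$message)
}

new_tktd_fit <- function(estimates, sds, rss, n_obs, n_iter, converged,
                         covariance, residuals = NULL, message = NULL,
                         extra = list()) {
  structure(c(list(estimates = estimates, sds = sds, rss = rss,
                   n_obs = n_obs, n_iter = n_iter, converged = converged,
                   covariance = covariance, residuals = residuals,
                   message = message), extra),
            class = "tktd_fit")
}

#' @export
print.tktd_fit <- function(x, ...) {
  cat("Nonlinear least-squares fit",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  tab <- data.frame(estimate = x$estimates, sd = x$sds)
  print(tab)
  cat(sprintf("rss = %g on %d observations (%d iterations)\n",
              x$rss, x$n_obs, x$n_iter))
  invisible(x)
}

#' @export
coef.tktd_fit <- function(object, ...) object$estimates

#' @export
vcov.tktd_fit <- function(object, ...) object$covariance

#' @export
residuals.tktd_fit <- function(object, ...) object$residuals

#' @export
summary.tktd_fit <- function(object, ...) {
  z <- object$estimates / object$sds
  structure(list(fit = object,
                 table = data.frame(estimate = object$estimates,
                                    sd = object$sds, z = z)),
            class = "summary.tktd_fit")
}

#' @export
print.summary.tktd_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

# "estimate +/- sd" rendering used in report tables
fmt_pm <- function(est, sd, digits = 3) {
  sprintf("%s ± %s", signif(est, digits), signif(sd, digits))
}
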