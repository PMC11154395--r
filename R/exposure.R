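# Waterborne exposure concentration Cw(t).

#' Waterborne copper exposure profile
#'
#' Describes the dissolved Cu concentration in the exposure medium as a
#' function of time. Evaluation beyond the last breakpoint holds the final
#' value (the medium is assumed unchanged after the last observation).
#'
#' @param breakpoints Strictly ascending times in hours; the first must be 0.
#' @param values Cw at each breakpoint, ug/L (all non-negative).
#' @param mode `"constant"` (single level throughout), `"piecewise_constant"`
#'   (step changes at breakpoints) or `"piecewise_linear"` (linear
#'   interpolation between breakpoints).
#'
#' @return An object of class `"exposure_profile"`.
#' @examples
#' constant <- exposure_profile(0, 15)
#' declining <- exposure_profile(c(0, 48, 96), c(300, 250, 210),
#'                               mode = "piecewise_linear")
#' cw_at(declining, c(0, 24, 96, 200))
#' @export
exposure_profile <- function(breakpoints = 0, values,
                             mode = c("constant", "piecewise_linear",
                                      "piecewise_constant")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(breakpoints), is.numeric(values),
            length(breakpoints) == length(values), length(values) >= 1L)
  if (breakpoints[1] != 0)
    stop("the first breakpoint must be time 0")
  if (length(breakpoints) > 1L && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly ascending")
  if (any(!is.finite(values)) || any(values < 0))
    stop("exposure concentrations must be finite and non-negative")
  if (mode == "constant" && length(values) > 1L)
    stop("mode 'constant' takes a single value; use piecewise modes otherwise")
  structure(list(breakpoints = breakpoints, values = values, mode = mode),
            class = "exposure_profile")
}

#' Evaluate an exposure profile
#'
#' @param profile An [exposure_profile()].
#' @param t Times in hours (vectorised, non-negative).
#' @return Cw(t) in ug/L.
#' @export
cw_at <- function(profile, t) {
  stopifnot(inherits(profile, "exposure_profile"), is.numeric(t))
  if (any(t < 0)) stop("exposure is defined for t >= 0 only")
  b <- profile$breakpoints
  v <- profile$values
  switch(profile$mode,
    constant = rep(v[1], length(t)),
    piecewise_constant = v[pmin(findInterval(t, b), length(v))],
    piecewise_linear = stats::approx(b, v, xout = pmin(t, b[length(b)]),
                                     method = "linear", rule = 2)$y)
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("Exposure profile (", x$mode, ")\n", sep = "")
  print(data.frame(time_h = x$breakpoints, cw_ug_L = x$values),
        row.names = FALSE)
  invisible(x)
}

# Internal: decompose a profile into segments on which Cw is affine,
# c + m * (t - t0). The final segment extends to Inf at the held value.
cw_segments <- function(profile) {
  b <- profile$breakpoints
  v <- profile$values
  n <- length(b)
  if (profile$mode == "constant" || n == 1L)
    return(data.frame(t0 = 0, t1 = Inf, c = v[1], m = 0))
  if (profile$mode == "piecewise_constant") {
    return(data.frame(t0 = b, t1 = c(b[-1], Inf), c = v, m = 0))
  }
  # piecewise_linear
  m <- diff(v) / diff(b)
  data.frame(t0 = b, t1 = c(b[-1], Inf), c = v, m = c(m, 0))
}
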