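# One-compartment toxicokinetics: closed forms, piecewise composition,
# and agreement with an independent Runge-Kutta oracle.

test_that("constant-exposure closed form handles limits and matches RK4", {
  # no uptake, no loss
  p0 <- tk_params(ku = 0.3, ke = 0)
  expect_equal(cint_constant_cw(p0, cw = 0, cint0 = 5, t = c(0, 7, 100)),
               rep(5, 3))
  # linear accumulation in the ke = 0 limit
  expect_equal(cint_constant_cw(p0, cw = 10, cint0 = 0, t = 4), 12)
  # reference parameters against the RK4 oracle
  v <- cint_constant_cw(tk_params(0.307, 0.002425), cw = 15, cint0 = 0, t = 12)
  o <- rk4_trajectory(0.307, 0.002425, function(t) 15, 0, c(0, 12),
                      step = 1e-3)[2]
  expect_equal(v, o, tolerance = 1e-9)
  expect_error(cint_constant_cw(p0, 10, 0, t = -1), "non-negative")
})

test_that("uptake rate is ku * Cw", {
  expect_equal(uptake_rate(tk_params(0.307, 0.01), 0), 0)
  expect_equal(uptake_rate(tk_params(1, 0.01), 15), 15)
  expect_equal(uptake_rate(tk_params(0.481, 0.01), 300), 144.3)
})

test_that("depuration is pure exponential decay with time-shift invariance", {
  expect_equal(depuration(tk_params(1, 0), cint0 = 7, t = 100), 7)
  expect_equal(depuration(tk_params(1, 0.3), cint0 = 0, t = 5), 0)
  p <- tk_params(1, 0.002425)
  expect_equal(depuration(p, 1, 168), exp(-0.002425 * 168))
  expect_equal(depuration(p, 1, 168), 0.6654, tolerance = 1e-4)
  # depuration(t1 + t2) == depuration(depuration(t1), t2)
  for (tt in list(c(3, 9), c(50, 118), c(0.5, 0.25))) {
    expect_equal(depuration(p, 2.4, sum(tt)),
                 depuration(p, depuration(p, 2.4, tt[1]), tt[2]))
  }
})

test_that("trajectories agree with the constant-exposure closed form", {
  p <- tk_params(0.307, 0.002425)
  tr <- simulate_trajectory(p, exposure_profile(0, 15), 0, c(0, 3, 6, 9, 12))
  expect_equal(tr$cint, cint_constant_cw(p, 15, 0, c(0, 3, 6, 9, 12)))
  expect_equal(tr$cint[1], 0)
})

test_that("12-h uptake then clean water glues the two analytic branches", {
  p <- tk_params(0.307, 0.002425)
  ex <- exposure_profile(c(0, 12), c(15, 0), mode = "piecewise_constant")
  times <- c(0, 3, 6, 9, 12, 24, 48, 72, 120, 180)
  tr <- simulate_trajectory(p, ex, 0, times)
  up <- cint_constant_cw(p, 15, 0, pmin(times, 12))
  c12 <- cint_constant_cw(p, 15, 0, 12)
  dep <- depuration(p, c12, pmax(times - 12, 0))
  expect_equal(tr$cint, ifelse(times <= 12, up, dep), tolerance = 1e-12)
  # continuity at the boundary
  sol <- tr$solution
  eps <- 1e-9
  expect_equal(tktdcu:::cint_at(sol, 12 - eps), tktdcu:::cint_at(sol, 12 + eps),
               tolerance = 1e-6)
})

test_that("piecewise-analytic solutions match the RK4 oracle on random draws", {
  set.seed(11)
  for (i in 1:30) {
    ku <- runif(1, 0.05, 1)
    ke <- sample(c(0, runif(1, 1e-4, 0.2)), 1)
    prof <- random_profile()
    p <- tk_params(ku, ke)
    times <- sort(runif(6, 0, 48))
    times <- c(0, times)
    tr <- simulate_trajectory(p, prof, cint0 = runif(1, 0, 5), times = times)
    o <- rk4_trajectory(ku, ke, function(t) cw_at(prof, t), tr$solution$cint0,
                        times, step = 0.005, breaks = prof$breakpoints)
    expect_equal(tr$cint, o, tolerance = 1e-6)
  }
})

test_that("with ke = 0 accumulation equals ku times the exposure integral", {
  prof <- exposure_profile(c(0, 5, 20, 30), c(10, 120, 40, 40),
                           mode = "piecewise_linear")
  p <- tk_params(0.4, 0)
  for (tt in c(2, 5, 13, 27, 45)) {
    # quadrature split at the profile's slope breaks
    pts <- sort(unique(c(0, prof$breakpoints[prof$breakpoints < tt], tt)))
    q <- sum(vapply(seq_len(length(pts) - 1L), function(k) {
      stats::integrate(function(s) cw_at(prof, s), pts[k], pts[k + 1L],
                       abs.tol = 1e-12)$value
    }, 0))
    tr <- simulate_trajectory(p, prof, cint0 = 1, times = c(0, tt))
    expect_equal(tr$cint[2] - 1, 0.4 * q, tolerance = 1e-8)
  }
})

test_that("constant exposure from zero is monotone and capped at steady state", {
  p <- tk_params(0.5, 0.05)
  tt <- seq(0, 400, by = 2)
  v <- cint_constant_cw(p, 20, 0, tt)
  expect_true(all(diff(v) >= 0))
  ss <- 0.5 * 20 / 0.05
  expect_true(all(v <= ss + 1e-12))
  expect_equal(v[length(v)], ss, tolerance = 1e-6)
})

test_that("invalid trajectory requests are rejected", {
  p <- tk_params(0.3, 0.01)
  expect_error(simulate_trajectory(p, exposure_profile(0, 15), 0, c(3, 1)),
               "ascending")
  expect_error(simulate_trajectory(p, exposure_profile(0, 15), 0, c(-1, 1)),
               "non-negative")
  expect_error(exposure_profile(c(0, 1), c(-2, 3), mode = "piecewise_linear"),
               "non-negative")
  expect_error(exposure_profile(c(1, 2), c(1, 1), mode = "piecewise_linear"),
               "first breakpoint")
  expect_error(tk_params(0, 0.1), "ku")
  expect_error(tk_params(0.1, -1), "ke")
})
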