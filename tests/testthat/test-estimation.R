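# Nonlinear least-squares machinery and the staged TK/TD fits:
# generate-then-fit identities, guards, and seeded noisy recovery.

test_that("lm_fit reproduces ordinary least squares on a linear model", {
  x <- c(0.5, 1, 2, 3, 5, 8)
  y <- 2.4 * x
  f <- lm_fit(function(par) par[["a"]] * x - y, c(a = 1))
  expect_equal(f$estimates[["a"]], 2.4, tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-16)

  set.seed(4)
  yn <- 2.4 * x + rnorm(6, sd = 0.3)
  f <- lm_fit(function(par) par[["a"]] * x - yn, c(a = 1))
  ols <- stats::lm(yn ~ x - 1)
  expect_equal(f$estimates[["a"]], unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$sds[["a"]], unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-6)
})

test_that("lm_fit guards underdetermined and invalid setups", {
  expect_error(lm_fit(function(par) rep(0, 3),
                      c(a = 1, b = 1, c = 1, d = 1)), "underdetermined")
  expect_error(lm_fit(function(par) rep(NA_real_, 5), c(a = 1)), "finite")
  expect_error(lm_fit(function(par) 1:5, c(1)), "named")
  expect_error(lm_fit(function(par) rep(0, 5), c(a = -1), lower = 0),
               "bounds")
})

test_that("noise-free uptake/elimination data return the generating values", {
  truth <- table1_truth
  ke_h <- truth$ke_h
  des <- experiment_design(noise_cv = 0, seed = 5)
  ds <- generate_uptake_depuration(des, truth)

  kef <- fit_ke_shared(ds)
  expect_equal(kef$estimates[["ke"]], ke_h, tolerance = 1e-6)
  expect_equal(attr(kef, "ke_per_day"), 0.0582, tolerance = 1e-6)

  for (key in c("ha0_cu15", "ha0_cu150", "ha20_cu300")) {
    f <- fit_ku(ds[[key]], ke_h)
    tr <- truth$ku[as.character(ds[[key]]$ha_mg_l),
                   as.character(ds[[key]]$cu_ug_l)]
    expect_equal(f$estimates[["ku"]], tr, tolerance = 1e-5)
  }
})

test_that("joint (ku, ke) refit also recovers noise-free truth", {
  des <- experiment_design(noise_cv = 0, seed = 5)
  ds <- generate_uptake_depuration(des, table1_truth)
  study <- fit_study(ds["ha0_cu15"], joint_tk = TRUE)
  expect_equal(unname(coef(study)[["ku_ha0_cu15"]]), 0.307, tolerance = 1e-4)
  expect_equal(study$ku_fits$ha0_cu15$estimates[["ke"]], 0.0582 / 24,
               tolerance = 1e-3)
})

test_that("pooling identical depuration series leaves ke unchanged", {
  p <- tk_params(0.3, 0.002425)
  dep <- data.frame(time_h = rep(c(12, 24, 48, 72, 120, 168), each = 2),
                    replicate = 1:2)
  dep$cint_ug_g <- depuration(p, 50, dep$time_h)
  d1 <- treatment_dataset(0, 15, depuration = dep,
                          exposure = exposure_profile(0, 15))
  one <- fit_ke_shared(list(d1))
  two <- fit_ke_shared(list(d1, d1))
  expect_equal(one$estimates[["ke"]], two$estimates[["ke"]], tolerance = 1e-8)
  expect_error(fit_ke_shared(list(treatment_dataset(0, 15))),
               "no depuration")
})

test_that("doubling the water concentration halves the fitted ku", {
  des <- experiment_design(noise_cv = 0, seed = 5, cu_levels = 15,
                           ha_levels = 0)
  ds <- generate_uptake_depuration(des, table1_truth)[[1]]
  ke_h <- table1_truth$ke_h
  f1 <- fit_ku(ds, ke_h)
  ds2 <- ds
  ds2$exposure <- exposure_profile(0, 30)
  f2 <- fit_ku(ds2, ke_h)
  expect_equal(f2$estimates[["ku"]], f1$estimates[["ku"]] / 2,
               tolerance = 1e-6)
  ds0 <- ds
  ds0$uptake$cint_ug_g <- 0
  expect_error(fit_ku(ds0, ke_h), "degenerate")
})

test_that("noisy uptake fits land within 3 fitted SDs of truth", {
  des <- experiment_design(noise_cv = 0.15, seed = 99)
  ds <- generate_uptake_depuration(des, table1_truth)
  f <- fit_ku(ds[["ha0_cu15"]], table1_truth$ke_h)
  expect_lt(abs(f$estimates[["ku"]] - 0.307), 3 * f$sds[["ku"]])
})

test_that("noisy shared-ke estimates are calibrated across seeded replicates", {
  # 15% lognormal noise, n = 6 per time point, the four depuration series
  # (one per HA level at 15 ug/L) fitted jointly as in the staged estimator
  truth <- table1_truth
  truth_ke <- truth$ke_h
  runs <- vapply(1:200, function(s) {
    des <- experiment_design(noise_cv = 0.15, seed = s, cu_levels = 15)
    f <- fit_ke_shared(generate_uptake_depuration(des, truth))
    c(est = f$estimates[["ke"]], sd = f$sds[["ke"]])
  }, c(est = 0, sd = 0))
  # within the reported +/- 0.0139/d band in at least 80% of replicates
  in_band <- mean(abs(runs["est", ] - truth_ke) <= 0.0139 / 24)
  expect_gte(in_band, 0.8)
  # near-unbiased mean and honestly reported uncertainty
  expect_lt(abs(mean(runs["est", ]) - truth_ke) / truth_ke, 0.05)
  ratio <- sd(runs["est", ]) / mean(runs["sd", ])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("toxicodynamic fit recovers generating parameters from a clean curve", {
  truth <- table1_truth
  tk <- truth_tk(truth, 0, 300)
  td <- truth_td(truth, 0)
  # record survival where it is informative: the model mortality at this
  # killing rate completes within the first hour of threshold crossing
  times <- seq(0, 1.2, by = 0.02)
  surv <- survival_fractions(tk, td, 300, times)
  ds <- treatment_dataset(0, 300, exposure = exposure_profile(0, 300),
                          survival = surv)
  f <- fit_td(ds, tk)
  expect_equal(f$estimates[["c_it"]], 104, tolerance = 1e-3)
  expect_equal(f$estimates[["kk"]], 10.6, tolerance = 1e-3)

  # least-squares and multinomial objectives agree in the small-noise limit
  f2 <- fit_td(ds, tk, objective = "multinomial_likelihood")
  expect_equal(f2$estimates[["c_it"]], f$estimates[["c_it"]],
               tolerance = 1e-3)
  expect_equal(f2$estimates[["kk"]], f$estimates[["kk"]], tolerance = 1e-2)
})

test_that("all-alive survival raises an unidentifiability error with a bound", {
  tk <- tk_params(0.481, 0.002425)
  surv <- data.frame(time_h = seq(0, 96, by = 8), n_alive = 60L,
                     replicate = 1L)
  ds <- treatment_dataset(0, 300, exposure = exposure_profile(0, 300),
                          survival = surv)
  err <- tryCatch(fit_td(ds, tk), tktd_unidentifiable = function(e) e)
  expect_s3_class(err, "tktd_unidentifiable")
  cmax <- cint_constant_cw(tk, 300, 0, 96)
  expect_equal(err$c_it_lower, cmax, tolerance = 1e-4)
})

test_that("binomial survival data identify gentle toxicodynamics within 3 SDs", {
  # slower kinetics and killing rate spread deaths over several recording
  # intervals, making both parameters identifiable at an 8-h cadence
  tk <- tk_params(0.05, 0.002425)
  td <- td_params(104, 5e-4)
  sol <- simulate_trajectory(tk, exposure_profile(0, 300), 0, c(0, 96))
  checks <- seq(0, 96, by = 8)
  S <- survival_prob(td, sol, checks)
  set.seed(17)
  surv <- do.call(rbind, lapply(1:3, function(r) {
    alive <- integer(length(checks)); alive[1] <- 20L
    for (i in seq_along(checks)[-1]) {
      p_die <- 1 - S[i] / S[i - 1]
      alive[i] <- alive[i - 1] - rbinom(1, alive[i - 1], p_die)
    }
    data.frame(time_h = checks, n_alive = alive, replicate = r)
  }))
  ds <- treatment_dataset(0, 300, exposure = exposure_profile(0, 300),
                          survival = surv)
  f <- fit_td(ds, tk)
  expect_lt(abs(f$estimates[["c_it"]] - 104), 3 * f$sds[["c_it"]])
  expect_lt(abs(f$estimates[["kk"]] - 5e-4), 3 * f$sds[["kk"]])
})

test_that("recording-time jitter moves the threshold by at most the
           concentration rise over the jitter window", {
  tk <- tk_params(0.05, 0.002425)
  td <- td_params(104, 5e-4)
  times <- seq(0, 96, by = 4)
  base <- survival_fractions(tk, td, 300, times)
  ds <- treatment_dataset(0, 300, exposure = exposure_profile(0, 300),
                          survival = base)
  f0 <- fit_td(ds, tk)
  jit <- base
  jit$time_h <- jit$time_h + 2   # deaths logged two hours late
  dsj <- treatment_dataset(0, 300, exposure = exposure_profile(0, 300),
                           survival = jit)
  fj <- fit_td(dsj, tk)
  rise_2h <- uptake_rate(tk, 300) * 2
  expect_lt(abs(fj$estimates[["c_it"]] - f0$estimates[["c_it"]]),
            rise_2h + 1)
})
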