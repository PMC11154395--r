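# Seeded virtual-experiment generator: determinism, noise structure, and
# faithfulness to the forward models.

test_that("identical seeds reproduce identical datasets and files", {
  des <- experiment_design(noise_cv = 0.15, seed = 42)
  a <- generate_uptake_depuration(des, table1_truth)
  b <- generate_uptake_depuration(des, table1_truth)
  expect_identical(a, b)
  ta <- generate_toxicity(des, table1_truth)
  tb <- generate_toxicity(des, table1_truth)
  expect_identical(ta, tb)

  d1 <- tempfile(); d2 <- tempfile()
  write_datasets(c(a, ta), d1)
  write_datasets(c(b, tb), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed actually changes the draw
  c2 <- generate_uptake_depuration(experiment_design(seed = 43), table1_truth)
  expect_false(identical(a, c2))
})

test_that("zero noise reproduces the closed-form trajectory exactly", {
  des <- experiment_design(noise_cv = 0, seed = 1)
  ds <- generate_uptake_depuration(des, table1_truth)
  d <- ds[["ha0_cu15"]]
  p <- truth_tk(table1_truth, 0, 15)
  expect_equal(d$uptake$cint_ug_g,
               cint_constant_cw(p, 15, 0, d$uptake$time_h))
  c12 <- cint_constant_cw(p, 15, 0, 12)
  expect_equal(d$depuration$cint_ug_g,
               depuration(p, c12, d$depuration$time_h))
  # depuration series exist only for the 15 ug/L groups
  expect_equal(nrow(ds[["ha0_cu150"]]$depuration), 0)
  expect_gt(nrow(ds[["ha10_cu15"]]$depuration), 0)
})

test_that("measurement noise is multiplicative with unit mean", {
  set.seed(8)
  f <- tktdcu:::lognormal_factors(1e4, 0.15)
  expect_true(all(f > 0))
  expect_lt(abs(mean(f) - 1), 0.01)
  expect_lt(abs(sd(f) / mean(f) - 0.15), 0.01)
  expect_identical(tktdcu:::lognormal_factors(5, 0), rep(1, 5))
})

test_that("survival counts start at n0 and never increase", {
  des <- experiment_design(seed = 7, tox_check_interval = 6)
  tox <- generate_toxicity(des, table1_truth)
  expect_length(tox, 4L)
  for (d in tox) {
    for (r in unique(d$survival$replicate)) {
      s <- d$survival[d$survival$replicate == r, ]
      s <- s[order(s$time_h), ]
      expect_equal(s$n_alive[1], 20L)
      expect_true(all(diff(s$n_alive) <= 0))
      expect_equal(s$time_h[1], 0)
      expect_equal(max(s$time_h), 96)
    }
  }
})

test_that("an unreachable threshold yields zero deaths everywhere", {
  safe <- table1_truth
  safe$td$c_it <- 1e9
  tox <- generate_toxicity(experiment_design(seed = 3), safe)
  for (d in tox) expect_true(all(d$survival$n_alive == 20L))
})

test_that("mean simulated survival matches the model curve", {
  # gentle toxicodynamics so the survival curve declines across intervals
  truth <- ground_truth(td = data.frame(ha_mg_l = c(0, 5, 10, 20),
                                        c_it = 104, kk = 5e-4, h0 = 0))
  truth$ku[] <- 0.05
  des <- experiment_design(ha_levels = 0, seed = 1, tox_replicates = 1)
  tk <- truth_tk(truth, 0, 300)
  td <- truth_td(truth, 0)
  sol <- simulate_trajectory(tk, exposure_profile(0, 300), 0, c(0, 96))
  checks <- seq(0, 96, by = 8)
  S <- survival_prob(td, sol, checks)
  tot <- numeric(length(checks))
  n_rep <- 400
  for (s in 1:n_rep) {
    des$seed <- s
    tox <- generate_toxicity(des, truth)
    tot <- tot + tox[[1]]$survival$n_alive
  }
  frac <- tot / (n_rep * 20)
  mc_se <- sqrt(S * (1 - S) / (n_rep * 20))
  expect_true(all(abs(frac - S) <= 4 * mc_se + 1e-9))
})

test_that("optional first-order water loss produces a declining exposure", {
  des <- experiment_design(noise_cv = 0, seed = 1, cw_loss_rate = 0.01,
                           ha_levels = 0, cu_levels = 15)
  ds <- generate_uptake_depuration(des, table1_truth)[[1]]
  expect_equal(ds$exposure$mode, "piecewise_linear")
  expect_lt(cw_at(ds$exposure, 12), 15)
  # generated observations follow the declining-exposure trajectory
  p <- truth_tk(table1_truth, 0, 15)
  tr <- simulate_trajectory(p, ds$exposure, 0, unique(ds$uptake$time_h))
  expect_equal(unique(ds$uptake$cint_ug_g), tr$cint, tolerance = 1e-12)
})

test_that("design defaults carry the measured DOC map", {
  des <- experiment_design()
  expect_equal(unname(des$doc_map[as.character(c(0, 5, 10, 20))]),
               c(0.58, 3.05, 5.61, 8.98))
  ds <- generate_uptake_depuration(experiment_design(noise_cv = 0, seed = 1),
                                   table1_truth)
  expect_equal(ds[["ha10_cu15"]]$doc_mg_l, 5.61)
  expect_error(experiment_design(uptake_times = c(3, 0, 6)), "ascending")
})
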