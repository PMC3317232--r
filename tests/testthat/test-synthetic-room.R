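# Room kinetics: steady state, limits, delay, determinism, emitted-record
# statistics.

quiet_cfg <- function(seed = 101, ...) room_config(seed = seed, ...)

test_that("config validation enforces physical constraints", {
  expect_s3_class(room_config(), "room_config")
  expect_error(room_config(lambda_v_closed = -1),
               class = "radonaero_config_error")
  expect_error(room_config(lambda_d_un = 0.1, lambda_d_att = 0.2),
               class = "radonaero_config_error")
  expect_error(room_config(recoil_prob = 1.5),
               class = "radonaero_config_error")
  expect_error(room_config(c_rn = NULL),
               class = "radonaero_config_error")
  expect_error(simulate_room(room_config(), dt_s = 120),
               class = "radonaero_config_error")
  expect_error(simulate_room(room_config(), duration_h = 0.5),
               class = "radonaero_config_error")
})

test_that("no attachment means a fully unattached steady state", {
  expect_equal(steady_state_fun(quiet_cfg(beta_attach = 0)), 1.0)
  expect_equal(steady_state_fun(quiet_cfg(), s_tot = 0), 1.0)
  run <- simulate_room(quiet_cfg(beta_attach = 0), duration_h = 6)
  expect_equal(tail(run$state$f_un, 1), 1.0, tolerance = 1e-10)
})

test_that("steady-state f_un decreases in surface area, not number", {
  cfg <- quiet_cfg()
  s_grid <- seq(1e7, 5e8, length.out = 10)
  f <- vapply(s_grid, function(s) steady_state_fun(cfg, s_tot = s),
              numeric(1))
  expect_true(all(diff(f) < 0))
  expect_gt(steady_state_fun(cfg, s_tot = 1e12), 0) # stays positive

  # two spectra with identical number but different surface must differ
  g <- size_grid("medium")
  small <- radonaero:::.lognormal_mode(g, 5000, 15, 1.5)
  large <- radonaero:::.lognormal_mode(g, 5000, 150, 1.5)
  s_small <- sum(small * pi * g$d_nm^2)
  s_large <- sum(large * pi * g$d_nm^2)
  expect_lt(s_small, s_large)
  expect_gt(steady_state_fun(cfg, s_tot = s_small),
            steady_state_fun(cfg, s_tot = s_large))
})

test_that("simulation relaxes from progeny-free air to the closed-form state", {
  set.seed(61)
  for (rep in 1:2) {
    cfg <- quiet_cfg(
      c_rn = stats::runif(1, 50, 500),
      lambda_v_closed = stats::runif(1, 0.1, 1),
      beta_attach = stats::runif(1, 5e-8, 4e-7),
      lambda_d_un = stats::runif(1, 10, 30),
      lambda_d_att = stats::runif(1, 0.05, 0.5),
      recoil_prob = stats::runif(1)
    )
    run <- simulate_room(cfg, duration_h = 48, dt_s = 60, init = "zero")
    expect_equal(tail(run$state$f_un, 1), steady_state_fun(cfg),
                 tolerance = 0.01)
  }
})

test_that("overwhelming ventilation of radon-free outdoor air empties the room", {
  cfg <- quiet_cfg(c_rn = NULL, radon_entry_bq_m3_h = 100,
                   lambda_v_closed = 200, lambda_v_open = 300,
                   outdoor_n_tot = 0)
  run <- simulate_room(cfg, duration_h = 2, dt_s = 10)
  last <- tail(run$state, 1)
  expect_lt(last$c_rn, 1)        # entry/lambda_v = 0.5 Bq m^-3
  expect_lt(last$u_po218 + last$u_pb214 + last$u_bi214 +
              last$a_po218 + last$a_pb214 + last$a_bi214, 1e-4)
})

test_that("identical config and seed give identical runs", {
  cfg <- quiet_cfg()
  r1 <- simulate_room(cfg, duration_h = 3)
  r2 <- simulate_room(cfg, duration_h = 3)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$smps, r2$smps)
  expect_identical(r1$eqf, r2$eqf)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_room_run(r1, d1); write_room_run(r2, d2)
  for (f in c("smps.csv", "eqf.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the emitted records but not the true state
  r3 <- simulate_room(quiet_cfg(seed = 555), duration_h = 3)
  expect_identical(r1$state, r3$state)
  expect_false(identical(r1$smps$n_cm3, r3$smps$n_cm3))
})

test_that("f_un responds to a surface-area step with a delayed half-response", {
  # step the room into candle conditions and watch the unattached fraction
  cfg <- quiet_cfg()
  script <- event_script(1, 12, "candle")
  run <- simulate_room(cfg, script, duration_h = 12)
  st <- run$state
  f0 <- st$f_un[st$time_s == 3600]
  f_inf <- tail(st$f_un, 1)
  expect_lt(f_inf, f0) # more surface, lower f_un
  half <- f0 + (f_inf - f0) / 2
  t_half <- st$time_s[st$time_s > 3600][
    which(st$f_un[st$time_s > 3600] <= half)[1]] - 3600
  # the aerosol itself equilibrates within ~1/(k_relax+lambda_v) ~ 26 min;
  # f_un must lag further behind on the progeny mean-lives
  expect_gt(t_half, 600)
})

test_that("quiescent emitted records reproduce the configured statistics", {
  run <- simulate_room(quiet_cfg(), duration_h = 48)
  c_tot <- run$smps %>%
    dplyr::summarise(c_tot = sum(n_cm3), .by = timestamp)
  s <- gm_gsd(c_tot$c_tot)
  expect_lt(abs(s$gm / 5120 - 1), 0.05)
  expect_lt(abs(s$gsd / 1.50 - 1), 0.05)
  # true state stays put
  expect_lt(abs(tail(run$state$c_tot, 1) / 5120 - 1), 1e-6)
  # progeny records: f_un of the emitted stream scatters around the
  # closed-form steady state
  m <- progeny_metrics(run$eqf)
  expect_lt(abs(exp(mean(log(m$f_un))) / steady_state_fun(quiet_cfg()) - 1),
            0.15)
})

test_that("with no removal processes the chain reaches secular equilibrium", {
  cfg <- quiet_cfg(lambda_v_closed = 0, lambda_v_open = 0, beta_attach = 0,
                   lambda_d_un = 0, lambda_d_att = 0)
  run <- simulate_room(cfg, duration_h = 6, dt_s = 20, init = "zero")
  lam <- chain_lambdas()
  last <- tail(run$state, 1)
  a_po <- number_to_activity(last$u_po218, "po218")
  a_pb <- number_to_activity(last$u_pb214, "pb214")
  a_bi <- number_to_activity(last$u_bi214, "bi214")
  expect_equal(a_po / last$c_rn, 1, tolerance = 0.002)
  expect_equal(a_pb / last$c_rn, 1, tolerance = 0.002)
  expect_equal(a_bi / last$c_rn, 1, tolerance = 0.002)

  # and the transient matches the closed-volume Bateman ingrowth ratios
  tr <- bateman_ingrowth(last$c_rn, run$state$time_s, unit = "s")
  sim_ratio <- number_to_activity(run$state$u_pb214, "pb214") / last$c_rn
  bate_ratio <- tr$a_pb214 / tr$a_rn
  expect_lt(max(abs(sim_ratio - bate_ratio)), 0.01)
})

test_that("glance and tidy summarise a run", {
  run <- simulate_room(quiet_cfg(), duration_h = 2)
  gl <- glance(run)
  expect_equal(gl$duration_h, 2)
  expect_equal(gl$n_eqf_records, 2) # t = 0 h and t = 2 h
  long <- tidy(run)
  expect_true(all(c("time_s", "variable", "value") %in% names(long)))
})
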