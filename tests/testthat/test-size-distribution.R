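# Channel grids, spectrum summaries, surface partitions, GM/GSD statistics,
# correlation and diurnal aggregation.

test_that("channel grids are 44 log-spaced increasing channels", {
  for (rng in list("medium", "long")) {
    g <- size_grid(rng)
    expect_equal(nrow(g), 44)
    expect_true(all(diff(g$d_nm) > 0))
    expect_true(all(g$d_nm > 0))
    # log-uniform: constant log step and edges at geometric midpoints
    expect_equal(diff(range(diff(log(g$d_nm)))), 0, tolerance = 1e-12)
    expect_equal(g$d_hi[-44], g$d_lo[-1], tolerance = 1e-12)
    expect_equal(sqrt(g$d_lo * g$d_hi), g$d_nm, tolerance = 1e-12)
  }
  expect_equal(range(size_grid("medium")$d_nm), c(5, 350))
  expect_equal(range(size_grid("long")$d_nm), c(10, 1100))
  expect_error(size_grid(c(10, 5)), class = "radonaero_invalid_input")
})

test_that("spectrum summaries match direct definitions", {
  g <- size_grid("medium")
  # monodisperse at the channel nearest 100 nm
  i100 <- which.min(abs(g$d_nm - 100))
  mono <- tibble::tibble(d_nm = g$d_nm,
                         n_cm3 = replace(numeric(44), i100, 500))
  s <- summarize_spectrum(mono)
  expect_equal(s$c_tot, 500)
  expect_equal(s$d_gm_nm, g$d_nm[i100])
  expect_equal(s$x_lt_20, 0)

  # equal counts at 10 and 1000 nm: geometric symmetry about 100 nm
  two <- tibble::tibble(d_nm = c(10, 1000), n_cm3 = c(50, 50))
  expect_equal(summarize_spectrum(two)$d_gm_nm, 100, tolerance = 1e-12)

  expect_error(summarize_spectrum(
    tibble::tibble(d_nm = g$d_nm, n_cm3 = numeric(44))),
    class = "radonaero_undefined_summary")
})

test_that("summaries agree with a brute-force per-channel oracle", {
  for (seed in 1:6) {
    sp <- random_spectrum(seed)
    s <- summarize_spectrum(sp, cuts = c(10, 20))
    # oracle: plain loops over channels
    c_tot <- 0; sl <- 0
    for (i in seq_len(nrow(sp))) {
      c_tot <- c_tot + sp$n_cm3[i]
      sl <- sl + sp$n_cm3[i] * log(sp$d_nm[i])
    }
    expect_equal(s$c_tot, c_tot, tolerance = 1e-12)
    expect_equal(s$d_gm_nm, exp(sl / c_tot), tolerance = 1e-12)
    expect_equal(s$x_lt_10, sum(sp$n_cm3[sp$d_nm < 10]) / c_tot,
                 tolerance = 1e-12)
    # nested cutoffs
    expect_lte(s$x_lt_10, s$x_lt_20)
    # d_GM bounded by the grid
    expect_gte(s$d_gm_nm, min(sp$d_nm))
    expect_lte(s$d_gm_nm, max(sp$d_nm))
    # partition conserves the total
    p <- surface_partition(sp, 20)
    expect_equal(p$n_lt + p$n_gt, c_tot, tolerance = 1e-12)
    expect_equal(p$s_lt + p$s_gt,
                 sum(sp$n_cm3 * pi * sp$d_nm^2), tolerance = 1e-12)
    expect_equal(p$s_ratio,
                 sum((sp$n_cm3 * pi * sp$d_nm^2)[sp$d_nm < 20]) /
                   sum((sp$n_cm3 * pi * sp$d_nm^2)[sp$d_nm >= 20]),
                 tolerance = 1e-12)
  }
})

test_that("surface partition separates number and area dominance", {
  # equal numbers at 5 and 50 nm: number ratio 1, surface ratio (5/50)^2
  sp <- tibble::tibble(d_nm = c(5, 50), n_cm3 = c(1000, 1000))
  p <- surface_partition(sp, 10)
  expect_equal(p$n_ratio, 1.0)
  expect_equal(p$s_ratio, 0.01, tolerance = 1e-12)

  # doubling the small side doubles both ratios
  sp2 <- sp; sp2$n_cm3[1] <- 2000
  p2 <- surface_partition(sp2, 10)
  expect_equal(p2$n_ratio, 2 * p$n_ratio)
  expect_equal(p2$s_ratio, 2 * p$s_ratio)

  # candle-like burst: twice as many particles below 10 nm, yet far less
  # surface area than the accumulation mode above
  g <- size_grid("medium")
  burst <- tibble::tibble(
    d_nm = g$d_nm,
    n_cm3 = 1e4 * radonaero:::.lognormal_mode(g, 2.4, 6, 1.3) +
      1e4 * radonaero:::.lognormal_mode(g, 1, 120, 1.6)
  )
  pb <- surface_partition(burst, 10)
  expect_gt(pb$n_ratio, 1.5)
  expect_lt(pb$s_ratio, 1)

  expect_error(surface_partition(sp, 4), class = "radonaero_undefined_ratio")
  expect_error(surface_partition(sp, 1000),
               class = "radonaero_undefined_ratio")
})

test_that("dN/dln d uses the grid's log bin widths", {
  g <- size_grid("medium")
  sp <- tibble::tibble(d_nm = g$d_nm, n_cm3 = rep(1, 44))
  d <- dndlnd(sp, grid = g)
  expect_equal(d$dndlnd, 1 / g$dln_d, tolerance = 1e-12)
  # integral of dN/dln d over ln d recovers the total
  expect_equal(sum(d$dndlnd * g$dln_d), sum(sp$n_cm3), tolerance = 1e-12)
})

test_that("gm_gsd matches closed forms and recovers lognormal parameters", {
  const <- gm_gsd(rep(7.5, 10))
  expect_equal(const$gm, 7.5)
  expect_equal(const$gsd, 1.0)
  two <- gm_gsd(c(4, 9))
  expect_equal(two$gm, 6) # sqrt(4 * 9)

  # scaling: GM scales, GSD invariant
  set.seed(8)
  x <- rlnorm(500, log(100), log(1.8))
  s1 <- gm_gsd(x); s2 <- gm_gsd(3 * x)
  expect_equal(s2$gm, 3 * s1$gm, tolerance = 1e-12)
  expect_equal(s2$gsd, s1$gsd, tolerance = 1e-12)

  # parameter recovery at the indoor-baseline parameters
  set.seed(2024)
  draws <- rlnorm(1e4, log(5120), log(1.50))
  rec <- gm_gsd(draws)
  expect_lt(abs(rec$gm / 5120 - 1), 0.02)
  expect_lt(abs(rec$gsd / 1.50 - 1), 0.02)

  expect_message(withzero <- gm_gsd(c(0, 1, 2, 4)), "dropped")
  expect_equal(withzero$n_dropped, 1)
  expect_error(gm_gsd(numeric(0)), class = "radonaero_invalid_input")
  expect_error(gm_gsd(c(0, 0)), class = "radonaero_invalid_input")
})

test_that("correlation aligns on time bins and detects degenerate input", {
  t_a <- seq(0, 86400, by = 240)
  a <- tibble::tibble(timestamp = t_a, value = sin(t_a / 5000))
  b_same <- tibble::tibble(timestamp = t_a + 60, value = sin(t_a / 5000))
  expect_equal(correlate_series(a, a), 1.0)
  expect_gt(correlate_series(a, b_same), 0.99)
  neg <- dplyr::mutate(a, value = -value)
  expect_equal(correlate_series(a, neg), -1.0)

  set.seed(99)
  t_w <- seq(0, 1000 * 1800 - 1, by = 1800)
  w1 <- tibble::tibble(timestamp = t_w, value = stats::rnorm(1000))
  w2 <- tibble::tibble(timestamp = t_w, value = stats::rnorm(1000))
  expect_lt(abs(correlate_series(w1, w2)), 0.1)

  short <- a[1:2, ]
  expect_error(correlate_series(short, short),
               class = "radonaero_undefined_correlation")
  flat <- dplyr::mutate(a, value = 1)
  expect_error(correlate_series(a, flat),
               class = "radonaero_undefined_correlation")
})

test_that("diurnal profiles localise constructed peaks", {
  ts <- seq(0, 3 * 86400 - 1, by = 1800)
  flat <- tibble::tibble(timestamp = ts, value = 5)
  p <- diurnal_profile(flat)
  expect_equal(nrow(p), 24)
  expect_true(all(p$mean == 5))

  hour <- (ts %% 86400) / 3600
  noonpeak <- tibble::tibble(timestamp = ts,
                             value = 10 + cos((hour - 12) / 24 * 2 * pi))
  expect_equal(diurnal_profile(noonpeak)$hour[
    which.max(diurnal_profile(noonpeak)$mean)], 12)

  twopeak <- tibble::tibble(timestamp = ts,
                            value = 10 + cos(hour / 12 * 2 * pi))
  pr <- diurnal_profile(twopeak)
  top2 <- sort(pr$hour[order(pr$mean, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(0, 12))

  expect_error(diurnal_profile(flat[1:10, ]),
               class = "radonaero_invalid_input")
})
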