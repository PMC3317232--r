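# Decay-chain constants, activity/number conversion, Bateman ingrowth.

test_that("decay constants follow ln2 / t_half in any unit", {
  # ln2/(3.82*86400) and ln2/183, computed directly as the oracle
  expect_equal(decay_constant(3.82, "d"), log(2) / (3.82 * 86400),
               tolerance = 1e-12)
  expect_equal(decay_constant(3.82, "d"), 2.100e-6, tolerance = 1e-3)
  expect_equal(decay_constant(3.05, "min"), log(2) / 183, tolerance = 1e-12)
  expect_equal(decay_constant(3.05, "min"), 3.788e-3, tolerance = 1e-3)
  expect_equal(decay_constant(log(2), "s"), 1.0)

  expect_error(decay_constant(-1, "s"), class = "radonaero_invalid_input")
  expect_error(decay_constant(0, "min"), class = "radonaero_invalid_input")
  expect_error(decay_constant(3.82), class = "radonaero_invalid_input")
  expect_error(decay_constant(3.82, "fortnight"),
               class = "radonaero_invalid_input")
})

test_that("chain table carries the fixed half-lives and lambda identity", {
  nucs <- rn_nuclides()
  expect_equal(nucs$nuclide, c("rn222", "po218", "pb214", "bi214", "po214"))
  expect_equal(nucs$t_half, c(3.82, 3.05, 26.8, 19.7, 164))
  expect_equal(nucs$lambda, log(2) / nucs$t_half_s, tolerance = 1e-12)
  # potential alpha-energy: Pb/Bi carry only the 214Po alpha
  expect_true(all(nucs$e_alpha_potential >= 0))
  expect_equal(nucs$e_alpha_potential[nucs$nuclide == "pb214"],
               nucs$e_alpha_potential[nucs$nuclide == "bi214"])
  expect_equal(nucs$e_alpha_potential[nucs$nuclide == "po218"],
               6.00 + 7.69)
})

test_that("activity/number conversion matches direct arithmetic and inverts", {
  # 1 Bq m^-3 of radon: 1/lambda atoms m^-3 = 0.476 cm^-3 with the 3.82 d
  # half-life (the often-quoted 0.477 comes from the unrounded 3.8235 d)
  expect_equal(activity_to_number(1, "rn222"), 0.477, tolerance = 3e-3)
  expect_equal(activity_to_number(1, "rn222"),
               1 / decay_constant(3.82, "d") / 1e6, tolerance = 1e-12)
  expect_equal(activity_to_number(0, "pb214"), 0)
  expect_equal(activity_to_number(1, "po218"), 264.0 / 1e6, tolerance = 1e-3)
  # nuclide aliases resolve
  expect_equal(activity_to_number(5, "Po-218"), activity_to_number(5, "po218"))

  # round trip to 1e-12 relative on random values
  set.seed(42)
  for (nuc in c("rn222", "po218", "pb214", "bi214")) {
    a <- stats::runif(20, 0, 500)
    expect_equal(number_to_activity(activity_to_number(a, nuc), nuc), a,
                 tolerance = 1e-12)
  }
  expect_error(activity_to_number(-1, "rn222"),
               class = "radonaero_invalid_input")
  expect_error(activity_to_number(1, "u238"),
               class = "radonaero_invalid_input")
})

test_that("ingrowth starts from pure radon and reaches secular equilibrium", {
  tr <- bateman_ingrowth(1, c(0, 24), unit = "h")
  first <- tr[1, ]
  expect_equal(first$a_po218, 0)
  expect_equal(first$a_pb214, 0)
  expect_equal(first$a_bi214, 0)
  expect_equal(first$n_rn, activity_to_number(1, "rn222"), tolerance = 1e-12)

  last <- tr[2, ]
  for (a in c(last$a_po218, last$a_pb214, last$a_bi214, last$a_po214)) {
    # 24 h >> progeny half-lives, but this is transient (not exactly secular)
    # equilibrium: each ratio sits lambda_Rn/lambda_i above 1, up to ~0.7%
    # cumulatively for 214Bi
    expect_gte(a / last$a_rn, 1)
    expect_lt(abs(a / last$a_rn - 1), 0.01)
  }
})

test_that("trajectory satisfies the activity-number tie and the 214Po alias", {
  tr <- bateman_ingrowth(50, seq(0, 120, by = 5), unit = "min")
  lam <- chain_lambdas()
  expect_equal(tr$a_rn, tr$n_rn * lam[["rn222"]] * 1e6, tolerance = 1e-12)
  expect_equal(tr$a_po218, tr$n_po218 * lam[["po218"]] * 1e6, tolerance = 1e-12)
  expect_equal(tr$a_pb214, tr$n_pb214 * lam[["pb214"]] * 1e6, tolerance = 1e-12)
  expect_equal(tr$a_bi214, tr$n_bi214 * lam[["bi214"]] * 1e6, tolerance = 1e-12)
  expect_identical(tr$a_po214, tr$a_bi214)
  expect_true(all(as.matrix(tr[-1]) >= 0))
})

test_that("analytic solution matches the ODE oracle on random instances", {
  lam <- unname(chain_lambdas()[c("rn222", "po218", "pb214", "bi214")])
  set.seed(7)
  for (rep in 1:5) {
    c0 <- stats::runif(1, 0.5, 300)
    t_s <- seq(0, 4 * 3600, by = 60)
    tr <- bateman_ingrowth(c0, t_s, unit = "s")
    oracle <- ode_chain_oracle(lam, c(c0 / lam[1] / 1e6, 0, 0, 0), t_s)
    got <- as.matrix(tr[, c("n_rn", "n_po218", "n_pb214", "n_bi214")])
    scale <- max(oracle)
    expect_lt(max(abs(got - oracle)) / scale, 1e-6)
  }
})

test_that("ingrowth toward radon is monotone and atom numbers order as 1/lambda", {
  tr <- bateman_ingrowth(10, seq(0, 3, by = 0.05), unit = "h")
  for (col in c("a_po218", "a_pb214", "a_bi214")) {
    ratio <- tr[[col]] / tr$a_rn
    expect_true(all(diff(ratio) >= -1e-12))
  }
  # near equilibrium, N per unit activity orders by mean-life
  last <- tr[nrow(tr), ]
  expect_gt(last$n_pb214, last$n_bi214)
  expect_gt(last$n_bi214, last$n_po218)
})

test_that("degenerate decay constants fall back to a stable integration", {
  # a synthetic 3-member chain with two equal rates exercises the fallback
  expect_true(radonaero:::.lambda_degenerate(c(1, 1 + 1e-12, 2)))
  expect_false(radonaero:::.lambda_degenerate(
    unname(chain_lambdas()[c("rn222", "po218", "pb214", "bi214")])))
})

test_that("ingrowth input validation rejects bad grids", {
  expect_error(bateman_ingrowth(1, c(1, 0, 2), unit = "h"),
               class = "radonaero_invalid_input")
  expect_error(bateman_ingrowth(1, c(0, -1, 2), unit = "h"),
               class = "radonaero_invalid_input")
  expect_error(bateman_ingrowth(-1, c(0, 1), unit = "h"),
               class = "radonaero_invalid_input")
  expect_error(bateman_ingrowth(1, c(0, 1)), class = "radonaero_invalid_input")
})

test_that("trajectory exports to CSV with the documented columns and tidies", {
  tr <- bateman_ingrowth(1, c(0, 1, 2), unit = "h")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("time_s", "a_rn", "a_po218", "a_pb214", "a_bi214",
                       "a_po214", "n_rn", "n_po218", "n_pb214", "n_bi214"))
  long <- tidy(tr)
  expect_setequal(unique(long$nuclide), c("rn", "po218", "pb214", "bi214",
                                          "po214"))
})
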