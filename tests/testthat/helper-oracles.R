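# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Brute-force ODE integration of a serial chain dN/dt = lambda_p N_p - lambda N,
# used as the independent oracle for the analytic Bateman solution and the
# counting forward model.
ode_chain_oracle <- function(lambda, n0, t_s, source = NULL) {
  src <- source %||% numeric(length(lambda))
  rhs <- function(t, y, parms) {
    inflow <- c(0, lambda[-length(lambda)] * y[-length(y)])
    list(inflow - lambda * y + src)
  }
  out <- deSolve::ode(y = n0, times = t_s, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-20)
  unname(out[, -1, drop = FALSE])
}

chain_lambdas <- function() {
  nucs <- rn_nuclides()
  setNames(nucs$lambda, nucs$nuclide)
}

# random positive spectrum on the standard grid
random_spectrum <- function(seed, n_tot = 5000) {
  set.seed(seed)
  g <- size_grid("medium")
  n <- stats::rgamma(nrow(g), shape = 0.8) *
    stats::dlnorm(g$d_nm, log(stats::runif(1, 20, 120)),
                  log(stats::runif(1, 1.4, 2.2)))
  tibble::tibble(d_nm = g$d_nm, n_cm3 = n_tot * n / sum(n))
}

`%||%` <- rlang::`%||%`
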