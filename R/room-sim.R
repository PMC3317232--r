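# Jacobi-type indoor kinetics of radon progeny coupled to an aerosol
# spectrum.
#
# Per progeny nuclide i (218Po, 214Pb, 214Bi) with chain parent p, in atoms
# cm^-3:
#
#   d u_i/dt = prod_i(t) - (lambda_i + lambda_v + lambda_d_un + X) u_i
#   d a_i/dt = X u_i + stay_i(t) - (lambda_i + lambda_v + lambda_d_att) a_i
#
# where X = beta * S_tot is the attachment rate (beta times total aerosol
# surface area), prod_i collects decays that feed the unattached pool
# (all newborn 218Po from radon; decay of unattached parents; the recoil
# share of 214Pb born on a particle when attached 218Po alpha-decays) and
# stay_i the decays that remain attached. Aerosol channels relax toward the
# quiescent baseline, exchange with the outdoor spectrum by ventilation, and
# receive scripted event injections. All kinetics are deterministic; only
# the emitted instrument records carry (seeded) measurement noise.

.room_rates_s <- function(cfg) {
  list(
    lv_closed = cfg$lambda_v_closed / 3600,
    lv_open = cfg$lambda_v_open / 3600,
    beta = cfg$beta_attach / 3600,
    ld_un = cfg$lambda_d_un / 3600,
    ld_att = cfg$lambda_d_att / 3600,
    k_relax = cfg$k_relax / 3600,
    entry = if (is.null(cfg$radon_entry_bq_m3_h)) NULL
            else cfg$radon_entry_bq_m3_h / 3600
  )
}

.progeny_lambdas <- function() {
  nucs <- rn_nuclides()
  setNames(nucs$lambda[match(c("rn222", "po218", "pb214", "bi214"),
                             nucs$nuclide)],
           c("rn222", "po218", "pb214", "bi214"))
}

#' Simulate coupled aerosol and radon-progeny time series in a room
#'
#' Integrates the room kinetics with a fixed-step RK4 scheme and emits
#' instrument-style records: one aerosol spectrum every 4 min (SMPS-like)
#' and one progeny record every 2 h (EQF-like), both with multiplicative
#' lognormal measurement noise under the configuration's seed. The true
#' (noise-free) state trajectory is returned alongside for validation.
#'
#' @param cfg A [room_config()].
#' @param script An [event_script()] (default: no events).
#' @param duration_h Run length in hours (>= 1).
#' @param dt_s Integration step in seconds (<= 60; default 30).
#' @param init `"steady"` (default) starts the progeny at the closed-form
#'   quiescent steady state, so undisturbed runs are stationary from t = 0;
#'   `"zero"` starts from freshly radon-filled air with no progeny, showing
#'   the full ingrowth/attachment transient.
#' @return A list of class `room_run` with elements
#'   \describe{
#'     \item{state}{tibble of the true state at every SMPS cadence:
#'       `time_s`, `c_rn`, unattached/attached atom concentrations per
#'       nuclide (cm^-3), `s_tot` (nm^2 cm^-3), `c_tot` (cm^-3), `f_un`.}
#'     \item{smps}{long spectrum records (`timestamp`, `d_nm`, `n_cm3`).}
#'     \item{eqf}{progeny records (`timestamp`, `rn`, `po218_un`, ...,
#'       `bi214_att`) in Bq m^-3.}
#'     \item{cfg, script}{the inputs, for the run manifest.}
#'   }
#' @examples
#' \donttest{
#' run <- simulate_room(room_config(seed = 7), duration_h = 2)
#' glance(run)
#' }
#' @export
simulate_room <- function(cfg = room_config(), script = event_script(),
                          duration_h = 48, dt_s = 30,
                          init = c("steady", "zero")) {
  init <- match.arg(init)
  if (!inherits(cfg, "room_config")) {
    abort("`cfg` must be a room_config().", class = "radonaero_config_error")
  }
  if (dt_s > 60 || dt_s <= 0) {
    abort("`dt_s` must be in (0, 60] seconds.",
          class = "radonaero_config_error")
  }
  if (duration_h < 1) {
    abort("`duration_h` must be at least 1 hour.",
          class = "radonaero_config_error")
  }
  rates <- .room_rates_s(cfg)
  lam <- .progeny_lambdas()
  grid <- cfg$grid
  nch <- nrow(grid)
  base_spec <- .lognormal_mode(grid, cfg$baseline_n_tot, cfg$baseline_cmd_nm,
                               cfg$baseline_gsd)
  out_spec <- .lognormal_mode(grid, cfg$outdoor_n_tot, cfg$outdoor_cmd_nm,
                              cfg$outdoor_gsd)
  pi_d2 <- pi * grid$d_nm^2

  # The configured baseline IS the quiescent stationary spectrum: the indoor
  # relaxation target is offset so that baseline restoration and closed-window
  # outdoor exchange balance exactly at n = base_spec.
  relax_target <- if (rates$k_relax > 0) {
    base_spec + (rates$lv_closed / rates$k_relax) * (base_spec - out_spec)
  } else {
    base_spec
  }

  inj <- script[script$kind %in% c("toaster", "cooking", "candle", "boiling"), ]
  inj_spec <- if (nrow(inj) > 0) {
    t(vapply(seq_len(nrow(inj)), function(i) {
      if (inj$kind[i] == "boiling") {
        .lognormal_mode(grid, inj$magnitude[i] / 2, 25, inj$mode_gsd[i]) +
          .lognormal_mode(grid, inj$magnitude[i] / 2, 85, inj$mode_gsd[i])
      } else {
        .lognormal_mode(grid, inj$magnitude[i], inj$mode_nm[i], inj$mode_gsd[i])
      }
    }, numeric(nch)))
  } else {
    matrix(0, 0, nch)
  }
  opens <- script[script$kind == "window_open", ]

  lambda_v_at <- function(t_s) {
    if (nrow(opens) > 0 &&
        any(t_s >= opens$start_h * 3600 & t_s < opens$end_h * 3600)) {
      rates$lv_open
    } else {
      rates$lv_closed
    }
  }

  # state vector: [c_rn, u_po, u_pb, u_bi, a_po, a_pb, a_bi, n_1..n_nch]
  deriv <- function(t, y, parms) {
    c_rn <- y[1]; u <- y[2:4]; a <- y[5:7]; n <- y[8:(7 + nch)]
    lv <- lambda_v_at(t)
    s_tot <- sum(n * pi_d2)
    x_att <- rates$beta * s_tot

    # injection source sustaining `magnitude` at quasi-steady state
    q <- numeric(nch)
    if (nrow(inj) > 0) {
      act <- which(t >= inj$start_h * 3600 & t < inj$end_h * 3600)
      for (i in act) q <- q + inj_spec[i, ] * (rates$k_relax + lv)
    }
    dn <- rates$k_relax * (relax_target - n) + lv * (out_spec - n) + q

    dc_rn <- if (is.null(rates$entry)) 0
             else rates$entry - (lam[["rn222"]] + lv) * c_rn

    prod_po <- c_rn / 1e6                       # newborn 218Po atoms cm^-3 s^-1
    loss_un <- lam[c("po218", "pb214", "bi214")] + lv + rates$ld_un + x_att
    loss_att <- lam[c("po218", "pb214", "bi214")] + lv + rates$ld_att

    du <- c(
      prod_po,
      lam[["po218"]] * u[1] + cfg$recoil_prob * lam[["po218"]] * a[1],
      lam[["pb214"]] * u[2]
    ) - loss_un * u
    da <- x_att * u + c(
      0,
      (1 - cfg$recoil_prob) * lam[["po218"]] * a[1],
      lam[["pb214"]] * a[2]
    ) - loss_att * a

    list(c(dc_rn, du, da, dn))
  }

  c_rn0 <- if (is.null(rates$entry)) cfg$c_rn
           else rates$entry / (lam[["rn222"]] + rates$lv_closed)
  y0 <- c(c_rn0, numeric(6), base_spec)
  if (init == "steady") {
    ss <- .steady_state_atoms(cfg, s_tot = sum(base_spec * pi_d2),
                              c_rn = c_rn0)
    y0[2:7] <- c(ss$u, ss$a)
  }

  times <- seq(0, duration_h * 3600, by = dt_s)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  y <- unname(sol[, -1, drop = FALSE])
  if (any(y < -1e-6 * max(abs(y)))) {
    abort("Integration produced negative state values; reduce `dt_s`.",
          class = "radonaero_integration_error")
  }
  y[y < 0] <- 0

  keep <- which(times %% cfg$smps_cadence_s == 0)
  tk <- times[keep]
  spec_mat <- y[keep, 8:(7 + nch), drop = FALSE]
  u_mat <- y[keep, 2:4, drop = FALSE]
  a_mat <- y[keep, 5:7, drop = FALSE]
  act_fac <- lam[c("po218", "pb214", "bi214")] * 1e6
  eec_un <- eec(u_mat[, 1] * act_fac[1], u_mat[, 2] * act_fac[2],
                u_mat[, 3] * act_fac[3])
  eec_tot <- eec((u_mat[, 1] + a_mat[, 1]) * act_fac[1],
                 (u_mat[, 2] + a_mat[, 2]) * act_fac[2],
                 (u_mat[, 3] + a_mat[, 3]) * act_fac[3])
  state <- tibble(
    time_s = tk,
    c_rn = y[keep, 1],
    u_po218 = u_mat[, 1], u_pb214 = u_mat[, 2], u_bi214 = u_mat[, 3],
    a_po218 = a_mat[, 1], a_pb214 = a_mat[, 2], a_bi214 = a_mat[, 3],
    s_tot = drop(spec_mat %*% pi_d2),
    c_tot = rowSums(spec_mat),
    f_un = ifelse(eec_tot > 0, eec_un / eec_tot, NA_real_)
  )

  set.seed(cfg$seed)
  # SMPS records: common per-record factor + small per-channel noise
  rec_fac <- rlnorm(length(tk), 0, log(cfg$noise_gsd_record))
  ch_fac <- matrix(rlnorm(length(tk) * nch, 0, log(cfg$noise_gsd_channel)),
                   length(tk), nch)
  noisy <- spec_mat * rec_fac * ch_fac
  smps <- tibble(
    timestamp = rep(tk, each = nch),
    d_nm = rep(grid$d_nm, times = length(tk)),
    n_cm3 = as.vector(t(noisy))
  )

  eqf_idx <- which(tk %% cfg$eqf_cadence_s == 0)
  act_true <- cbind(
    rn = y[keep, 1][eqf_idx],
    po218_un = u_mat[eqf_idx, 1] * act_fac[1],
    pb214_un = u_mat[eqf_idx, 2] * act_fac[2],
    bi214_un = u_mat[eqf_idx, 3] * act_fac[3],
    po218_att = a_mat[eqf_idx, 1] * act_fac[1],
    pb214_att = a_mat[eqf_idx, 2] * act_fac[2],
    bi214_att = a_mat[eqf_idx, 3] * act_fac[3]
  )
  act_noise <- matrix(rlnorm(length(act_true), 0, log(cfg$noise_gsd_activity)),
                      nrow(act_true), ncol(act_true))
  eqf <- as_tibble(act_true * act_noise)
  eqf <- dplyr::mutate(eqf, timestamp = tk[eqf_idx], .before = 1)

  structure(list(state = state, smps = smps, eqf = eqf,
                 cfg = cfg, script = script),
            class = "room_run")
}

# closed-form steady state of the linear progeny system at fixed radon and
# fixed aerosol surface; atoms cm^-3
.steady_state_atoms <- function(cfg, s_tot, c_rn) {
  rates <- .room_rates_s(cfg)
  lam <- .progeny_lambdas()
  lv <- rates$lv_closed
  x_att <- rates$beta * s_tot
  p <- cfg$recoil_prob
  lp <- lam[c("po218", "pb214", "bi214")]
  loss_un <- lp + lv + rates$ld_un + x_att
  loss_att <- lp + lv + rates$ld_att

  u <- numeric(3); a <- numeric(3)
  u[1] <- (c_rn / 1e6) / loss_un[1]
  a[1] <- x_att * u[1] / loss_att[1]
  u[2] <- (lp[1] * u[1] + p * lp[1] * a[1]) / loss_un[2]
  a[2] <- (x_att * u[2] + (1 - p) * lp[1] * a[1]) / loss_att[2]
  u[3] <- lp[2] * u[2] / loss_un[3]
  a[3] <- (x_att * u[3] + lp[2] * a[2]) / loss_att[3]
  list(u = u, a = a)
}

#' Closed-form steady-state unattached fraction of the room model
#'
#' Solves the quiescent (event-free, closed-window) progeny balance
#' analytically and returns the activity-weighted unattached fraction f_un.
#' With no attachment (`beta_attach = 0` or an empty spectrum) the entire
#' chain stays unattached and f_un is exactly 1; f_un decreases
#' monotonically as the total aerosol *surface area* grows — two spectra
#' with equal number concentration but different surface area give
#' different f_un.
#'
#' @param cfg A [room_config()].
#' @param s_tot Total aerosol surface concentration, nm^2 cm^-3; default:
#'   the surface area of the configured baseline spectrum.
#' @return Steady-state f_un (a single number in (0, 1]).
#' @examples
#' steady_state_fun(room_config())
#' steady_state_fun(room_config(beta_attach = 0))
#' @export
steady_state_fun <- function(cfg = room_config(), s_tot = NULL) {
  if (!inherits(cfg, "room_config")) {
    abort("`cfg` must be a room_config().", class = "radonaero_config_error")
  }
  if (is.null(s_tot)) {
    base <- .lognormal_mode(cfg$grid, cfg$baseline_n_tot, cfg$baseline_cmd_nm,
                            cfg$baseline_gsd)
    s_tot <- sum(base * pi * cfg$grid$d_nm^2)
  }
  check_nonneg(s_tot, "s_tot")
  rates <- .room_rates_s(cfg)
  lam <- .progeny_lambdas()
  c_rn <- if (is.null(cfg$c_rn)) {
    rates$entry / (lam[["rn222"]] + rates$lv_closed)
  } else {
    cfg$c_rn
  }
  ss <- .steady_state_atoms(cfg, s_tot = s_tot, c_rn = c_rn)
  act_fac <- lam[c("po218", "pb214", "bi214")] * 1e6
  au <- ss$u * act_fac
  at <- (ss$u + ss$a) * act_fac
  unname(eec(au[1], au[2], au[3]) / eec(at[1], at[2], at[3]))
}

#' @export
print.room_run <- function(x, ...) {
  cat("Synthetic room run: ", max(x$state$time_s) / 3600, " h, ",
      nrow(x$smps) / nrow(x$cfg$grid), " spectra, ", nrow(x$eqf),
      " progeny records\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.room_run <- function(x, ...) {
  st <- x$state
  tibble(
    duration_h = max(st$time_s) / 3600,
    c_rn_mean = mean(st$c_rn),
    c_tot_gm = geomean(st$c_tot[st$c_tot > 0]),
    s_tot_gm = geomean(st$s_tot[st$s_tot > 0]),
    f_un_final = tail(st$f_un, 1),
    n_smps_records = nrow(x$smps) / nrow(x$cfg$grid),
    n_eqf_records = nrow(x$eqf)
  )
}

#' @exportS3Method generics::tidy
tidy.room_run <- function(x, ...) {
  tidyr::pivot_longer(x$state, -"time_s", names_to = "variable")
}
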