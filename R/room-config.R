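# Configuration and event scripting for the synthetic room.

#' Configuration of the Jacobi-type room kinetics model
#'
#' Rate constants and baseline conditions for [simulate_room()] and
#' [steady_state_fun()]. Defaults describe a quiescent basement room with
#' closed window: radon held at the observed indoor geometric mean, an
#' accumulation-mode background aerosol, fast deposition of the unattached
#' clusters, and an attachment coefficient calibrated so the quiescent
#' steady-state unattached fraction sits near the observed indoor value
#' (f_un about 0.16, within the observed 0.09-0.28 range).
#'
#' @param c_rn Fixed radon activity concentration, Bq m^-3 (default 229).
#'   Set to `NULL` and give `radon_entry_bq_m3_h` to make radon dynamic
#'   (entering at a constant rate, removed by ventilation and decay).
#' @param radon_entry_bq_m3_h Radon entry rate, Bq m^-3 h^-1 (optional).
#' @param lambda_v_closed,lambda_v_open Air-exchange rates with the window
#'   closed / open, h^-1 (defaults 0.3, 3).
#' @param beta_attach Attachment coefficient, h^-1 per unit aerosol surface
#'   concentration (nm^2 cm^-3). The default 1.17e-7 puts the quiescent
#'   attachment rate beta x S_tot near 13 h^-1 for the default baseline
#'   spectrum, giving a steady-state f_un of 0.16.
#' @param lambda_d_un,lambda_d_att Deposition rates of unattached clusters
#'   and of aerosol-attached progeny, h^-1 (defaults 20, 0.2; the unattached
#'   clusters diffuse to surfaces far faster, and the constructor enforces
#'   `lambda_d_un > lambda_d_att`).
#' @param recoil_prob Probability that the 214Pb atom formed by alpha decay
#'   of attached 218Po recoils off its carrier particle (default 0.5).
#' @param baseline_n_tot,baseline_cmd_nm,baseline_gsd Quiescent indoor
#'   aerosol: total number concentration (cm^-3), count median diameter (nm)
#'   and spectral geometric standard deviation (defaults 5120, 57, 1.9).
#' @param outdoor_n_tot,outdoor_cmd_nm,outdoor_gsd Outdoor boundary
#'   spectrum exchanged in by ventilation (defaults 6900, 59, 2.0). Set
#'   `outdoor_n_tot = 0` for particle-free outdoor air.
#' @param k_relax Relaxation rate of the indoor spectrum toward its
#'   quiescent baseline, h^-1 (default 2: indoor sources/sinks restore the
#'   background within about an hour after a perturbation).
#' @param grid Channel grid for the aerosol spectrum ([size_grid()]).
#' @param noise_gsd_record Multiplicative lognormal measurement noise
#'   applied as a common factor to each emitted spectrum record (default
#'   1.5, reproducing the observed record-to-record spread of C_tot).
#' @param noise_gsd_channel Additional independent per-channel noise
#'   (default 1.05).
#' @param noise_gsd_activity Multiplicative noise per reported activity in
#'   the progeny records (default 1.15).
#' @param smps_cadence_s,eqf_cadence_s Record cadences: one spectrum per
#'   4 min, one progeny record per 2 h.
#' @param seed Integer seed controlling all randomness of a run.
#' @return A list of class `room_config`.
#' @examples
#' room_config()
#' @export
room_config <- function(c_rn = 229,
                        radon_entry_bq_m3_h = NULL,
                        lambda_v_closed = 0.3,
                        lambda_v_open = 3,
                        beta_attach = 1.17e-7,
                        lambda_d_un = 20,
                        lambda_d_att = 0.2,
                        recoil_prob = 0.5,
                        baseline_n_tot = 5120,
                        baseline_cmd_nm = 57,
                        baseline_gsd = 1.9,
                        outdoor_n_tot = 6900,
                        outdoor_cmd_nm = 59,
                        outdoor_gsd = 2.0,
                        k_relax = 2,
                        grid = size_grid("medium"),
                        noise_gsd_record = 1.5,
                        noise_gsd_channel = 1.05,
                        noise_gsd_activity = 1.15,
                        smps_cadence_s = 240,
                        eqf_cadence_s = 7200,
                        seed = 1L) {
  rates <- c(lambda_v_closed = lambda_v_closed, lambda_v_open = lambda_v_open,
             beta_attach = beta_attach, lambda_d_un = lambda_d_un,
             lambda_d_att = lambda_d_att, k_relax = k_relax)
  if (any(rates < 0)) {
    abort("All rate constants must be non-negative.",
          class = "radonaero_config_error")
  }
  if (lambda_d_un < lambda_d_att ||
      (lambda_d_un == lambda_d_att && lambda_d_un > 0)) {
    # unattached clusters diffuse to surfaces faster; equality is only
    # admissible in the deposition-free limit used for equilibrium checks
    abort("`lambda_d_un` must exceed `lambda_d_att` (unless both are zero).",
          class = "radonaero_config_error")
  }
  if (recoil_prob < 0 || recoil_prob > 1) {
    abort("`recoil_prob` must lie in [0, 1].", class = "radonaero_config_error")
  }
  if (is.null(c_rn) && is.null(radon_entry_bq_m3_h)) {
    abort("Give either `c_rn` or `radon_entry_bq_m3_h`.",
          class = "radonaero_config_error")
  }
  if (!is.null(c_rn)) check_nonneg(c_rn, "c_rn")
  structure(list(
    c_rn = c_rn,
    radon_entry_bq_m3_h = radon_entry_bq_m3_h,
    lambda_v_closed = lambda_v_closed,
    lambda_v_open = lambda_v_open,
    beta_attach = beta_attach,
    lambda_d_un = lambda_d_un,
    lambda_d_att = lambda_d_att,
    recoil_prob = recoil_prob,
    baseline_n_tot = baseline_n_tot,
    baseline_cmd_nm = baseline_cmd_nm,
    baseline_gsd = baseline_gsd,
    outdoor_n_tot = outdoor_n_tot,
    outdoor_cmd_nm = outdoor_cmd_nm,
    outdoor_gsd = outdoor_gsd,
    k_relax = k_relax,
    grid = grid,
    noise_gsd_record = noise_gsd_record,
    noise_gsd_channel = noise_gsd_channel,
    noise_gsd_activity = noise_gsd_activity,
    smps_cadence_s = smps_cadence_s,
    eqf_cadence_s = eqf_cadence_s,
    seed = as.integer(seed)
  ), class = "room_config")
}

# channel concentrations of a lognormal mode on a grid (sums to n_tot)
.lognormal_mode <- function(grid, n_tot, cmd_nm, gsd) {
  if (n_tot == 0) return(numeric(nrow(grid)))
  w <- stats::dlnorm(grid$d_nm, meanlog = log(cmd_nm), sdlog = log(gsd)) *
    grid$dln_d * grid$d_nm
  # dlnorm is a density in d; weight by bin width in ln d: p(ln d) = d p(d)
  n_tot * w / sum(w)
}

# default injected-mode shapes per household event kind
.event_defaults <- function() tibble(
  kind = c("window_open", "window_close", "toaster", "cooking", "candle",
           "boiling"),
  magnitude = c(0, 0, 3e5, 5e4, 1.32e6, 5e4),
  mode_nm = c(NA, NA, 15, 9, 8, 25),
  mode_gsd = c(NA, NA, 1.6, 1.6, 1.5, 1.5)
)

#' Script household aerosol events for the room simulator
#'
#' Builds the ordered event table consumed by [simulate_room()]. Injection
#' events (`toaster`, `cooking`, `candle`, `boiling`) add a lognormal mode
#' to the indoor spectrum while active, at a source rate that would sustain
#' `magnitude` cm^-3 at quasi-steady state; `boiling` injects a bimodal
#' water-cluster/droplet pair at 25 and 85 nm (equal split). `window_open`
#' switches the air-exchange rate to its open-window value for the event's
#' duration; `window_close` is a no-op marker. Default magnitudes follow the
#' observed indoor peaks (candle 1.32e6 cm^-3, toaster 3e5 cm^-3, cooking
#' about 5e4 cm^-3).
#'
#' @param start_h,end_h Event start/end, hours from the run start.
#' @param kind One of `window_open`, `window_close`, `toaster`, `cooking`,
#'   `candle`, `boiling` (recycled).
#' @param magnitude Target injected total concentration, cm^-3 (default per
#'   kind).
#' @param mode_nm,mode_gsd Injected mode diameter and width (defaults per
#'   kind).
#' @return A tibble of class `event_script`.
#' @examples
#' event_script(c(6, 20), c(9.5, 23.5), kind = c("cooking", "candle"))
#' @export
event_script <- function(start_h = numeric(), end_h = numeric(),
                         kind = character(), magnitude = NULL,
                         mode_nm = NULL, mode_gsd = NULL) {
  ev <- tibble(start_h = start_h, end_h = end_h, kind = kind)
  if (nrow(ev) == 0) {
    ev <- dplyr::mutate(ev, magnitude = numeric(), mode_nm = numeric(),
                        mode_gsd = numeric())
    class(ev) <- c("event_script", class(ev))
    return(ev)
  }
  if (!all(ev$kind %in% .event_defaults()$kind)) {
    abort(paste("Unknown event kind(s):",
                paste(setdiff(ev$kind, .event_defaults()$kind), collapse = ", ")),
          class = "radonaero_config_error")
  }
  if (any(ev$end_h <= ev$start_h)) {
    abort("Events must have end_h > start_h.",
          class = "radonaero_config_error")
  }
  defaults <- .event_defaults()[match(ev$kind, .event_defaults()$kind), ]
  ev$magnitude <- magnitude %||% defaults$magnitude
  ev$mode_nm <- mode_nm %||% defaults$mode_nm
  ev$mode_gsd <- mode_gsd %||% defaults$mode_gsd
  check_nonneg(ev$magnitude, "magnitude")
  # same-kind events may not overlap
  ovl <- ev %>%
    dplyr::arrange(.data$start_h) %>%
    dplyr::group_by(.data$kind) %>%
    dplyr::filter(dplyr::lead(.data$start_h) < .data$end_h) %>%
    dplyr::ungroup()
  if (nrow(ovl) > 0) {
    abort("Events of the same kind overlap.", class = "radonaero_config_error")
  }
  ev <- dplyr::arrange(ev, .data$start_h)
  class(ev) <- c("event_script", class(ev))
  ev
}
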