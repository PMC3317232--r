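# Scalar exposure metrics for radon short-lived decay products (RnDP).
#
# The equilibrium equivalent concentration (EEC) weights the three measurable
# progeny by their share of the chain's potential alpha-energy at secular
# equilibrium; the weights and the per-Bq alpha-energy coefficients are two
# prints of the same nuclear arithmetic, which is why the package derives one
# from the other in its self-consistency checks.

.eec_weights <- c(po218 = 0.1065, pb214 = 0.515, bi214 = 0.379)
# MeV m^-3 per Bq m^-3; the bi214 value printed in some sources as 113120 is
# inconsistent by ~10x with both the EEC weights and the per-atom arithmetic
# (7.69 MeV x 1/lambda_Bi = 7.69/5.864e-4 ~= 13114); 13120 is the default.
.ealpha_coefs_corrected <- c(po218 = 3690, pb214 = 17830, bi214 = 13120)
.ealpha_coefs_printed   <- c(po218 = 3690, pb214 = 17830, bi214 = 113120)

# WLM definition: 170 h of breathing at E_alpha = 1.3e8 MeV m^-3
.wlm_hours <- 170
.wlm_ealpha <- 1.3e8

# ICRP-65 conventional dose conversion factors, exposed as constants only
.dcf_conventional <- c(home = 4, workplace = 5) # mSv WLM^-1

#' Equilibrium equivalent concentration (EEC) of radon progeny
#'
#' Weighted sum of the individual progeny activity concentrations,
#' \eqn{C^A_{RnDP} = 0.1065\,C_{Po218} + 0.515\,C_{Pb214} + 0.379\,C_{Bi214}}.
#' \eqn{^{214}Po} needs no term of its own: its activity equals that of
#' \eqn{^{214}Bi} and is folded into the last coefficient. Vectorised.
#'
#' @param c_po218,c_pb214,c_bi214 Activity concentrations, Bq m^-3 (>= 0).
#' @return EEC in Bq m^-3.
#' @examples
#' eec(100, 100, 100)
#' @export
eec <- function(c_po218, c_pb214, c_bi214) {
  check_nonneg(c_po218, "c_po218")
  check_nonneg(c_pb214, "c_pb214")
  check_nonneg(c_bi214, "c_bi214")
  .eec_weights[["po218"]] * c_po218 +
    .eec_weights[["pb214"]] * c_pb214 +
    .eec_weights[["bi214"]] * c_bi214
}

#' Equilibrium factor between radon and its progeny
#'
#' \eqn{F = C^A_{RnDP} / C^A_{Rn}}; 1 at secular equilibrium, below 1 in
#' ambient air where ventilation and deposition remove progeny.
#'
#' @param eec EEC, Bq m^-3 (>= 0).
#' @param c_rn Radon activity concentration, Bq m^-3 (> 0).
#' @return Dimensionless equilibrium factor.
#' @export
equilibrium_factor <- function(eec, c_rn) {
  check_nonneg(eec, "eec")
  if (!is.numeric(c_rn) || anyNA(c_rn) || any(c_rn <= 0)) {
    abort("`c_rn` must be strictly positive: F is undefined without radon.",
          class = "radonaero_undefined_factor")
  }
  eec / c_rn
}

#' Potential alpha-energy concentration of radon progeny
#'
#' Total alpha energy that the airborne progeny will eventually emit per unit
#' air volume, \eqn{E_\alpha = 3690\,C_{Po218} + 17830\,C_{Pb214} +
#' c_{Bi}\,C_{Bi214}} MeV m^-3. The default \eqn{^{214}Bi} coefficient is the
#' self-consistent 13120; the alternative 113120 found in print is selectable
#' but warned about, since it disagrees with the EEC weights by a factor of
#' about ten.
#'
#' @inheritParams eec
#' @param bi214_coefficient `"corrected"` (13120, default) or `"printed"`
#'   (113120, with a warning).
#' @return Potential alpha-energy concentration, MeV m^-3.
#' @export
potential_alpha_energy <- function(c_po218, c_pb214, c_bi214,
                                   bi214_coefficient = c("corrected", "printed")) {
  bi214_coefficient <- match.arg(bi214_coefficient)
  check_nonneg(c_po218, "c_po218")
  check_nonneg(c_pb214, "c_pb214")
  check_nonneg(c_bi214, "c_bi214")
  co <- if (bi214_coefficient == "corrected") .ealpha_coefs_corrected
        else .ealpha_coefs_printed
  if (bi214_coefficient == "printed") {
    warn(paste("Using the printed 214Bi coefficient 113120 MeV m^-3 per",
               "Bq m^-3; it is inconsistent with the EEC weights by ~10x."))
  }
  co[["po218"]] * c_po218 + co[["pb214"]] * c_pb214 + co[["bi214"]] * c_bi214
}

#' Unattached activity and number fractions of radon progeny
#'
#' From one or more progeny records split into unattached (molecular
#' clusters, < ~5 nm) and aerosol-attached fractions, computes
#' \itemize{
#'   \item `f_un`: the activity fraction, EEC of the unattached progeny over
#'     the EEC of all progeny;
#'   \item `x_un`: the number fraction, unattached atoms over all progeny
#'     atoms, after converting each activity to an atom number with the
#'     nuclide's decay constant.
#' }
#' Records with all six activities zero are an error: both fractions are
#' undefined 0/0 there, and silently returning 0 would bias time averages.
#'
#' @param data Data frame with columns `po218_un`, `pb214_un`, `bi214_un`,
#'   `po218_att`, `pb214_att`, `bi214_att` (activity concentrations,
#'   Bq m^-3).
#' @return `data` as a tibble with columns `f_un` and `x_un` appended.
#' @examples
#' rec <- tibble::tibble(po218_un = 5, pb214_un = 8, bi214_un = 6,
#'                       po218_att = 45, pb214_att = 72, bi214_att = 54)
#' unattached_fractions(rec)
#' @export
unattached_fractions <- function(data) {
  need <- c("po218_un", "pb214_un", "bi214_un",
            "po218_att", "pb214_att", "bi214_att")
  if (!all(need %in% names(data))) {
    abort(paste("Missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")),
          class = "radonaero_invalid_input")
  }
  for (nm in need) check_nonneg(data[[nm]], nm)
  tot <- Reduce(`+`, lapply(need, function(nm) data[[nm]]))
  if (any(tot == 0)) {
    abort("Record(s) with all six activities zero: f_un and x_un undefined.",
          class = "radonaero_undefined_fraction")
  }
  eec_un  <- eec(data$po218_un, data$pb214_un, data$bi214_un)
  eec_tot <- eec(data$po218_un + data$po218_att,
                 data$pb214_un + data$pb214_att,
                 data$bi214_un + data$bi214_att)
  n_un <- activity_to_number(data$po218_un, "po218") +
    activity_to_number(data$pb214_un, "pb214") +
    activity_to_number(data$bi214_un, "bi214")
  n_att <- activity_to_number(data$po218_att, "po218") +
    activity_to_number(data$pb214_att, "pb214") +
    activity_to_number(data$bi214_att, "bi214")
  dplyr::mutate(as_tibble(data),
                f_un = eec_un / eec_tot,
                x_un = n_un / (n_un + n_att))
}

#' Empirical dose-conversion factor from the unattached fraction
#'
#' The dosimetric dose-conversion factor rises linearly with the unattached
#' fraction: \eqn{D_{CF} = 11.35 + 43 f_{un}} mSv per WLM. The intercept is
#' the attached-only dose; the steep slope is why f_un matters for dose.
#'
#' @param f_un Unattached activity fraction(s), in \[0, 1\].
#' @return Dose conversion factor, mSv WLM^-1.
#' @examples
#' dose_conversion_empirical(0.16)
#' @export
dose_conversion_empirical <- function(f_un) {
  if (!is.numeric(f_un) || anyNA(f_un) || any(f_un < 0 | f_un > 1)) {
    abort("`f_un` must lie in [0, 1].", class = "radonaero_invalid_input")
  }
  11.35 + 43 * f_un
}

#' Cumulative exposure in working-level-months (WLM)
#'
#' Time-integral of the potential alpha-energy concentration divided by the
#' WLM norm: 1 WLM is 170 hours of breathing air at
#' \eqn{E_\alpha = 1.3 \times 10^8} MeV m^-3.
#'
#' @param e_alpha Potential alpha-energy concentrations, MeV m^-3 (>= 0).
#' @param duration_h Duration of each record, hours (> 0); recycled if
#'   length 1.
#' @return Total exposure in WLM (a single number). Additivity holds: the
#'   WLM of a concatenated series equals the sum over its parts.
#' @examples
#' exposure_wlm(1.3e8, 170) # one WLM by definition
#' @export
exposure_wlm <- function(e_alpha, duration_h) {
  if (length(e_alpha) == 0) {
    abort("Empty exposure series.", class = "radonaero_invalid_input")
  }
  check_nonneg(e_alpha, "e_alpha")
  if (!is.numeric(duration_h) || anyNA(duration_h) || any(duration_h <= 0)) {
    abort("`duration_h` must be positive.", class = "radonaero_invalid_input")
  }
  if (length(duration_h) == 1L) duration_h <- rep(duration_h, length(e_alpha))
  if (length(duration_h) != length(e_alpha)) {
    abort("`duration_h` must match `e_alpha` in length (or be scalar).",
          class = "radonaero_invalid_input")
  }
  sum(e_alpha * duration_h) / (.wlm_hours * .wlm_ealpha)
}

#' Effective dose from WLM exposure
#'
#' @param wlm Exposure in WLM.
#' @param dcf Dose-conversion factor, mSv WLM^-1 (e.g. from
#'   [dose_conversion_empirical()], or the ICRP-65 conventional 4 at home /
#'   5 in the workplace).
#' @return Effective dose, mSv.
#' @export
effective_dose <- function(wlm, dcf) {
  check_nonneg(wlm, "wlm")
  check_nonneg(dcf, "dcf")
  wlm * dcf
}

#' Empirical inverse relation between f_un and aerosol concentration
#'
#' The classical inverse proportionality \eqn{f_{un} = 400 / C^N(tot)} with
#' the total number concentration in cm^-3, capped at 1. This is a
#' diagnostic predictor only: comparing it with measured f_un is precisely
#' how one detects regimes (fast indoor events, surface-area-controlled
#' attachment) where it fails, so the pipeline never substitutes it for a
#' measurement.
#'
#' @param c_tot Total aerosol number concentration(s), cm^-3 (> 0).
#' @return Predicted unattached fraction in (0, 1\].
#' @examples
#' predicted_fun(c(400, 4000, 40000))
#' @export
predicted_fun <- function(c_tot) {
  if (!is.numeric(c_tot) || anyNA(c_tot) || any(c_tot <= 0)) {
    abort("`c_tot` must be strictly positive.",
          class = "radonaero_invalid_input")
  }
  pmin(400 / c_tot, 1)
}

#' Derived exposure metrics for a table of progeny records
#'
#' The workhorse tidy verb of the progeny stream: takes a table of records
#' (radon plus the six unattached/attached progeny activities) and appends
#' EEC, unattached EEC, equilibrium factor, f_un, x_un, potential
#' alpha-energy, the empirical dose-conversion factor, and — when records
#' carry a duration — cumulative WLM exposure.
#'
#' @param data Data frame with columns `rn` (radon activity, Bq m^-3) and
#'   the six progeny columns of [unattached_fractions()]. An optional
#'   `timestamp` column is carried through.
#' @param record_duration_h Duration represented by each record in hours
#'   (default 2, the progeny monitor's cadence); used for cumulative WLM.
#' @param bi214_coefficient Passed to [potential_alpha_energy()].
#' @return A tibble with columns `eec`, `eec_un`, `f_equilibrium`, `f_un`,
#'   `x_un`, `e_alpha`, `dcf`, `wlm_cum` appended.
#' @examples
#' recs <- tibble::tibble(rn = 229, po218_un = 5, pb214_un = 8, bi214_un = 6,
#'                        po218_att = 45, pb214_att = 72, bi214_att = 54)
#' progeny_metrics(recs)
#' @export
progeny_metrics <- function(data, record_duration_h = 2,
                            bi214_coefficient = c("corrected", "printed")) {
  bi214_coefficient <- match.arg(bi214_coefficient)
  data <- unattached_fractions(data)
  if (!"rn" %in% names(data)) {
    abort("Missing `rn` column (radon activity, Bq m^-3).",
          class = "radonaero_invalid_input")
  }
  tot_po <- data$po218_un + data$po218_att
  tot_pb <- data$pb214_un + data$pb214_att
  tot_bi <- data$bi214_un + data$bi214_att
  out <- dplyr::mutate(
    data,
    eec = eec(tot_po, tot_pb, tot_bi),
    eec_un = eec(.data$po218_un, .data$pb214_un, .data$bi214_un),
    f_equilibrium = equilibrium_factor(.data$eec, .data$rn),
    e_alpha = potential_alpha_energy(tot_po, tot_pb, tot_bi,
                                     bi214_coefficient = bi214_coefficient),
    dcf = dose_conversion_empirical(.data$f_un)
  )
  out$wlm_cum <- cumsum(out$e_alpha * record_duration_h) /
    (.wlm_hours * .wlm_ealpha)
  out
}
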