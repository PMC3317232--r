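# Nuclear data for the 222Rn short-lived chain.
#
# Half-lives: 222Rn 3.82 d, 218Po 3.05 min, 214Pb 26.8 min, 214Bi 19.7 min,
# 214Po 164 us. Alpha energies (not derivable from the half-lives) are the
# standard evaluated values: 5.49 MeV (222Rn), 6.00 MeV (218Po),
# 7.69 MeV (214Po). 214Pb and 214Bi are beta/gamma emitters; their potential
# alpha-energy per atom is the single 214Po alpha still owed downstream.

.alpha_mev <- c(rn222 = 5.49, po218 = 6.00, po214 = 7.69)

#' Nuclear constants of the radon short-lived decay chain
#'
#' One row per nuclide of the serial chain
#' \eqn{^{222}Rn \to {}^{218}Po \to {}^{214}Pb \to {}^{214}Bi \to {}^{214}Po},
#' with half-life, decay constant and the potential alpha-energy per atom
#' (the alpha energy the atom and all its short-lived descendants down to
#' \eqn{^{214}Po} will eventually emit; beta/gamma energy is not counted).
#'
#' @return A tibble with columns `nuclide`, `t_half`, `t_half_unit`,
#'   `t_half_s`, `lambda` (s^-1) and `e_alpha_potential` (MeV per atom).
#' @examples
#' rn_nuclides()
#' @export
rn_nuclides <- function() {
  half <- tibble(
    nuclide     = c("rn222", "po218", "pb214", "bi214", "po214"),
    t_half      = c(3.82, 3.05, 26.8, 19.7, 164),
    t_half_unit = c("d", "min", "min", "min", "us")
  )
  half$t_half_s <- purrr::map2_dbl(half$t_half, half$t_half_unit, to_seconds)
  half$lambda <- log(2) / half$t_half_s
  half$e_alpha_potential <- c(
    .alpha_mev[["rn222"]] + .alpha_mev[["po218"]] + .alpha_mev[["po214"]],
    .alpha_mev[["po218"]] + .alpha_mev[["po214"]],
    .alpha_mev[["po214"]],
    .alpha_mev[["po214"]],
    .alpha_mev[["po214"]]
  )
  half
}

.nuclide_row <- function(nuclide) {
  nucs <- rn_nuclides()
  key <- tolower(gsub("[^a-z0-9]", "", tolower(nuclide)))
  # accept "Po-218", "218Po", "po218"
  key <- vapply(key, function(k) {
    m <- regmatches(k, regexec("([a-z]+)([0-9]+)|([0-9]+)([a-z]+)", k))[[1]]
    if (length(m) == 0) return(k)
    if (nzchar(m[2])) paste0(m[2], m[3]) else paste0(m[5], m[4])
  }, character(1))
  idx <- match(key, nucs$nuclide)
  if (anyNA(idx)) {
    abort(paste0("Unknown nuclide: ", paste(nuclide[is.na(idx)], collapse = ", ")),
          class = "radonaero_invalid_input")
  }
  nucs[idx, ]
}

#' Decay constant from a half-life
#'
#' \eqn{\lambda = \ln 2 / t_{1/2}}, returned in s^-1 whatever the input unit.
#'
#' @param t_half Half-life value (> 0).
#' @param unit Time unit of `t_half` (required; see [to_seconds()]).
#' @return Decay constant in s^-1.
#' @examples
#' decay_constant(3.82, "d")   # 222Rn
#' decay_constant(3.05, "min") # 218Po
#' @export
decay_constant <- function(t_half, unit) {
  t_s <- to_seconds(t_half, unit)
  if (anyNA(t_s) || any(t_s <= 0)) {
    abort("Half-life must be positive.", class = "radonaero_invalid_input")
  }
  log(2) / t_s
}

#' Convert activity concentration to atom number concentration
#'
#' Applies the radioactivity law \eqn{C^A = \lambda C^N}: an activity
#' concentration in Bq m^-3 divided by the decay constant gives atoms per
#' m^3, reported per cm^3 (divide by 1e6). 1 Bq m^-3 of radon corresponds to
#' 0.477 atoms cm^-3.
#'
#' @param c_a Activity concentration(s), Bq m^-3 (>= 0).
#' @param nuclide Nuclide name (e.g. `"rn222"`, `"Po-218"`).
#' @return Atom number concentration, cm^-3.
#' @seealso [number_to_activity()]
#' @examples
#' activity_to_number(1, "rn222")
#' @export
activity_to_number <- function(c_a, nuclide) {
  check_nonneg(c_a, "c_a")
  lam <- .nuclide_row(nuclide)$lambda
  c_a / lam / 1e6
}

#' Convert atom number concentration to activity concentration
#'
#' Inverse of [activity_to_number()]: atoms cm^-3 times the decay constant,
#' reported in Bq m^-3.
#'
#' @param c_n Atom number concentration(s), cm^-3 (>= 0).
#' @inheritParams activity_to_number
#' @return Activity concentration, Bq m^-3.
#' @export
number_to_activity <- function(c_n, nuclide) {
  check_nonneg(c_n, "c_n")
  lam <- .nuclide_row(nuclide)$lambda
  c_n * lam * 1e6
}
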