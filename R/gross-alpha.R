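# Two-detector, three-interval gross-alpha counting.
#
# The progeny monitor pumps air for 6 min at 2.4 dm^3 min^-1 through a
# screen/filter pair (a wire screen catches the unattached clusters below
# ~5 nm, a filter the attached fraction); each deposit sits on its own
# silicon detector and gross alpha counts are accumulated over three
# consecutive intervals within 110 min after pumping stops. Alphas come from
# 218Po directly and from 214Po, which at a 164 us half-life is in lockstep
# with 214Bi.
#
# Because deposition and decay are linear, the expected counts are a linear
# map of the three airborne activity concentrations; the forward model
# computes that 3x3 design matrix in closed form (Bateman exponential sums,
# including ingrowth on the deposit during the 6-min pump) and the inversion
# solves the linear system per detector — an interval-deconvolution in the
# spirit of the classical gross-count estimators, not a reproduction of any
# particular instrument's firmware.

#' Counting schedule for the gross-alpha measurement
#'
#' @param sample_duration_min Pumping time, minutes (default 6).
#' @param flow_dm3_min Sampling flow, dm^3 min^-1 (default 2.4).
#' @param intervals_min 3 (or more) non-overlapping `(start, end)` pairs in
#'   minutes after the end of pumping, all within 0-110 min; a matrix or
#'   list of length-2 vectors. Default `(0,30), (30,70), (70,110)`: the
#'   early interval is dominated by the fast 218Po alpha, the late one by
#'   214Po fed from ingrown 214Pb/214Bi, which is what makes the linear
#'   system well conditioned.
#' @param efficiency Detector counting efficiency in (0, 1] (default 0.25).
#' @param screen_cutoff_nm Unattached/attached separation diameter (5 nm).
#' @param detector_area_mm2 Detector area (150 mm^2, informational).
#' @return A list of class `counting_schedule`.
#' @examples
#' counting_schedule()
#' @export
counting_schedule <- function(sample_duration_min = 6,
                              flow_dm3_min = 2.4,
                              intervals_min = list(c(0, 30), c(30, 70), c(70, 110)),
                              efficiency = 0.25,
                              screen_cutoff_nm = 5,
                              detector_area_mm2 = 150) {
  if (is.matrix(intervals_min)) {
    intervals_min <- lapply(seq_len(nrow(intervals_min)),
                            function(i) intervals_min[i, ])
  }
  iv <- do.call(rbind, intervals_min)
  if (ncol(iv) != 2 || any(iv[, 2] <= iv[, 1]) || any(iv < 0) ||
      any(iv > 110) || is.unsorted(as.vector(t(iv)))) {
    abort("Intervals must be increasing, non-overlapping and within 0-110 min.",
          class = "radonaero_config_error")
  }
  if (sample_duration_min <= 0 || flow_dm3_min <= 0) {
    abort("Sampling duration and flow must be positive.",
          class = "radonaero_config_error")
  }
  if (efficiency <= 0 || efficiency > 1) {
    abort("Efficiency must lie in (0, 1].", class = "radonaero_config_error")
  }
  structure(list(
    sample_duration_s = sample_duration_min * 60,
    flow_m3_s = flow_dm3_min * 1e-3 / 60,
    intervals_s = iv * 60,
    efficiency = efficiency,
    screen_cutoff_nm = screen_cutoff_nm,
    detector_area_mm2 = detector_area_mm2
  ), class = "counting_schedule")
}

# 3-chain constants for the deposit (radon itself is a gas and not collected)
.deposit_lambdas <- function() {
  nucs <- rn_nuclides()
  nucs$lambda[match(c("po218", "pb214", "bi214"), nucs$nuclide)]
}

# expected counts in each interval for a unit source pattern:
# air activities `act` (Bq m^-3) of (po218, pb214, bi214) in one fraction
.expected_counts <- function(act, sched) {
  lam <- .deposit_lambdas()
  # atoms deposited per second while pumping: C^N (m^-3) x flow (m^3 s^-1)
  src <- act / lam * sched$flow_m3_s
  # deposit builds up with ingrowth during the pump...
  build <- .chain_expsum(lam, source = src)
  n_end <- drop(.expsum_eval(build, sched$sample_duration_s))
  # ...then decays freely; alpha rate = lam_Po218 N_Po218 + lam_Bi N_Bi
  # (the 214Po alpha follows 214Bi instantaneously)
  decay <- .chain_expsum(lam, init = n_end)
  vapply(seq_len(nrow(sched$intervals_s)), function(k) {
    ab <- sched$intervals_s[k, ]
    ints <- .expsum_integral(decay, ab[1], ab[2])
    sched$efficiency * (lam[1] * ints[1] + lam[3] * ints[3])
  }, numeric(1))
}

# design matrix: column i = expected counts for 1 Bq m^-3 of nuclide i
.design_matrix <- function(sched) {
  m <- vapply(1:3, function(i) .expected_counts(replace(numeric(3), i, 1), sched),
              numeric(nrow(sched$intervals_s)))
  colnames(m) <- c("po218", "pb214", "bi214")
  m
}

#' Forward model: expected alpha counts from airborne activities
#'
#' Expected gross-alpha counts per counting interval for one deposit
#' (one detector / one fraction), given the airborne activity concentrations
#' during sampling. Atoms collect on the deposit at a constant rate during
#' the pump (decaying and ingrowing as they sit), then decay freely; counts
#' integrate the 218Po and 214Po alpha emission over each interval. The map
#' is exactly linear in the three activities.
#'
#' @param activities Named numeric: `po218`, `pb214`, `bi214` activity
#'   concentrations in air, Bq m^-3 (>= 0).
#' @param sched A [counting_schedule()].
#' @param poisson If `TRUE`, return one Poisson draw per interval instead of
#'   the expectation.
#' @return A tibble: `interval`, `t_start_s`, `t_end_s`, `counts`.
#' @examples
#' forward_counts(c(po218 = 40, pb214 = 30, bi214 = 20), counting_schedule())
#' @export
forward_counts <- function(activities, sched = counting_schedule(),
                           poisson = FALSE) {
  if (!inherits(sched, "counting_schedule")) {
    abort("`sched` must be a counting_schedule().",
          class = "radonaero_config_error")
  }
  act <- .activity_vector(activities)
  mu <- .expected_counts(act, sched)
  counts <- if (poisson) rpois(length(mu), mu) else mu
  tibble(
    interval = seq_along(counts),
    t_start_s = sched$intervals_s[, 1],
    t_end_s = sched$intervals_s[, 2],
    counts = counts
  )
}

.activity_vector <- function(activities) {
  nm <- c("po218", "pb214", "bi214")
  if (is.null(names(activities))) {
    if (length(activities) != 3) {
      abort("`activities` must have 3 elements (po218, pb214, bi214).",
            class = "radonaero_invalid_input")
    }
    names(activities) <- nm
  }
  if (!all(nm %in% names(activities))) {
    abort("`activities` must be named po218, pb214, bi214.",
          class = "radonaero_invalid_input")
  }
  act <- as.numeric(activities[nm])
  check_nonneg(act, "activities")
  act
}

#' Invert alpha counts to per-nuclide airborne activities
#'
#' Solves the linear system `counts = M activities` where `M` is the
#' forward-model design matrix of the schedule. With the default three
#' intervals the system is square; with more intervals it is solved by least
#' squares. Approximate 1-sigma uncertainties come from propagating Poisson
#' count variances through the inverse map. Negative solutions (possible
#' under noise) are clipped to zero and flagged.
#'
#' @param counts Numeric vector of observed counts, one per schedule
#'   interval, or a tibble from [forward_counts()].
#' @param sched The same [counting_schedule()] that produced the counts.
#' @return A list of class `gross_alpha_fit`: `activities` tibble
#'   (`nuclide`, `activity_bq_m3`, `sd_bq_m3`, `clipped`), the design
#'   matrix, its condition number, and the residual counts.
#' @examples
#' obs <- forward_counts(c(po218 = 40, pb214 = 30, bi214 = 20))
#' invert_counts(obs)
#' @export
invert_counts <- function(counts, sched = counting_schedule()) {
  if (is.data.frame(counts)) counts <- counts$counts
  check_nonneg(counts, "counts")
  if (length(counts) != nrow(sched$intervals_s)) {
    abort("`counts` length must match the schedule's intervals.",
          class = "radonaero_invalid_input")
  }
  m <- .design_matrix(sched)
  kappa_m <- kappa(m, exact = TRUE)
  if (!is.finite(kappa_m) || kappa_m > 1e12) {
    abort("Design matrix is numerically singular (degenerate intervals).",
          class = "radonaero_inversion_error")
  }
  fit <- tryCatch(unname(qr.solve(m, counts)), error = function(e) {
    abort("Design matrix is numerically singular (degenerate intervals).",
          class = "radonaero_inversion_error")
  })
  # Poisson variance ~= observed counts; propagate through the pseudoinverse
  minv <- qr.solve(m, diag(nrow(m)))
  vcov <- minv %*% diag(pmax(counts, 1), nrow(m)) %*% t(minv)
  clipped <- fit < 0
  act <- pmax(fit, 0)
  structure(list(
    activities = tibble(
      nuclide = colnames(m),
      activity_bq_m3 = act,
      sd_bq_m3 = sqrt(diag(vcov)),
      clipped = clipped
    ),
    design = m,
    condition = kappa_m,
    residual = drop(counts - m %*% act)
  ), class = "gross_alpha_fit")
}

#' @export
print.gross_alpha_fit <- function(x, ...) {
  cat("Gross-alpha inversion (condition number ",
      format(x$condition, digits = 4), ")\n", sep = "")
  print(x$activities)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gross_alpha_fit <- function(x, ...) {
  dplyr::rename(x$activities, estimate = "activity_bq_m3",
                std.error = "sd_bq_m3")
}

#' @exportS3Method generics::glance
glance.gross_alpha_fit <- function(x, ...) {
  tibble(
    condition = x$condition,
    rss = sum(x$residual^2),
    n_clipped = sum(x$activities$clipped)
  )
}
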