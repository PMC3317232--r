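# SMPS-style number size distributions.
#
# Spectra are kept in long (tidy) form: one row per (timestamp, channel),
# columns `timestamp`, `d_nm`, `n_cm3`. The mobility spectrometer reports 44
# log-spaced channels over its size range; only channel centers are reported,
# so bin edges are reconstructed at geometric midpoints (log-uniform grids
# make the two conventions identical except at the end channels, which get
# half a log-step on the outside).

#' Construct a log-spaced SMPS channel grid
#'
#' @param range `"medium"` (5-350 nm), `"long"` (10-1100 nm), or a numeric
#'   `c(min, max)` in nm.
#' @param n_channels Number of channels (default 44).
#' @return A tibble with columns `d_nm` (channel center), `d_lo`, `d_hi`
#'   (geometric bin edges) and `dln_d` (log bin width).
#' @examples
#' size_grid("medium")
#' @export
size_grid <- function(range = "medium", n_channels = 44) {
  if (is.character(range)) {
    range <- switch(match.arg(range, c("medium", "long")),
                    medium = c(5, 350), long = c(10, 1100))
  }
  if (!is.numeric(range) || length(range) != 2 || any(range <= 0) ||
      range[1] >= range[2]) {
    abort("`range` must be an increasing positive pair of diameters (nm).",
          class = "radonaero_invalid_input")
  }
  if (n_channels < 2) {
    abort("Need at least 2 channels.", class = "radonaero_invalid_input")
  }
  ld <- seq(log(range[1]), log(range[2]), length.out = n_channels)
  step <- ld[2] - ld[1]
  edges <- c(ld[1] - step / 2, (ld[-1] + ld[-n_channels]) / 2,
             ld[n_channels] + step / 2)
  tibble(
    d_nm = exp(ld),
    d_lo = exp(edges[-(n_channels + 1)]),
    d_hi = exp(edges[-1]),
    dln_d = diff(edges)
  )
}

.check_spectrum <- function(data) {
  need <- c("d_nm", "n_cm3")
  if (!all(need %in% names(data))) {
    abort("Spectrum data needs columns `d_nm` and `n_cm3`.",
          class = "radonaero_invalid_input")
  }
  check_nonneg(data$n_cm3, "n_cm3")
  if (any(data$d_nm <= 0)) {
    abort("Channel diameters must be positive.",
          class = "radonaero_invalid_input")
  }
  invisible(data)
}

.spectrum_groups <- function(data) {
  if ("timestamp" %in% names(data)) dplyr::group_by(data, .data$timestamp)
  else dplyr::group_by(data, .dummy = 1L)
}

#' Summarise a number size distribution
#'
#' Per spectrum: total number concentration \eqn{C_{tot} = \sum_i n_i},
#' number-weighted geometric-mean diameter
#' \eqn{d_{GM} = \exp(\sum n_i \ln d_i / \sum n_i)}, and the sub-cutoff
#' number fractions \eqn{x(<c) = C(<c)/C_{tot}} for each requested cutoff. A
#' channel counts as below a cutoff iff its center diameter is strictly
#' smaller. All-zero spectra have no defined summary and raise an error.
#'
#' @param data Long spectrum tibble with columns `d_nm`, `n_cm3` and
#'   optionally `timestamp` (one spectrum per timestamp).
#' @param cuts Diameter cutoffs in nm (default 10 and 20).
#' @return One row per spectrum: `c_tot` (cm^-3), `d_gm_nm`, and one
#'   `x_lt_<cut>` column per cutoff.
#' @examples
#' g <- size_grid("medium")
#' sp <- tibble::tibble(d_nm = g$d_nm, n_cm3 = stats::dlnorm(g$d_nm, log(57), log(1.9)))
#' summarize_spectrum(sp)
#' @export
summarize_spectrum <- function(data, cuts = c(10, 20)) {
  .check_spectrum(data)
  if (length(cuts) && is.unsorted(cuts, strictly = TRUE)) {
    abort("`cuts` must be strictly increasing.",
          class = "radonaero_invalid_input")
  }
  out <- dplyr::summarise(
    .spectrum_groups(data),
    c_tot = sum(.data$n_cm3),
    d_gm_nm = exp(sum(.data$n_cm3 * log(.data$d_nm)) / sum(.data$n_cm3)),
    !!!setNames(
      lapply(cuts, function(ct) {
        rlang::expr(sum(.data$n_cm3[.data$d_nm < !!ct]) / sum(.data$n_cm3))
      }),
      paste0("x_lt_", cuts)
    ),
    .groups = "drop"
  )
  if (any(out$c_tot == 0)) {
    abort("All-zero spectrum: summary undefined.",
          class = "radonaero_undefined_summary")
  }
  dplyr::select(out, -dplyr::any_of(".dummy"))
}

#' Normalised size distribution dN/dln d
#'
#' Divides each channel concentration by its logarithmic bin width, taken
#' from a channel grid ([size_grid()]) matched to the spectrum's diameters.
#'
#' @inheritParams summarize_spectrum
#' @param grid A [size_grid()] tibble; reconstructed log-uniformly from the
#'   spectrum's own diameter range when omitted.
#' @return `data` with a `dndlnd` column appended (cm^-3 per unit ln d).
#' @export
dndlnd <- function(data, grid = NULL) {
  .check_spectrum(data)
  d <- sort(unique(data$d_nm))
  if (is.null(grid)) grid <- size_grid(range(d), n_channels = length(d))
  idx <- match(round(log(data$d_nm), 10), round(log(grid$d_nm), 10))
  if (anyNA(idx)) {
    abort("Spectrum diameters do not match the channel grid.",
          class = "radonaero_invalid_input")
  }
  dplyr::mutate(as_tibble(data), dndlnd = .data$n_cm3 / grid$dln_d[idx])
}

#' Number and surface-area partition of a spectrum about a cutoff
#'
#' Splits each spectrum at a diameter cutoff and reports the below/above
#' ratios of number concentration and of total (spherical, \eqn{\pi d^2})
#' surface area. The two ratios answer different questions: a nucleation
#' burst can hold twice the *number* of particles below 10 nm while carrying
#' several-fold less *surface area* than the larger particles — and it is
#' surface area that competes for attaching progeny clusters.
#'
#' @inheritParams summarize_spectrum
#' @param cut Diameter cutoff, nm.
#' @return One row per spectrum: `n_lt`, `n_gt` (cm^-3), `n_ratio`, `s_lt`,
#'   `s_gt` (nm^2 cm^-3), `s_ratio`. An empty side of the cut makes the
#'   ratio undefined and raises an error rather than returning Inf.
#' @examples
#' sp <- tibble::tibble(d_nm = c(5, 50), n_cm3 = c(1000, 1000))
#' surface_partition(sp, cut = 10)
#' @export
surface_partition <- function(data, cut) {
  .check_spectrum(data)
  if (!is.numeric(cut) || length(cut) != 1L || cut <= 0) {
    abort("`cut` must be a single positive diameter (nm).",
          class = "radonaero_invalid_input")
  }
  out <- dplyr::summarise(
    .spectrum_groups(data),
    n_lt = sum(.data$n_cm3[.data$d_nm < cut]),
    n_gt = sum(.data$n_cm3[.data$d_nm >= cut]),
    s_lt = sum((.data$n_cm3 * pi * .data$d_nm^2)[.data$d_nm < cut]),
    s_gt = sum((.data$n_cm3 * pi * .data$d_nm^2)[.data$d_nm >= cut]),
    .groups = "drop"
  )
  if (any(out$n_lt == 0 | out$n_gt == 0)) {
    abort("Empty side of the cut: partition ratios undefined.",
          class = "radonaero_undefined_ratio")
  }
  out <- dplyr::mutate(out,
                       n_ratio = .data$n_lt / .data$n_gt,
                       s_ratio = .data$s_lt / .data$s_gt)
  dplyr::select(
    dplyr::select(out, -dplyr::any_of(".dummy")),
    dplyr::any_of("timestamp"), "n_lt", "n_gt", "n_ratio",
    "s_lt", "s_gt", "s_ratio"
  )
}

#' Total aerosol surface-area concentration of a spectrum
#'
#' Spherical surface per particle, \eqn{\pi d^2}, summed over channels.
#' Units nm^2 cm^-3. This is the quantity that drives progeny attachment in
#' the room model.
#'
#' @inheritParams summarize_spectrum
#' @return One row per spectrum with column `s_tot`.
#' @export
surface_total <- function(data) {
  .check_spectrum(data)
  out <- dplyr::summarise(.spectrum_groups(data),
                          s_tot = sum(.data$n_cm3 * pi * .data$d_nm^2),
                          .groups = "drop")
  dplyr::select(out, -dplyr::any_of(".dummy"))
}

#' Lognormal (and arithmetic) summary statistics of a series
#'
#' The summary convention for environmental concentration series: geometric
#' mean \eqn{GM = \exp(\overline{\ln x})} and geometric standard deviation
#' \eqn{GSD = \exp(sd(\ln x))}, alongside min/max and the arithmetic
#' mean/SD variant used for sign-changing quantities such as solar
#' radiation. Non-positive values carry no information about a lognormal
#' spread; they are dropped and counted, never imputed.
#'
#' @param x Numeric series.
#' @return A one-row tibble: `n`, `n_dropped`, `min`, `max`, `gm`, `gsd`,
#'   `mean`, `sd`.
#' @examples
#' gm_gsd(rlnorm(100, log(5120), log(1.5)))
#' @export
gm_gsd <- function(x) {
  if (!is.numeric(x)) {
    abort("`x` must be numeric.", class = "radonaero_invalid_input")
  }
  x <- x[!is.na(x)]
  keep <- x > 0
  dropped <- sum(!keep)
  x <- x[keep]
  if (length(x) == 0) {
    abort("No positive values: GM/GSD undefined.",
          class = "radonaero_invalid_input")
  }
  if (dropped > 0) {
    inform(paste("gm_gsd: dropped", dropped, "non-positive value(s)."))
  }
  lx <- log(x)
  tibble(
    n = length(x), n_dropped = dropped,
    min = min(x), max = max(x),
    gm = exp(mean(lx)),
    gsd = if (length(x) > 1) exp(sd(lx)) else NA_real_,
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else NA_real_
  )
}

#' Pearson correlation between two time-stamped series
#'
#' Averages both series onto a common time bin (half-hour by default), inner
#' joins on the bin, and reports the Pearson correlation coefficient of the
#' paired averages.
#'
#' @param a,b Data frames with columns `timestamp` (POSIXct or numeric
#'   seconds) and `value`.
#' @param bin_s Bin width in seconds (default 1800).
#' @return The correlation coefficient R.
#' @export
correlate_series <- function(a, b, bin_s = 1800) {
  bin <- function(df) {
    if (!all(c("timestamp", "value") %in% names(df))) {
      abort("Series need `timestamp` and `value` columns.",
            class = "radonaero_invalid_input")
    }
    df %>%
      dplyr::mutate(.bin = floor(as.numeric(.data$timestamp) / bin_s)) %>%
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .by = ".bin")
  }
  paired <- dplyr::inner_join(bin(a), bin(b), by = ".bin",
                              suffix = c("_a", "_b"))
  paired <- paired[stats::complete.cases(paired), ]
  if (nrow(paired) < 3) {
    abort("Fewer than 3 aligned pairs: correlation undefined.",
          class = "radonaero_undefined_correlation")
  }
  if (sd(paired$value_a) == 0 || sd(paired$value_b) == 0) {
    abort("Zero variance in an aligned series: correlation undefined.",
          class = "radonaero_undefined_correlation")
  }
  cor(paired$value_a, paired$value_b)
}

#' Diurnal (hour-of-day) profile of a series
#'
#' Aggregates a series spanning at least one full day by hour of day,
#' reporting arithmetic mean, geometric mean and number of records per hour.
#'
#' @param data Data frame with `timestamp` (POSIXct or numeric seconds) and
#'   `value` columns.
#' @return A tibble with columns `hour` (0-23), `n`, `mean`, `gm`.
#' @export
diurnal_profile <- function(data) {
  if (!all(c("timestamp", "value") %in% names(data))) {
    abort("`data` needs `timestamp` and `value` columns.",
          class = "radonaero_invalid_input")
  }
  ts <- as.numeric(data$timestamp)
  if (diff(range(ts)) < 86400) {
    abort("Series must span at least 24 h for a diurnal profile.",
          class = "radonaero_invalid_input")
  }
  hr <- if (inherits(data$timestamp, "POSIXt")) {
    as.POSIXlt(data$timestamp)$hour
  } else {
    floor((ts %% 86400) / 3600)
  }
  data %>%
    dplyr::mutate(hour = hr) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value, na.rm = TRUE),
      gm = if (all(.data$value > 0, na.rm = TRUE))
        exp(mean(log(.data$value), na.rm = TRUE)) else NA_real_,
      .by = "hour"
    ) %>%
    dplyr::arrange(.data$hour)
}
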