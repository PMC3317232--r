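# ggplot2 views of the package's result types. Figures are conveniences;
# every number they show comes from the tabular results.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   scale_x_log10 scale_y_log10 labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot chain ingrowth activities
#'
#' Activity of each chain member against time, the classic ingrowth-curve
#' view of a decay-chain trajectory.
#'
#' @param object A [bateman_ingrowth()] trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rn_chain_trajectory <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$time_s / 3600, y = .data$activity_bq_m3,
                   colour = .data$nuclide)) +
    geom_line() +
    labs(x = "time (h)", y = expression("activity (Bq m"^-3 * ")"),
         colour = NULL) +
    theme_minimal()
}

#' Plot a number size distribution
#'
#' dN/dln d against diameter on log-log axes; multiple timestamps are
#' overlaid as separate lines.
#'
#' @param data Long spectrum tibble (`timestamp` optional, `d_nm`, `n_cm3`).
#' @param grid Optional [size_grid()] for the bin widths.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(data, grid = NULL) {
  d <- dndlnd(data, grid = grid)
  p <- if ("timestamp" %in% names(d)) {
    ggplot(d, aes(x = .data$d_nm, y = .data$dndlnd,
                  group = .data$timestamp)) +
      geom_line(alpha = 0.4)
  } else {
    ggplot(d, aes(x = .data$d_nm, y = .data$dndlnd)) + geom_line()
  }
  p + scale_x_log10() +
    labs(x = "diameter (nm)",
         y = expression(dN / d * ln ~ d ~ "(cm"^-3 * ")")) +
    theme_minimal()
}

#' Overview plot of a simulated room run
#'
#' Total aerosol concentration, total surface area and the unattached
#' fraction of the true state, stacked as facets over time.
#'
#' @param object A [simulate_room()] run.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.room_run <- function(object, ...) {
  long <- object$state %>%
    dplyr::select("time_s", "c_tot", "s_tot", "f_un") %>%
    tidyr::pivot_longer(-"time_s", names_to = "variable")
  ggplot(long, aes(x = .data$time_s / 3600, y = .data$value)) +
    geom_line() +
    facet_wrap(~variable, ncol = 1, scales = "free_y") +
    labs(x = "time (h)", y = NULL) +
    theme_minimal()
}

#' Plot a diurnal profile
#'
#' @param profile A [diurnal_profile()] result.
#' @return A ggplot object showing the hourly means.
#' @export
plot_diurnal <- function(profile) {
  ggplot(profile, aes(x = .data$hour, y = .data$mean)) +
    geom_col() +
    labs(x = "hour of day", y = "mean") +
    theme_minimal()
}

#' Plot measured f_un against the inverse-concentration prediction
#'
#' Scatter of measured unattached fraction versus total aerosol number
#' concentration with the 400/C_tot curve overlaid — the diagnostic for
#' whether the classical inverse relation holds in a data set.
#'
#' @param fun_prediction The `fun_prediction` table of an [analyze_run()]
#'   report.
#' @return A ggplot object.
#' @export
plot_fun_prediction <- function(fun_prediction) {
  curve <- tibble(
    c_tot = exp(seq(log(min(fun_prediction$c_tot)),
                    log(max(fun_prediction$c_tot)), length.out = 100))
  )
  curve$f_un_predicted <- predicted_fun(curve$c_tot)
  ggplot(fun_prediction, aes(x = .data$c_tot, y = .data$f_un)) +
    geom_point() +
    geom_line(data = curve, aes(y = .data$f_un_predicted), colour = "red") +
    scale_x_log10() + scale_y_log10() +
    labs(x = expression(C[tot] ~ "(cm"^-3 * ")"), y = expression(f^un)) +
    theme_minimal()
}
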