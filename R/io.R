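# Instrument-style CSV dialects.
#
# SMPS: header of channel diameters in nm; one row per record, first column
# the timestamp. EQF: one row per 2-h record with radon and the six
# unattached/attached progeny activities. Timestamps are written as numeric
# seconds or ISO-8601 local clock time (timezone-naive), whichever they were.

.fmt_timestamp <- function(ts) {
  if (inherits(ts, "POSIXt")) format(ts, "%Y-%m-%dT%H:%M:%S") else ts
}

.parse_timestamp <- function(x) {
  if (is.numeric(x)) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out)) {
    abort("Unparseable timestamps (expected ISO-8601 or numeric seconds).",
          class = "radonaero_data_error")
  }
  out
}

#' Write / read spectrum records in the SMPS CSV dialect
#'
#' One row per record: timestamp followed by the 44 per-channel number
#' concentrations; the header carries the channel diameters in nm.
#'
#' @param data Long spectrum tibble (`timestamp`, `d_nm`, `n_cm3`).
#' @param path File path.
#' @return `write_smps_csv()` returns `path` invisibly; `read_smps_csv()`
#'   returns the long tibble.
#' @export
write_smps_csv <- function(data, path) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(data, timestamp = .fmt_timestamp(.data$timestamp),
                  d_nm = sprintf("%.4f", .data$d_nm)),
    names_from = "d_nm", values_from = "n_cm3"
  )
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_smps_csv
#' @export
read_smps_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(wide)[1] != "timestamp") {
    abort("SMPS CSV must start with a `timestamp` column.",
          class = "radonaero_data_error")
  }
  d <- suppressWarnings(as.numeric(names(wide)[-1]))
  if (anyNA(d)) {
    abort("SMPS CSV header must be channel diameters in nm.",
          class = "radonaero_data_error")
  }
  long <- tidyr::pivot_longer(wide, -"timestamp", names_to = "d_nm",
                              values_to = "n_cm3")
  dplyr::mutate(long,
                timestamp = .parse_timestamp(.data$timestamp),
                d_nm = as.numeric(.data$d_nm))
}

#' Write / read progeny records in the EQF CSV dialect
#'
#' Columns: `timestamp`, `rn`, `po218_un`, `pb214_un`, `bi214_un`,
#' `po218_att`, `pb214_att`, `bi214_att` (activity concentrations,
#' Bq m^-3).
#'
#' @param data Progeny record tibble.
#' @param path File path.
#' @return `write_eqf_csv()` returns `path` invisibly; `read_eqf_csv()` the
#'   tibble.
#' @export
write_eqf_csv <- function(data, path) {
  readr::write_csv(
    dplyr::mutate(data, timestamp = .fmt_timestamp(.data$timestamp)), path)
  invisible(path)
}

#' @rdname write_eqf_csv
#' @export
read_eqf_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("timestamp", "rn", "po218_un", "pb214_un", "bi214_un",
            "po218_att", "pb214_att", "bi214_att")
  if (!all(need %in% names(out))) {
    abort(paste("EQF CSV missing columns:",
                paste(setdiff(need, names(out)), collapse = ", ")),
          class = "radonaero_data_error")
  }
  dplyr::mutate(out, timestamp = .parse_timestamp(.data$timestamp))
}

#' Export a decay-chain trajectory as CSV
#'
#' Columns `time_s`, activities `a_rn` ... `a_po214` (Bq m^-3) and atom
#' numbers `n_rn` ... `n_bi214` (cm^-3).
#'
#' @param trajectory A [bateman_ingrowth()] result.
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(as_tibble(trajectory), path)
  invisible(path)
}

#' Write a simulated room run to a directory
#'
#' Emits `smps.csv`, `eqf.csv` and a plain-text `manifest.txt` recording the
#' configuration, seed and event script, so a run can be re-analysed (or
#' exactly reproduced) from its files alone.
#'
#' @param run A [simulate_room()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_room_run <- function(run, dir) {
  if (!inherits(run, "room_run")) {
    abort("`run` must come from simulate_room().",
          class = "radonaero_invalid_input")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_smps_csv(run$smps, file.path(dir, "smps.csv"))
  write_eqf_csv(run$eqf, file.path(dir, "eqf.csv"))
  cfg <- run$cfg
  scalars <- cfg[!vapply(cfg, is.data.frame, logical(1))]
  manifest <- c(
    "radonaero room run manifest",
    paste0(names(scalars), " = ",
           vapply(scalars, function(v)
             if (is.null(v)) "NULL" else paste(format(v), collapse = " "),
             character(1))),
    paste0("grid_range_nm = ", format(min(cfg$grid$d_nm), digits = 6), " ",
           format(max(cfg$grid$d_nm), digits = 6)),
    paste0("n_channels = ", nrow(cfg$grid)),
    "events:",
    if (nrow(run$script) == 0) "  (none)" else
      sprintf("  %s %g-%g h magnitude %g cm-3", run$script$kind,
              run$script$start_h, run$script$end_h, run$script$magnitude)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
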