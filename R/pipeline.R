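# End-to-end analysis: align the 4-min spectrum stream with the 2-h progeny
# stream, derive every exposure metric, summarise quiescent windows in the
# GM/GSD table layout, tabulate event windows, and compare measured f_un with
# the inverse-concentration prediction.

.qc_stream <- function(timestamps, values_nonneg, name) {
  ts <- as.numeric(sort(unique(timestamps)))
  cadence <- if (length(ts) > 1) stats::median(diff(ts)) else NA_real_
  gaps <- if (length(ts) > 1) {
    d <- diff(ts)
    idx <- which(d > 1.5 * cadence)
    tibble(gap_start = ts[idx], gap_end = ts[idx + 1], gap_s = d[idx])
  } else {
    tibble(gap_start = numeric(), gap_end = numeric(), gap_s = numeric())
  }
  tibble(
    stream = name,
    n_records = length(ts),
    cadence_s = cadence,
    n_gaps = nrow(gaps),
    longest_gap_s = if (nrow(gaps)) max(gaps$gap_s) else 0,
    n_negative = sum(values_nonneg < 0, na.rm = TRUE),
    n_zero = sum(values_nonneg == 0, na.rm = TRUE)
  )
}

# average SMPS-derived summaries onto half-open 2-h bins labelled by start
.align_to_bins <- function(summary_tbl, bin_s) {
  summary_tbl %>%
    dplyr::mutate(bin = floor(as.numeric(.data$timestamp) / bin_s) * bin_s) %>%
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .by = "bin") %>%
    dplyr::select(-dplyr::any_of("timestamp")) %>%
    dplyr::rename(timestamp = "bin")
}

#' Analyse aligned spectrum and progeny streams
#'
#' The report-generating verb: computes per-record spectrum summaries,
#' derives the progeny exposure metrics, averages the fast stream onto the
#' slow stream's 2-h bins (half-open, labelled by interval start), and
#' produces
#' \itemize{
#'   \item a QC table (records, cadence, gaps, zero/negative counts),
#'   \item the aligned metric series,
#'   \item a GM/GSD summary table over quiescent windows for the nine
#'     standard indoor parameters (C_tot, d_GM, x(<10), x(<20), C_Rn, EEC,
#'     F, f_un, x_un),
#'   \item event before/during/after tables via [segment_events()],
#'   \item measured f_un against the 400/C_tot prediction, with residuals.
#' }
#' Everything is deterministic: the same inputs give byte-identical tables.
#'
#' @param smps Long spectrum tibble (`timestamp`, `d_nm`, `n_cm3`).
#' @param eqf Progeny record tibble (see [read_eqf_csv()]).
#' @param cuts Diameter cutoffs for number fractions, nm.
#' @param quiescent_windows Optional tibble (`start`, `end`, in the
#'   timestamps' units) marking undisturbed periods for the summary table;
#'   default: the full overlap.
#' @param annotations Optional event annotation tibble (`timestamp`,
#'   `label`) for [segment_events()].
#' @param bin_s Alignment bin width in seconds (default 7200).
#' @param bi214_coefficient Passed to [progeny_metrics()].
#' @return A list of class `rndp_report`: `qc`, `series`, `summary`,
#'   `events`, `fun_prediction`.
#' @export
analyze_run <- function(smps, eqf, cuts = c(10, 20),
                        quiescent_windows = NULL, annotations = NULL,
                        bin_s = 7200,
                        bi214_coefficient = c("corrected", "printed")) {
  bi214_coefficient <- match.arg(bi214_coefficient)
  if (is.null(smps) && is.null(eqf)) {
    abort("At least one input stream is required.",
          class = "radonaero_data_error")
  }
  qc <- dplyr::bind_rows(
    if (!is.null(smps)) .qc_stream(smps$timestamp, smps$n_cm3, "smps"),
    if (!is.null(eqf)) .qc_stream(eqf$timestamp, as.matrix(
      eqf[setdiff(names(eqf), "timestamp")]), "eqf")
  )

  spec_sum <- if (!is.null(smps)) {
    summarize_spectrum(smps, cuts = cuts) %>%
      dplyr::left_join(surface_total(smps), by = "timestamp")
  } else NULL
  prog <- if (!is.null(eqf)) {
    progeny_metrics(eqf, record_duration_h = bin_s / 3600,
                    bi214_coefficient = bi214_coefficient)
  } else NULL

  series <- if (!is.null(spec_sum) && !is.null(prog)) {
    joined <- dplyr::inner_join(
      .align_to_bins(spec_sum, bin_s),
      dplyr::mutate(prog,
                    timestamp = floor(as.numeric(.data$timestamp) / bin_s) * bin_s),
      by = "timestamp"
    )
    if (nrow(joined) == 0) {
      abort("No overlapping time coverage between the SMPS and EQF streams.",
            class = "radonaero_alignment_error")
    }
    joined
  } else {
    spec_sum %||% prog
  }

  in_windows <- function(ts) {
    if (is.null(quiescent_windows)) rep(TRUE, length(ts))
    else {
      Reduce(`|`, lapply(seq_len(nrow(quiescent_windows)), function(i) {
        as.numeric(ts) >= as.numeric(quiescent_windows$start[i]) &
          as.numeric(ts) < as.numeric(quiescent_windows$end[i])
      }))
    }
  }

  summary_params <- c(
    c_tot = "c_tot", d_gm_nm = "d_gm_nm",
    setNames(paste0("x_lt_", cuts), paste0("x_lt_", cuts)),
    c_rn = "rn", eec = "eec", f_equilibrium = "f_equilibrium",
    f_un = "f_un", x_un = "x_un"
  )
  quiet <- series[in_windows(series$timestamp), , drop = FALSE]
  summary_tbl <- purrr::map_dfr(names(summary_params), function(pname) {
    col <- summary_params[[pname]]
    if (!col %in% names(quiet)) return(NULL)
    v <- quiet[[col]]
    v <- v[!is.na(v) & v > 0]
    if (length(v) == 0) return(NULL)
    dplyr::mutate(gm_gsd(v), parameter = pname, .before = 1)
  })

  events <- if (!is.null(annotations) && nrow(annotations) > 0) {
    segment_events(series, annotations)
  } else {
    tibble(label = character(), phase = character(),
           parameter = character(), gm = numeric())
  }

  fun_pred <- if (!is.null(spec_sum) && !is.null(prog) &&
                  all(c("f_un", "c_tot") %in% names(series))) {
    series %>%
      dplyr::select("timestamp", "c_tot", "f_un") %>%
      dplyr::filter(!is.na(.data$f_un), .data$c_tot > 0) %>%
      dplyr::mutate(f_un_predicted = predicted_fun(.data$c_tot),
                    residual = .data$f_un - .data$f_un_predicted)
  } else NULL

  structure(list(qc = qc, series = series, summary = summary_tbl,
                 events = events, fun_prediction = fun_pred),
            class = "rndp_report")
}

#' Before/during/after windows around annotated events
#'
#' For each annotation, takes a window of `before_h` hours before the label,
#' the labelled instant's bin as "during" (or the annotated duration if an
#' `end` column is present), and `after_h` hours after, and reports the
#' geometric mean of every numeric metric in each phase. Annotations outside
#' the series' coverage are skipped with a warning.
#'
#' @param series Aligned metric series (from [analyze_run()]'s `series`).
#' @param annotations Tibble with `timestamp` (event start), optional `end`,
#'   and `label`.
#' @param before_h,after_h Window lengths, hours (default 2 each).
#' @return A long tibble: `label`, `phase` (before/during/after),
#'   `parameter`, `gm`, `n`.
#' @export
segment_events <- function(series, annotations, before_h = 2, after_h = 2) {
  ts <- as.numeric(series$timestamp)
  span <- range(ts)
  out <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    t0 <- as.numeric(annotations$timestamp[i])
    t1 <- if ("end" %in% names(annotations)) {
      as.numeric(annotations$end[i])
    } else {
      t0 + 7200
    }
    if (t0 < span[1] || t0 > span[2]) {
      warn(paste0("Annotation '", annotations$label[i],
                  "' lies outside the series coverage; skipped."))
      return(NULL)
    }
    phases <- tibble(
      phase = c("before", "during", "after"),
      lo = c(t0 - before_h * 3600, t0, t1),
      hi = c(t0, t1, t1 + after_h * 3600)
    )
    purrr::map_dfr(seq_len(3), function(k) {
      sel <- series[ts >= phases$lo[k] & ts < phases$hi[k], , drop = FALSE]
      num <- sel[vapply(sel, is.numeric, logical(1))]
      num <- num[setdiff(names(num), "timestamp")]
      if (nrow(num) == 0) return(NULL)
      purrr::map_dfr(names(num), function(col) {
        v <- num[[col]]
        v <- v[!is.na(v) & v > 0]
        if (length(v) == 0) return(NULL)
        tibble(label = annotations$label[i], phase = phases$phase[k],
               parameter = col, gm = exp(mean(log(v))), n = length(v))
      })
    })
  })
  if (is.null(out) || ncol(out) == 0) {
    out <- tibble(label = character(), phase = character(),
                  parameter = character(), gm = numeric(), n = integer())
  }
  out
}

#' Write an analysis report bundle to CSV files
#'
#' @param report An [analyze_run()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "rndp_report")) {
    abort("`report` must come from analyze_run().",
          class = "radonaero_invalid_input")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$qc, file.path(dir, "qc.csv"))
  readr::write_csv(report$series, file.path(dir, "series.csv"))
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  readr::write_csv(report$events, file.path(dir, "events.csv"))
  if (!is.null(report$fun_prediction)) {
    readr::write_csv(report$fun_prediction, file.path(dir, "fun_prediction.csv"))
  }
  invisible(dir)
}

#' @export
print.rndp_report <- function(x, ...) {
  cat("RnDP analysis report:", nrow(x$series), "aligned records,",
      nrow(x$summary), "summary parameters,",
      length(unique(x$events$label)), "events\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.rndp_report <- function(x, ...) {
  gm_of <- function(p) {
    v <- x$summary$gm[x$summary$parameter == p]
    if (length(v)) v else NA_real_
  }
  tibble(
    n_records = nrow(x$series),
    c_tot_gm = gm_of("c_tot"),
    c_rn_gm = gm_of("c_rn"),
    eec_gm = gm_of("eec"),
    f_un_gm = gm_of("f_un")
  )
}
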