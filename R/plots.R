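# Visualization: longitudinal volume trends, DVH spread (sliding
# box-and-whiskers) plots, and dosimetric-objective distributions.
#
# Every figure is built from a figure_spec object that carries the complete
# tabular series behind each visual element; rendering is a pure function of
# the spec, so tests assert on the exported series rather than pixels, and
# each image is written with its series as a CSV sidecar.

new_figure_spec <- function(kind, series, options = list()) {
  structure(list(kind = kind, series = series, options = options),
            class = "figure_spec")
}

#' @export
print.figure_spec <- function(x, ...) {
  cat(sprintf("<figure_spec> %s: %d series row(s)%s\n", x$kind, nrow(x$series),
              if (length(x$options)) paste0(" [",
                paste(names(x$options), unlist(lapply(x$options, format)),
                      sep = "=", collapse = ", "), "]") else ""))
  invisible(x)
}

write_figure <- function(spec, plot, file) {
  if (is.null(file)) return(invisible(NULL))
  ext <- tolower(tools::file_ext(file))
  if (!ext %in% c("png", "svg")) {
    oartex_error("figure output must be .png or .svg", "oartex_config_error")
  }
  dev <- if (ext == "svg") grDevices::svg else ext
  ggplot2::ggsave(file, plot, device = dev, width = 8, height = 5, dpi = 150)
  utils::write.csv(spec$series, paste0(tools::file_path_sans_ext(file), "_series.csv"),
                   row.names = FALSE)
  invisible(file)
}

#' Longitudinal structure-volume trend figure
#'
#' One point per delivered session: x is the fraction number, y the
#' structure volume (absolute mode, cm3) or the relative volume change
#' versus the reference structure set (relative mode, %). Point colour
#' encodes whether the session was adapted or treated with the scheduled
#' plan; the reference baseline is a horizontal line (the reference volume,
#' or 0% in relative mode).
#'
#' @param course A `course_record`.
#' @param structure Structure name.
#' @param mode `"relative"` or `"absolute"`.
#' @param file Optional output image (`.png`/`.svg`); its series is written
#'   alongside as `*_series.csv`.
#' @return A `figure_spec` (invisibly when `file` given). `spec$series` has
#'   one row per delivered fraction.
#' @export
plot_volume_trend <- function(course, structure, mode = c("relative", "absolute"),
                              file = NULL) {
  mode <- match.arg(mode)
  trend <- volume_trend(course, structure)
  if (!nrow(trend)) {
    avail <- if (!is.null(course$reference_doc)) {
      vapply(course$reference_doc$structures, `[[`, character(1), "name")
    } else character()
    oartex_error(sprintf("no volume data for structure '%s'; available: %s",
                         structure, paste(avail, collapse = ", ")),
                 "oartex_missing_structure")
  }
  trend$value <- if (mode == "relative") 100 * trend$delta_rel else trend$volume_cm3
  trend$session <- ifelse(trend$adapted, "adapted", "scheduled")
  ref_entry <- if (!is.null(course$reference_doc)) {
    find_structure(course$reference_doc, structure)
  }
  baseline <- if (mode == "relative") 0 else
    if (!is.null(ref_entry)) as.numeric(ref_entry$volume_cm3) else NA_real_
  spec <- new_figure_spec("volume_trend", trend,
                          list(structure = structure, mode = mode,
                               baseline = baseline))
  p <- ggplot2::ggplot(trend, ggplot2::aes(x = .data$fraction, y = .data$value,
                                           colour = .data$session)) +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Fraction",
                  y = if (mode == "relative") "Volume change vs reference (%)"
                      else "Volume (cm³)",
                  colour = "Session",
                  title = sprintf("%s volume over the course (%s)", structure,
                                  course$patient_id)) +
    ggplot2::theme_minimal()
  write_figure(spec, p, file)
  if (is.null(file)) spec else invisible(spec)
}

#' DVH spread (sliding box-and-whiskers) figure
#'
#' For each requested structure, aggregates the daily DVH curves of the
#' course into percentile bands: the light band spans the extrema, the dark
#' band the 20th-80th percentile range, the solid line is the median and the
#' dashed line the reference plan's DVH. Adaptive-plan and scheduled-plan
#' aggregates are shown side by side.
#'
#' @param course A `course_record`.
#' @param structures Character vector of structure names.
#' @param phase `"primary"` or `"boost"`: which treatment phase's fractions
#'   to aggregate. Fractions before `boost_start` are primary, the rest
#'   boost; with no `boost_start` the whole course is primary.
#' @param boost_start First boost fraction number, or `NULL`.
#' @param source DVH source: `"tpms"` or `"secondary"` (never mixed).
#' @param grid_step Dose grid step in Gy.
#' @param file Optional output image path.
#' @return A `figure_spec`; `series` has one row per (structure, panel,
#'   grid dose) with columns `lo`, `p20`, `median`, `p80`, `hi`,
#'   `reference`.
#' @export
plot_dvh_spread <- function(course, structures, phase = c("primary", "boost"),
                            boost_start = NULL, source = c("tpms", "secondary"),
                            grid_step = 0.1, file = NULL) {
  phase <- match.arg(phase)
  source <- match.arg(source)
  fracs <- vapply(course$fractions, `[[`, integer(1), "fraction")
  in_phase <- if (is.null(boost_start)) {
    if (phase == "primary") rep(TRUE, length(fracs)) else rep(FALSE, length(fracs))
  } else if (phase == "primary") fracs < boost_start else fracs >= boost_start
  if (!any(in_phase)) {
    oartex_error(sprintf("no fractions in the %s phase", phase),
                 "oartex_empty_phase")
  }
  sessions <- course$fractions[in_phase]

  series <- list()
  for (st in structures) {
    ref_dvh <- if (!is.null(course$reference_doc)) {
      document_dvh(course$reference_doc, st, source)
    }
    for (panel in c("adaptive", "scheduled")) {
      curves <- list()
      for (fs in sessions) {
        doc <- select_fraction_plan(fs, panel)
        if (is.null(doc)) next
        d <- document_dvh(doc, st, source)
        if (!is.null(d)) curves[[length(curves) + 1L]] <- d
      }
      if (!length(curves)) {
        oartex_error(sprintf("no %s-plan DVH curves for structure '%s'", panel, st),
                     "oartex_missing_structure")
      }
      band <- dvh_band(curves, reference = ref_dvh, grid_step = grid_step)
      series[[length(series) + 1L]] <- data.frame(
        structure = st, panel = panel, dose_gy = band$grid,
        lo = band$lo, p20 = band$p20, median = band$median,
        p80 = band$p80, hi = band$hi,
        reference = band$reference %||% NA_real_)
    }
  }
  series <- do.call(rbind, series)
  spec <- new_figure_spec("dvh_spread", series,
                          list(phase = phase, source = source,
                               grid_step = grid_step))
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$dose_gy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$structure), alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p20, ymax = .data$p80,
                                      fill = .data$structure), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median, colour = .data$structure)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reference, colour = .data$structure),
                       linetype = "dashed", na.rm = TRUE) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = sprintf("DVH spread, %s phase (%s dose)", phase, source)) +
    ggplot2::theme_minimal()
  write_figure(spec, p, file)
  if (is.null(file)) spec else invisible(spec)
}

#' Dosimetric-objective distribution figure
#'
#' Distribution of one dose-volume objective across all sessions of a
#' cohort. `comparison = "vs_reference"` plots each plan's value minus its
#' patient's reference-plan value; `comparison = "adaptive_vs_scheduled"`
#' plots paired per-fraction differences between the adaptive and scheduled
#' plan of the same structure-set revision — both the difference in
#' percentage points (`diff`) and the ratio (`ratio`) are exported, since
#' either reading of a "relative difference" may be wanted. Default binning
#' is Freedman-Diaconis.
#'
#' @param store A `cohort_store` whose rows carry the objective column (see
#'   [course_to_rows()]; the column is named by the objective label, e.g.
#'   `V42.5Gy_Rectum`).
#' @param spec An [objective_spec()].
#' @param grouping `"overlay"` or `"side_by_side"` panel layout for the
#'   adaptive and scheduled distributions.
#' @param comparison `"vs_reference"` or `"adaptive_vs_scheduled"`.
#' @param file Optional output image path.
#' @return A `figure_spec`; for `vs_reference` the series has one row per
#'   contributing (patient, fraction, plan type), for
#'   `adaptive_vs_scheduled` one row per contributing (patient, fraction).
#' @export
plot_objective_distribution <- function(store, spec,
                                        grouping = c("overlay", "side_by_side"),
                                        comparison = c("vs_reference",
                                                       "adaptive_vs_scheduled"),
                                        file = NULL) {
  stopifnot(inherits(store, "cohort_store"), inherits(spec, "objective_spec"))
  grouping <- match.arg(grouping)
  comparison <- match.arg(comparison)
  col <- objective_label(spec)
  rows <- store$rows
  if (!col %in% names(rows)) {
    oartex_error(sprintf("objective column '%s' not present in the cohort", col),
                 "oartex_missing_objective")
  }
  rows <- rows[normalize_roi(rows$structure) == normalize_roi(spec$structure) &
                 !is.na(rows[[col]]), , drop = FALSE]
  if (!nrow(rows)) {
    oartex_error(sprintf("objective '%s' is missing in every session", col),
                 "oartex_missing_objective")
  }

  if (comparison == "vs_reference") {
    refs <- rows[rows$plan_type == "reference", , drop = FALSE]
    ref_by_pat <- stats::setNames(refs[[col]], refs$patient_uid)
    sess <- rows[rows$plan_type %in% c("adaptive", "scheduled") &
                   rows$patient_uid %in% names(ref_by_pat), , drop = FALSE]
    series <- data.frame(
      patient_uid = sess$patient_uid, fraction = sess$fraction,
      plan_type = sess$plan_type, value = sess[[col]],
      reference = ref_by_pat[sess$patient_uid],
      stringsAsFactors = FALSE)
    series$diff <- series$value - series$reference
    series$ratio <- ifelse(series$reference != 0,
                           series$value / series$reference, NA_real_)
    xlab <- sprintf("%s minus reference value", col)
  } else {
    sess <- rows[rows$plan_type %in% c("adaptive", "scheduled"), , drop = FALSE]
    pieces <- split(sess, list(sess$patient_uid, sess$fraction), drop = TRUE)
    out <- lapply(pieces, function(g) {
      rev_target <- if (any(g$delivered %in% TRUE)) {
        g$revision[g$delivered %in% TRUE][1]
      } else max(g$revision)
      g <- g[g$revision == rev_target, , drop = FALSE]
      adp <- g[[col]][g$plan_type == "adaptive"]
      sch <- g[[col]][g$plan_type == "scheduled"]
      if (!length(adp) || !length(sch)) return(NULL)
      data.frame(patient_uid = g$patient_uid[1], fraction = g$fraction[1],
                 adaptive = adp[1], scheduled = sch[1],
                 diff = adp[1] - sch[1],
                 ratio = if (sch[1] != 0) adp[1] / sch[1] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    series <- do.call(rbind, out)
    rownames(series) <- NULL
    xlab <- sprintf("%s: adaptive minus scheduled", col)
  }

  fig <- new_figure_spec("objective_distribution", series,
                         list(objective = col, comparison = comparison,
                              grouping = grouping))
  binwidth <- fd_binwidth(series$diff)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$diff))
  p <- if (comparison == "vs_reference" && grouping == "overlay") {
    p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$plan_type),
                                position = "identity", alpha = 0.5,
                                binwidth = binwidth)
  } else if (comparison == "vs_reference") {
    p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$plan_type),
                                binwidth = binwidth) +
      ggplot2::facet_wrap(~plan_type)
  } else {
    p + ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue")
  }
  p <- p + ggplot2::labs(x = xlab, y = "Sessions") + ggplot2::theme_minimal()
  write_figure(fig, p, file)
  if (is.null(file)) fig else invisible(fig)
}

# Freedman-Diaconis binwidth with a degenerate-data fallback.
fd_binwidth <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(NULL)
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) NULL else bw
}
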