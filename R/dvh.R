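# Cumulative DVH reconstruction and dose-volume objectives.
#
# The source system stores each structure's cumulative DVH as a truncated
# point list: the flat 100% head and the 0% tail are omitted. A continuous
# dose -> volume% function is rebuilt by piecewise-linear interpolation over
# the listed points, padded to exactly 100% below the first listed dose and
# exactly 0% above the last. Padding is exact by construction, not a limit.

#' Build a continuous cumulative DVH from a truncated point list
#'
#' @param dose_gy Numeric vector of doses in Gy (non-negative).
#' @param volume_pct Numeric vector of cumulative volume percentages, same
#'   length as `dose_gy`.
#'
#' @details Input points are sorted by dose; duplicate doses are collapsed
#' keeping the maximum volume; volumes are clipped to `[0, 100]`. A
#' non-monotone input (volume increasing with dose) is repaired by a running
#' cumulative minimum, with a warning — such lists indicate an upstream
#' artifact but should not kill a course extraction.
#'
#' @return An object of class `dvh`: list with `dose_gy`, `volume_pct` (the
#'   cleaned node lists) and `max_dose_gy`.
#' @examples
#' d <- build_dvh(c(10, 20), c(80, 20))
#' volume_at_dose(d, 5)   # 100 (below listed range)
#' volume_at_dose(d, 15)  # 50  (linear interpolation)
#' volume_at_dose(d, 25)  # 0   (above listed range)
#' @export
build_dvh <- function(dose_gy, volume_pct) {
  if (length(dose_gy) < 1L) {
    oartex_error("cannot build a DVH from an empty point list", "oartex_empty_dvh")
  }
  if (length(dose_gy) != length(volume_pct)) {
    oartex_error("dose and volume vectors must have equal length", "oartex_domain_error")
  }
  if (any(!is.finite(dose_gy)) || any(!is.finite(volume_pct))) {
    oartex_error("DVH points must be finite", "oartex_domain_error")
  }
  if (any(dose_gy < 0)) {
    oartex_error("DVH doses must be non-negative", "oartex_domain_error")
  }
  ord <- order(dose_gy)
  dose_gy <- dose_gy[ord]; volume_pct <- volume_pct[ord]
  # collapse duplicate doses keeping max volume
  if (anyDuplicated(dose_gy)) {
    volume_pct <- vapply(split(volume_pct, match(dose_gy, unique(dose_gy))),
                         max, numeric(1))
    dose_gy <- unique(dose_gy)
  }
  volume_pct <- pmin(100, pmax(0, volume_pct))
  if (is.unsorted(rev(volume_pct))) {
    oartex_warn("non-monotone DVH point list repaired by cumulative minimum",
                "oartex_dvh_repair")
    volume_pct <- cummin(volume_pct)
  }
  structure(list(dose_gy = as.numeric(dose_gy),
                 volume_pct = as.numeric(volume_pct),
                 max_dose_gy = dose_gy[length(dose_gy)]),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d points, dose range [%.3g, %.3g] Gy, volume range [%.3g, %.3g]%%\n",
              length(x$dose_gy), x$dose_gy[1], x$max_dose_gy,
              min(x$volume_pct), max(x$volume_pct)))
  invisible(x)
}

#' Volume receiving at least a given dose (V_D)
#'
#' Evaluates the cumulative DVH at `dose`: the percentage of the structure's
#' volume receiving at least that dose. Below the first listed dose the
#' result is exactly 100; above the last it is exactly 0.
#'
#' @param dvh A `dvh` object from [build_dvh()].
#' @param dose Dose(s) in Gy, non-negative (vectorised).
#' @return Volume percentage(s) in `[0, 100]`.
#' @export
volume_at_dose <- function(dvh, dose) {
  stopifnot(inherits(dvh, "dvh"))
  if (any(!is.finite(dose)) || any(dose < 0)) {
    oartex_error("dose must be finite and non-negative", "oartex_domain_error")
  }
  if (length(dvh$dose_gy) == 1L) {
    out <- ifelse(dose < dvh$dose_gy, 100,
                  ifelse(dose > dvh$dose_gy, 0, dvh$volume_pct))
    return(as.numeric(out))
  }
  out <- stats::approx(dvh$dose_gy, dvh$volume_pct, xout = dose,
                       method = "linear", yleft = NA, yright = NA)$y
  out[dose < dvh$dose_gy[1]] <- 100
  out[dose > dvh$max_dose_gy] <- 0
  as.numeric(out)
}

#' Minimum dose to the hottest V% of a structure (D_V)
#'
#' Returns the smallest dose `d` at which the cumulative DVH has dropped to
#' at most `volume` percent. On flat segments the left endpoint (smallest
#' dose) is returned, which is deterministic and conservative. `volume = 100`
#' gives 0 Gy for any curve (padding holds 100% below the listed range); a
#' target below the last listed volume returns the last listed dose, beyond
#' which the padded curve is 0.
#'
#' @param dvh A `dvh` object.
#' @param volume Target volume percentage in `[0, 100]` (vectorised).
#' @return Dose(s) in Gy.
#' @examples
#' d <- build_dvh(c(10, 20), c(80, 20))
#' dose_at_volume(d, 50)  # 15
#' @export
dose_at_volume <- function(dvh, volume) {
  stopifnot(inherits(dvh, "dvh"))
  if (any(!is.finite(volume)) || any(volume < 0) || any(volume > 100)) {
    oartex_error("volume must be in [0, 100]", "oartex_domain_error")
  }
  vapply(volume, function(v) .dose_at_volume_one(dvh, v), numeric(1))
}

.dose_at_volume_one <- function(dvh, v) {
  d <- dvh$dose_gy; vol <- dvh$volume_pct
  if (v >= 100) return(0)
  # walk segments left to right; first dose where the curve is <= v
  if (vol[1] <= v) return(d[1])
  n <- length(d)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      v0 <- vol[i]; v1 <- vol[i + 1L]
      if (v1 <= v) {
        if (v0 == v1) return(d[i])  # flat segment: left endpoint
        return(d[i] + (v0 - v) / (v0 - v1) * (d[i + 1L] - d[i]))
      }
    }
  }
  # target below the listed tail: curve only reaches it past the last point
  d[n]
}

#' Percentile band of a set of DVH curves
#'
#' Evaluates every curve on a shared dose grid (0 to the largest listed dose
#' plus one step) and computes, at each grid dose, the minimum, 20th
#' percentile, median, 80th percentile and maximum of the evaluated volumes.
#' Percentiles use linear interpolation between closest order statistics
#' ([stats::quantile()] type 7). This is the data behind a DVH
#' "sliding box-and-whiskers" spread plot.
#'
#' @param curves List of `dvh` objects (at least one).
#' @param reference Optional reference `dvh`, evaluated on the same grid.
#' @param grid_step Dose grid step in Gy (default 0.1).
#' @return Object of class `dvh_band`: list with `grid` (dose, Gy) and
#'   volume-percent vectors `lo`, `p20`, `median`, `p80`, `hi`, plus
#'   `reference` when supplied. Pointwise `lo <= p20 <= median <= p80 <= hi`.
#' @export
dvh_band <- function(curves, reference = NULL, grid_step = 0.1) {
  if (length(curves) < 1L) {
    oartex_error("dvh_band needs at least one curve", "oartex_domain_error")
  }
  stopifnot(all(vapply(curves, inherits, logical(1), "dvh")))
  assert_scalar_number(grid_step, "grid_step", min = 0, strict_min = TRUE)
  dmax <- max(vapply(curves, function(x) x$max_dose_gy, numeric(1)),
              if (!is.null(reference)) reference$max_dose_gy else 0)
  grid <- seq(0, dmax + grid_step, by = grid_step)
  vals <- vapply(curves, volume_at_dose, numeric(length(grid)), dose = grid)
  vals <- matrix(vals, nrow = length(grid))
  q <- apply(vals, 1L, stats::quantile, probs = c(0.2, 0.5, 0.8), type = 7,
             names = FALSE)
  band <- structure(list(
    grid = grid,
    lo = apply(vals, 1L, min),
    p20 = q[1L, ],
    median = q[2L, ],
    p80 = q[3L, ],
    hi = apply(vals, 1L, max),
    n_curves = length(curves)
  ), class = "dvh_band")
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "dvh"))
    band$reference <- volume_at_dose(reference, grid)
  }
  band
}

#' @export
print.dvh_band <- function(x, ...) {
  cat(sprintf("<dvh_band> %d curves on %d grid points (0 to %.3g Gy)%s\n",
              x$n_curves, length(x$grid), max(x$grid),
              if (!is.null(x$reference)) ", with reference curve" else ""))
  invisible(x)
}

#' Dose-volume objective specification
#'
#' Describes a single dosimetric objective to evaluate against a structure's
#' DVH: either `V_at_dose` (volume percentage receiving at least `threshold`
#' Gy, e.g. V42.5Gy to rectum) or `D_at_volume` (minimum dose to the hottest
#' `threshold` percent).
#'
#' @param kind `"V_at_dose"` or `"D_at_volume"`.
#' @param threshold Dose in Gy (for V) or volume percentage (for D), >= 0.
#' @param structure Structure name the objective applies to.
#' @param relative_to_reference If `TRUE`, downstream evaluation also reports
#'   the difference to the reference plan's value.
#' @return An `objective_spec` object.
#' @export
objective_spec <- function(kind = c("V_at_dose", "D_at_volume"), threshold,
                           structure, relative_to_reference = TRUE) {
  kind <- match.arg(kind)
  assert_scalar_number(threshold, "threshold", min = 0)
  if (kind == "D_at_volume" && threshold > 100) {
    oartex_error("volume threshold must be <= 100", "oartex_domain_error")
  }
  structure(list(kind = kind, threshold = threshold, structure = structure,
                 relative_to_reference = isTRUE(relative_to_reference)),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  lab <- if (x$kind == "V_at_dose") sprintf("V%.4gGy", x$threshold)
         else sprintf("D%.4g%%", x$threshold)
  cat(sprintf("<objective_spec> %s to %s\n", lab, x$structure))
  invisible(x)
}

# Short machine label for an objective, used as a cohort column name.
objective_label <- function(spec) {
  if (spec$kind == "V_at_dose") sprintf("V%.4gGy_%s", spec$threshold, spec$structure)
  else sprintf("D%.4gpct_%s", spec$threshold, spec$structure)
}

evaluate_objective <- function(dvh, spec) {
  if (spec$kind == "V_at_dose") volume_at_dose(dvh, spec$threshold)
  else dose_at_volume(dvh, spec$threshold)
}

#' Per-fraction series of a dosimetric objective over a course
#'
#' Evaluates one objective for every fraction of a course, selecting per
#' fraction the plan requested by `plan_filter`: the `"delivered"` plan, or
#' the `"adaptive"`/`"scheduled"` plan of the delivered structure-set revision
#' (falling back to the highest revision when no plan was delivered). The
#' relative value is the plan value minus the reference plan's value.
#'
#' @param course A `course_record` from [build_course()].
#' @param spec An [objective_spec()].
#' @param plan_filter `"delivered"`, `"adaptive"` or `"scheduled"`.
#' @param source DVH source to evaluate: `"tpms"` (treatment planning /
#'   on-couch dose) or `"secondary"` (independent recalculation). The two
#'   series are never mixed.
#' @return A data.frame with columns `fraction`, `plan_name`, `value`,
#'   `reference_value`, `relative_value` (`value - reference_value`) and
#'   `missing` (TRUE when the structure was absent from that fraction's
#'   document — flagged, never coerced to zero).
#' @export
objective_series <- function(course, spec,
                             plan_filter = c("delivered", "adaptive", "scheduled"),
                             source = c("tpms", "secondary")) {
  stopifnot(inherits(course, "course_record"), inherits(spec, "objective_spec"))
  plan_filter <- match.arg(plan_filter)
  source <- match.arg(source)

  ref_value <- NA_real_
  if (!is.null(course$reference_doc)) {
    ref_dvh <- document_dvh(course$reference_doc, spec$structure, source)
    if (!is.null(ref_dvh)) ref_value <- evaluate_objective(ref_dvh, spec)
  }

  rows <- lapply(course$fractions, function(fs) {
    doc <- select_fraction_plan(fs, plan_filter)
    if (is.null(doc)) return(NULL)
    dvh <- document_dvh(doc, spec$structure, source)
    if (is.null(dvh)) {
      return(data.frame(fraction = fs$fraction, plan_name = doc$planName_str,
                        value = NA_real_, reference_value = ref_value,
                        relative_value = NA_real_, missing = TRUE))
    }
    v <- evaluate_objective(dvh, spec)
    data.frame(fraction = fs$fraction, plan_name = doc$planName_str,
               value = v, reference_value = ref_value,
               relative_value = v - ref_value, missing = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fraction = integer(), plan_name = character(),
                      value = numeric(), reference_value = numeric(),
                      relative_value = numeric(), missing = logical())
  }
  out[order(out$fraction), , drop = FALSE]
}

# Pick the document a plan_filter refers to within one fraction session:
# the delivered plan, or the adaptive/scheduled plan of the delivered
# revision (else the highest revision).
select_fraction_plan <- function(fs, plan_filter) {
  if (plan_filter == "delivered") return(fs$delivered_doc)
  rev_target <- if (!is.null(fs$delivered_doc)) {
    parse_plan_name(fs$delivered_doc$planName_str)$revision
  } else {
    max(vapply(fs$pairs, function(p) p$revision, integer(1)))
  }
  for (p in fs$pairs) {
    if (p$revision == rev_target) {
      return(if (plan_filter == "adaptive") p$adaptive_doc else p$scheduled_doc)
    }
  }
  NULL
}

# Extract one structure's DVH from a plan-check document, or NULL if absent.
document_dvh <- function(doc, structure, source = c("tpms", "secondary")) {
  source <- match.arg(source)
  entry <- doc$dvh[[source]][[structure]]
  if (is.null(entry)) return(NULL)
  build_dvh(as.numeric(entry$dose_gy), as.numeric(entry$volume_pct))
}

#' Write DVH node lists to CSV
#'
#' Long-format interchange: columns `structure`, `source`, `dose_gy`,
#' `volume_pct`. The inverse of [read_dvh_csv()].
#'
#' @param doc A plan-check document (list with a `dvh` field).
#' @param path Output CSV path.
#' @export
write_dvh_csv <- function(doc, path) {
  rows <- list()
  for (src in names(doc$dvh)) {
    for (st in names(doc$dvh[[src]])) {
      e <- doc$dvh[[src]][[st]]
      rows[[length(rows) + 1L]] <- data.frame(
        structure = st, source = src,
        dose_gy = as.numeric(e$dose_gy), volume_pct = as.numeric(e$volume_pct))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read DVH node lists from CSV written by [write_dvh_csv()]
#'
#' @param path CSV path.
#' @return Nested list `dvh[[source]][[structure]]` with `dose_gy`,
#'   `volume_pct` fields.
#' @export
read_dvh_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (src in unique(tab$source)) {
    out[[src]] <- list()
    sub <- tab[tab$source == src, , drop = FALSE]
    for (st in unique(sub$structure)) {
      ss <- sub[sub$structure == st, , drop = FALSE]
      out[[src]][[st]] <- list(dose_gy = ss$dose_gy, volume_pct = ss$volume_pct)
    }
  }
  out
}
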