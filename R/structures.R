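# Structure-role assignment and longitudinal volume analytics.
#
# ROI names vary across institutions, so organ-at-risk lookup goes through a
# per-site registry of canonical names with synonym lists; matching is
# case-insensitive and ignores whitespace/underscores. Target structures are
# recognised by a PTV/CTV name prefix and tiered by prescribed dose. Daily
# consistency metrics are limited to what the data source carries: structure
# volume and centroid (center-of-mass) position — no contour geometry is
# available, so overlap metrics such as Dice are out of reach by design.

normalize_roi <- function(x) gsub("[[:space:]_]+", "", tolower(x))

#' Built-in organ-at-risk registry
#'
#' Ships default OAR lists per treatment site: pelvis (bladder, rectum,
#' bowel space), thorax and head-and-neck. Extend or replace a site's list
#' with [set_oars()].
#'
#' @return An `oar_registry` object: per site, a named list mapping canonical
#'   OAR name to a character vector of accepted synonyms.
#' @export
oar_registry <- function() {
  reg <- list(
    pelvis = list(
      Bladder = c("bladder", "urinary bladder"),
      Rectum = c("rectum"),
      BowelSpace = c("bowelspace", "bowel space", "bowel_space", "bowel bag", "bowelbag")
    ),
    thorax = list(
      Lung_L = c("lung_l", "left lung", "lung left"),
      Lung_R = c("lung_r", "right lung", "lung right"),
      Heart = c("heart"),
      Esophagus = c("esophagus", "oesophagus"),
      SpinalCord = c("spinalcord", "spinal cord", "cord")
    ),
    head_and_neck = list(
      Parotid_L = c("parotid_l", "left parotid"),
      Parotid_R = c("parotid_r", "right parotid"),
      SpinalCord = c("spinalcord", "spinal cord", "cord"),
      Mandible = c("mandible"),
      Larynx = c("larynx")
    )
  )
  structure(reg, class = "oar_registry")
}

#' Define the relevant OARs for a treatment site
#'
#' Replaces or extends a site's OAR list. Each entry maps a canonical
#' structure name to its accepted synonyms (the canonical name itself is
#' always accepted). A synonym may not resolve to two canonical names within
#' one site.
#'
#' @param registry An `oar_registry`.
#' @param site Site label (non-empty string); created if new.
#' @param oars Named list: canonical name -> character vector of synonyms,
#'   or a character vector of canonical names (no extra synonyms). An empty
#'   list clears the site.
#' @param extend If `TRUE`, merge into the existing site list instead of
#'   replacing it.
#' @return The updated registry.
#' @export
set_oars <- function(registry, site, oars, extend = FALSE) {
  stopifnot(inherits(registry, "oar_registry"))
  if (!is.character(site) || length(site) != 1L || !nzchar(site)) {
    oartex_error("site label must be a non-empty string", "oartex_config_error")
  }
  if (is.character(oars)) {
    oars <- stats::setNames(lapply(oars, function(x) character()), oars)
  }
  current <- if (extend) registry[[site]] %||% list() else list()
  for (nm in names(oars)) current[[nm]] <- unique(c(current[[nm]], oars[[nm]]))
  # synonym collision check: canonical names count as their own synonym
  seen <- list()
  for (nm in names(current)) {
    for (syn in normalize_roi(c(nm, current[[nm]]))) {
      if (!is.null(seen[[syn]]) && seen[[syn]] != nm) {
        oartex_error(sprintf("synonym '%s' maps to both '%s' and '%s' in site '%s'",
                             syn, seen[[syn]], nm, site),
                     "oartex_config_error")
      }
      seen[[syn]] <- nm
    }
  }
  registry[[site]] <- current
  registry
}

#' Resolve an ROI name to its canonical OAR name
#'
#' @param registry An `oar_registry`.
#' @param site Site label.
#' @param name ROI name as found in a document (matching is
#'   case/whitespace/underscore-insensitive).
#' @return The canonical name, or `NA_character_` when unmatched.
#' @export
lookup_oar <- function(registry, site, name) {
  stopifnot(inherits(registry, "oar_registry"))
  oars <- registry[[site]]
  if (is.null(oars) || !length(oars)) return(NA_character_)
  key <- normalize_roi(name)
  for (nm in names(oars)) {
    if (key %in% normalize_roi(c(nm, oars[[nm]]))) return(nm)
  }
  NA_character_
}

#' Write / read an OAR registry as an editable YAML-like config file
#'
#' Plain JSON on disk: `{site: {Canonical: [synonyms...]}}`.
#' @param registry An `oar_registry`.
#' @param path File path.
#' @export
write_oar_registry <- function(registry, path) {
  stopifnot(inherits(registry, "oar_registry"))
  write_json_file(unclass(registry), path)
}

#' @rdname write_oar_registry
#' @export
read_oar_registry <- function(path) {
  reg <- read_json_file(path)
  reg <- lapply(reg, function(site) lapply(site, function(x) unlist(x) %||% character()))
  structure(reg, class = "oar_registry")
}

#' Assign roles to a structure set
#'
#' Classifies each structure as an organ at risk (via the site registry), a
#' tiered target, or `other`. Structures whose name starts with `PTV` or
#' `CTV` (case-insensitive) and that appear in `target_dose_levels` are
#' ranked by prescribed dose: lowest dose gets `target_low`, highest gets
#' `target_high`, everything between pools into `target_int`. A single
#' target is `target_high`; two targets are low/high. Dose ties are broken
#' alphabetically with a warning. Assignment does not depend on input order.
#'
#' @param structures List of structure entries (each with a `name`).
#' @param site Site label for OAR lookup.
#' @param target_dose_levels Named numeric: target ROI name -> prescribed
#'   dose (Gy).
#' @param registry An `oar_registry` (defaults to the built-ins).
#' @return `structures` with a `role` field added to each entry.
#' @export
assign_roles <- function(structures, site, target_dose_levels = NULL,
                         registry = oar_registry()) {
  target_dose_levels <- target_dose_levels %||% numeric()
  nms <- vapply(structures, `[[`, character(1), "name")
  is_target <- grepl("^\\s*(ptv|ctv)", tolower(nms)) &
    normalize_roi(nms) %in% normalize_roi(names(target_dose_levels))

  roles <- rep("other", length(structures))
  # targets tiered by prescribed dose
  if (any(is_target)) {
    t_nms <- nms[is_target]
    doses <- vapply(t_nms, function(nm) {
      target_dose_levels[[which(normalize_roi(names(target_dose_levels)) == normalize_roi(nm))[1]]]
    }, numeric(1))
    if (anyDuplicated(doses)) {
      oartex_warn("targets with equal prescribed dose; tie broken alphabetically",
                  "oartex_target_tie")
    }
    ord <- order(doses, t_nms)  # alphabetical tie-break
    tier <- character(length(t_nms))
    if (length(t_nms) == 1L) tier <- "target_high"
    else {
      tier[ord] <- "target_int"
      tier[ord[1L]] <- "target_low"
      tier[ord[length(ord)]] <- "target_high"
    }
    roles[is_target] <- tier
  }
  for (i in which(!is_target)) {
    if (!is.na(lookup_oar(registry, site, nms[i]))) roles[i] <- "oar"
  }
  for (i in seq_along(structures)) structures[[i]]$role <- roles[i]
  structures
}

centroid_shift <- function(session, reference) {
  if (is.null(session) || is.null(reference)) return(NA_real_)
  sqrt(sum((as.numeric(session) - as.numeric(reference))^2))
}

#' Per-fraction volume deltas versus the reference structure set
#'
#' For every delivered session of a course, reports the structure's carried
#' volume alongside absolute and relative deltas to the reference structure
#' set, the centroid (center-of-mass) shift magnitude and per-axis
#' components, and the session's adapted flag. Volumes are carried from the
#' source documents, never recomputed. A zero or absent reference volume
#' leaves the relative delta undefined (`NA`) — no division is attempted;
#' absolute values are still emitted.
#'
#' @param course A `course_record`.
#' @param structure Structure name as found in the documents.
#' @return A data.frame with columns `fraction`, `plan_name`, `volume_cm3`,
#'   `delta_cm3`, `delta_rel`, `centroid_shift_cm`, `centroid_dx_cm`,
#'   `centroid_dy_cm`, `centroid_dz_cm`, `adapted`.
#' @export
volume_trend <- function(course, structure) {
  stopifnot(inherits(course, "course_record"))
  ref_entry <- NULL
  if (!is.null(course$reference_doc)) {
    ref_entry <- find_structure(course$reference_doc, structure)
  } else {
    oartex_warn("course has no reference plan; relative volume deltas unavailable",
                "oartex_missing_reference")
  }
  ref_vol <- if (!is.null(ref_entry)) as.numeric(ref_entry$volume_cm3) else NA_real_
  rows <- lapply(course$fractions, function(fs) {
    doc <- fs$delivered_doc
    if (is.null(doc)) return(NULL)
    entry <- find_structure(doc, structure)
    if (is.null(entry)) return(NULL)
    v <- as.numeric(entry$volume_cm3)
    dvec <- if (!is.null(entry$centroid_cm) && !is.null(ref_entry$centroid_cm)) {
      as.numeric(entry$centroid_cm) - as.numeric(ref_entry$centroid_cm)
    } else rep(NA_real_, 3L)
    data.frame(
      fraction = fs$fraction, plan_name = doc$planName_str, volume_cm3 = v,
      delta_cm3 = if (is.na(ref_vol)) NA_real_ else v - ref_vol,
      delta_rel = if (is.na(ref_vol) || ref_vol <= 0) NA_real_ else (v - ref_vol) / ref_vol,
      centroid_shift_cm = sqrt(sum(dvec^2)),
      centroid_dx_cm = dvec[1], centroid_dy_cm = dvec[2], centroid_dz_cm = dvec[3],
      adapted = isTRUE(fs$adapted))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fraction = integer(), plan_name = character(),
                      volume_cm3 = numeric(), delta_cm3 = numeric(),
                      delta_rel = numeric(), centroid_shift_cm = numeric(),
                      centroid_dx_cm = numeric(), centroid_dy_cm = numeric(),
                      centroid_dz_cm = numeric(), adapted = logical())
  }
  rownames(out) <- NULL
  out
}

find_structure <- function(doc, structure) {
  key <- normalize_roi(structure)
  for (s in doc$structures) {
    if (normalize_roi(s$name) == key) return(s)
  }
  NULL
}
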