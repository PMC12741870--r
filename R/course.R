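# Course assembly: group one patient's plan-check documents into a timeline
# of fraction sessions, attach the reference plan as baseline, and mark which
# plan was delivered (and whether the session was adapted).

#' Assemble a patient's course from plan-check documents
#'
#' Groups pre-treatment documents by fraction; within a fraction, each
#' structure-set revision contributes one scheduled/adaptive plan pair,
#' ordered by revision. The reference-plan document (name without a
#' `/SCH`–`/ADP` token) becomes the course baseline. Delivered and adapted
#' flags come from `delivered_map` (the output of [resolve_delivered()]).
#' Plan names that violate the grammar are quarantined with a warning — one
#' bad name must not kill a course.
#'
#' @param documents List of `plan_check_document`s for one patient
#'   (log-file documents are ignored; linkage is `delivered_map`'s job).
#' @param delivered_map Data.frame from [resolve_delivered()].
#' @return A `course_record`: list with `patient_id`, `reference_id`,
#'   `reference_doc` (may be `NULL`, with a warning — volume deltas are then
#'   unavailable), `site`, and `fractions`, an ordered list of sessions each
#'   holding `fraction`, `pairs` (per revision: `revision`, `scheduled_doc`,
#'   `adaptive_doc`), `delivered_doc` and `adapted`.
#' @export
build_course <- function(documents, delivered_map = NULL) {
  if (is.null(delivered_map)) {
    delivered_map <- data.frame(fraction = integer(), plan_name = character(),
                                check_id = character(), adapted = logical())
  }
  pre <- Filter(function(d) identical(d$check_kind, "pretreatment"), documents)
  reference_doc <- NULL
  by_fraction <- list()
  patient_id <- NA_character_
  reference_id <- NA_character_
  site <- NA_character_

  for (doc in pre) {
    patient_id <- doc$patient_id %||% patient_id
    site <- doc$site %||% site
    id <- tryCatch(parse_plan_name(doc$planName_str),
                   oartex_malformed_name = function(e) {
                     oartex_warn(sprintf("quarantined malformed plan name '%s'",
                                         doc$planName_str),
                                 "oartex_quarantined_name")
                     NULL
                   })
    if (is.null(id)) next
    if (id$plan_type == "reference") {
      reference_doc <- doc
      reference_id <- id$reference_id
      next
    }
    reference_id <- if (is.na(reference_id)) id$reference_id else reference_id
    key <- as.character(id$fraction)
    fs <- by_fraction[[key]] %||% list(fraction = id$fraction, revisions = list())
    rkey <- as.character(id$revision)
    pair <- fs$revisions[[rkey]] %||% list(revision = id$revision,
                                           scheduled_doc = NULL, adaptive_doc = NULL)
    if (id$plan_type == "scheduled") pair$scheduled_doc <- doc
    else pair$adaptive_doc <- doc
    fs$revisions[[rkey]] <- pair
    by_fraction[[key]] <- fs
  }

  if (is.null(reference_doc) && length(by_fraction)) {
    oartex_warn("no reference plan found for this course; baseline deltas unavailable",
                "oartex_missing_reference")
  }

  fractions <- lapply(by_fraction, function(fs) {
    ord <- order(vapply(fs$revisions, `[[`, integer(1), "revision"))
    pairs <- unname(fs$revisions[ord])
    del <- delivered_map[delivered_map$fraction == fs$fraction, , drop = FALSE]
    delivered_doc <- NULL; adapted <- NA
    if (nrow(del)) {
      for (p in pairs) {
        for (slot in c("scheduled_doc", "adaptive_doc")) {
          d <- p[[slot]]
          if (!is.null(d) && identical(d$planName_str, del$plan_name[1])) {
            delivered_doc <- d
          }
        }
      }
      adapted <- del$adapted[1]
    }
    list(fraction = fs$fraction, pairs = pairs,
         delivered_doc = delivered_doc, adapted = adapted)
  })
  fractions <- fractions[order(vapply(fractions, `[[`, integer(1), "fraction"))]
  names(fractions) <- NULL

  structure(list(patient_id = patient_id, reference_id = reference_id,
                 reference_doc = reference_doc, site = site,
                 fractions = fractions),
            class = "course_record")
}

#' @export
print.course_record <- function(x, ...) {
  n_del <- sum(vapply(x$fractions, function(f) !is.null(f$delivered_doc), logical(1)))
  n_adp <- sum(vapply(x$fractions, function(f) isTRUE(f$adapted), logical(1)))
  cat(sprintf("<course_record> patient %s, reference %s (%s)\n",
              x$patient_id, x$reference_id, x$site))
  cat(sprintf("  %d fractions, %d delivered (%d adapted), reference plan %s\n",
              length(x$fractions), n_del, n_adp,
              if (is.null(x$reference_doc)) "missing" else "present"))
  invisible(x)
}

#' @export
summary.course_record <- function(object, ...) {
  rows <- lapply(object$fractions, function(fs) {
    data.frame(
      fraction = fs$fraction,
      n_revisions = length(fs$pairs),
      delivered = if (is.null(fs$delivered_doc)) NA_character_
                  else fs$delivered_doc$planName_str,
      adapted = fs$adapted)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(fraction = integer(), n_revisions = integer(),
               delivered = character(), adapted = logical())
  rownames(out) <- NULL
  out
}
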