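# End-to-end extraction workflow: read patient IDs -> query the plan-check
# source -> resolve delivered plans -> assemble courses -> analytics ->
# de-identified cohort store. One patient's failure never aborts a cohort
# run; progress and problems are logged as line-delimited JSON on stderr.

# Shipped planning-directive target levels (course dose, Gy) per site,
# matching the structure names the per-site templates use. Overridable per
# run via run_config(target_dose_levels=).
.default_target_levels <- list(
  pelvis = c(PTV_High = 62.5, PTV_Int = 55, PTV_Low = 45),
  thorax = c(PTV_High = 60),
  head_and_neck = c(PTV_High = 70, PTV_Int = 63, PTV_Low = 56)
)

log_json <- function(level, event, ...) {
  fields <- list(level = level, event = event, ...)
  message(to_json(fields))
}

#' Extraction run configuration
#'
#' A fully serializable description of one extraction run: with the same
#' configuration and source data, a run is reproducible.
#'
#' @param source Either `list(kind = "file", dir = ...)` for a file-backed
#'   source directory or `list(kind = "http", base_url = ...)` for an HTTP
#'   endpoint.
#' @param token Access token for the source.
#' @param institution_id Institution prefix for de-identified patient UIDs.
#' @param store_dir Directory where the cohort store is persisted (a
#'   [dir_collector()] location); loaded if it already exists.
#' @param objectives List of [objective_spec()]s evaluated per plan and
#'   stored as extensible cohort columns.
#' @param target_dose_levels Named numeric, target ROI name -> prescribed
#'   course dose in Gy, used for target tiering; defaults per site ship with
#'   the package.
#' @param registry An `oar_registry` (or path to one written by
#'   [write_oar_registry()]).
#' @param seed Integer seed recorded with the run.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` object.
#' @export
run_config <- function(source, token, institution_id, store_dir,
                       objectives = list(), target_dose_levels = NULL,
                       registry = oar_registry(), seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!is.list(source) || is.null(source$kind) ||
      !source$kind %in% c("file", "http")) {
    oartex_error("source must be list(kind = 'file', dir=) or list(kind = 'http', base_url=)",
                 "oartex_config_error")
  }
  if (is.character(registry)) registry <- read_oar_registry(registry)
  structure(list(source = source, token = token,
                 institution_id = institution_id, store_dir = store_dir,
                 objectives = objectives,
                 target_dose_levels = target_dose_levels,
                 registry = registry, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

config_transport <- function(config) {
  if (config$source$kind == "file") file_transport(config$source$dir)
  else http_transport(config$source$base_url)
}

config_store <- function(config) {
  collector <- dir_collector(config$store_dir)
  if (file.exists(file.path(config$store_dir, "manifest.json"))) {
    collector_load(collector)
  } else {
    cohort_store(institution_id = config$institution_id)
  }
}

#' Flatten an analyzed course into cohort rows
#'
#' One row per (plan, structure) over every pre-treatment plan of the course
#' — the reference plan (fraction 0) and each scheduled/adaptive plan of
#' each structure-set revision. Each row carries the structure's role,
#' volume and deltas versus the reference structure set, the plan's
#' complexity summary, delivered/adapted flags and any requested dosimetric
#' objectives (stored in columns named by their objective label, evaluated
#' on the chosen DVH `source` only for the objective's own structure).
#'
#' @param course A `course_record`.
#' @param patient_uid De-identified UID for the rows.
#' @param objectives List of [objective_spec()]s.
#' @param registry An `oar_registry`.
#' @param target_dose_levels Named numeric for target tiering; per-site
#'   defaults when `NULL`.
#' @param source DVH source for objective evaluation.
#' @return A cohort-row data.frame (see [append_patient()]).
#' @export
course_to_rows <- function(course, patient_uid, objectives = list(),
                           registry = oar_registry(),
                           target_dose_levels = NULL,
                           source = "tpms") {
  stopifnot(inherits(course, "course_record"))
  site <- course$site
  levels <- target_dose_levels %||% .default_target_levels[[site]] %||% numeric()

  ref_structs <- list()
  if (!is.null(course$reference_doc)) {
    for (s in course$reference_doc$structures) ref_structs[[normalize_roi(s$name)]] <- s
  }

  plan_rows <- function(doc, fraction, plan_type, revision, delivered, adapted) {
    structs <- assign_roles(doc$structures, site, levels, registry)
    cx <- plan_complexity(doc$beams, doc$prescription_cgy)
    rows <- lapply(structs, function(s) {
      ref <- ref_structs[[normalize_roi(s$name)]]
      ref_vol <- if (!is.null(ref)) as.numeric(ref$volume_cm3) else NA_real_
      v <- as.numeric(s$volume_cm3)
      shift <- if (!is.null(s$centroid_cm) && !is.null(ref$centroid_cm)) {
        sqrt(sum((as.numeric(s$centroid_cm) - as.numeric(ref$centroid_cm))^2))
      } else NA_real_
      row <- data.frame(
        patient_uid = patient_uid, site = site, fraction = fraction,
        plan_name = doc$planName_str, plan_type = plan_type,
        revision = revision, delivered = delivered, adapted = adapted,
        structure = s$name, role = s$role, volume_cm3 = v,
        delta_cm3 = if (is.na(ref_vol)) NA_real_ else v - ref_vol,
        delta_rel = if (is.na(ref_vol) || ref_vol <= 0) NA_real_ else (v - ref_vol) / ref_vol,
        centroid_shift_cm = shift,
        total_mu = cx$total_mu, modulation_factor = cx$modulation_factor,
        n_control_points = cx$n_control_points, n_beams = cx$n_beams,
        timestamp = doc$timestamp, stringsAsFactors = FALSE)
      for (ob in objectives) {
        val <- NA_real_
        if (normalize_roi(ob$structure) == normalize_roi(s$name)) {
          dvh <- document_dvh(doc, s$name, source)
          if (!is.null(dvh)) val <- evaluate_objective(dvh, ob)
        }
        row[[objective_label(ob)]] <- val
      }
      row
    })
    do.call(rbind, rows)
  }

  out <- list()
  if (!is.null(course$reference_doc)) {
    out[[1L]] <- plan_rows(course$reference_doc, 0L, "reference", NA_integer_,
                           FALSE, NA)
  }
  for (fs in course$fractions) {
    for (p in fs$pairs) {
      for (slot in c("scheduled_doc", "adaptive_doc")) {
        doc <- p[[slot]]
        if (is.null(doc)) next
        delivered <- !is.null(fs$delivered_doc) &&
          identical(doc$planName_str, fs$delivered_doc$planName_str)
        out[[length(out) + 1L]] <- plan_rows(
          doc, fs$fraction,
          if (slot == "scheduled_doc") "scheduled" else "adaptive",
          p$revision, delivered,
          if (delivered) isTRUE(fs$adapted) else NA)
      }
    }
  }
  res <- do.call(rbind, out) %||% empty_cohort_rows()
  rownames(res) <- NULL
  res
}

extract_one_patient <- function(session, config, store, patient_id) {
  checks <- list_plan_checks(session, patient_id)
  if (!nrow(checks)) {
    return(list(status = "empty", sessions = 0L, plans = 0L))
  }
  pre_ids <- checks$check_id[checks$check_kind == "pretreatment"]
  docs <- lapply(pre_ids, function(id) fetch_check(session, id))
  delivered <- resolve_delivered(checks)
  course <- build_course(docs, delivered)
  uid <- assign_uid(store, patient_id)
  for (ob in config$objectives) {
    register_column(store, objective_label(ob),
                    unit = if (ob$kind == "V_at_dose") "%" else "Gy",
                    description = "dose-volume objective")
  }
  rows <- course_to_rows(course, uid, objectives = config$objectives,
                         registry = config$registry,
                         target_dose_levels = config$target_dose_levels)
  append_patient(store, rows)
  # advance the incremental-update mark to the newest listed check (log-file
  # checks run later than the pre-treatment rows the store keeps)
  store$last_seen[[uid]] <- max(checks$timestamp)
  list(status = "ok", sessions = length(course$fractions), plans = length(docs))
}

#' Run a full extraction over a list of patients
#'
#' For each patient: list checks, fetch pre-treatment documents, resolve the
#' delivered plan per fraction, assemble the course, run structure and DVH
#' analytics, and append de-identified rows to the cohort store (persisted
#' to `config$store_dir`). A failure on one patient is logged and counted;
#' the run continues. The run fails (error) only when every patient failed.
#'
#' @param config A [run_config()].
#' @param patient_ids Character vector of source patient IDs, or the path to
#'   a text file with one ID per line.
#' @return A `run_report`: counts of patients (ok / empty / failed),
#'   sessions and plans, plus per-patient details.
#' @export
run_extraction <- function(config, patient_ids) {
  stopifnot(inherits(config, "run_config"))
  if (length(patient_ids) == 1L && file.exists(patient_ids)) {
    patient_ids <- readLines(patient_ids, warn = FALSE)
    patient_ids <- trimws(patient_ids)
    patient_ids <- patient_ids[nzchar(patient_ids)]
  }
  if (!length(patient_ids)) {
    oartex_error("no patient IDs supplied", "oartex_config_error")
  }
  session <- open_session(config_transport(config), config$token)
  store <- config_store(config)
  details <- list()
  n_warn <- 0L
  for (pid in patient_ids) {
    res <- withCallingHandlers(
      tryCatch(extract_one_patient(session, config, store, pid),
               error = function(e) list(status = "failed",
                                        message = conditionMessage(e),
                                        sessions = 0L, plans = 0L)),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        if (config$log_level == "info") {
          log_json("warning", "patient_warning", patient = pid,
                   message = conditionMessage(w))
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (config$log_level == "info") {
      log_json("info", "patient_done", patient = pid, status = res$status,
               sessions = res$sessions, plans = res$plans)
    }
    details[[pid]] <- res
  }
  statuses <- vapply(details, `[[`, character(1), "status")
  if (all(statuses == "failed")) {
    oartex_error("extraction failed for every patient", "oartex_run_error",
                 details = details)
  }
  collector_save(dir_collector(config$store_dir), store)
  structure(list(
    n_patients = length(patient_ids),
    n_ok = sum(statuses == "ok"),
    n_empty = sum(statuses == "empty"),
    n_failed = sum(statuses == "failed"),
    n_sessions = sum(vapply(details, `[[`, integer(1), "sessions")),
    n_plans = sum(vapply(details, `[[`, integer(1), "plans")),
    n_warnings = n_warn,
    details = details
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d patients: %d ok, %d empty, %d failed; %d sessions, %d plans fetched, %d warnings\n",
              x$n_patients, x$n_ok, x$n_empty, x$n_failed, x$n_sessions,
              x$n_plans, x$n_warnings))
  invisible(x)
}

#' Incremental daily update of an existing store
#'
#' Re-lists every patient already in the store and fetches only checks newer
#' than that patient's last-seen timestamp (plus, for context, the reference
#' plan and the sibling checks of any fraction that gained a new check —
#' needed to recompute deltas and pairing). New rows are appended on top of
#' the existing ones. If a previously unseen check carries a timestamp at or
#' before the last-seen mark (clock skew at the source), the whole patient
#' is re-fetched with a warning. Updating twice in a row is a no-op.
#'
#' @param config A [run_config()] whose `store_dir` holds an existing store.
#' @return A `run_report` (sessions/plans count only newly fetched ones).
#' @export
run_daily_update <- function(config) {
  stopifnot(inherits(config, "run_config"))
  collector <- dir_collector(config$store_dir)
  if (!file.exists(file.path(config$store_dir, "manifest.json"))) {
    oartex_error("run_daily_update needs an existing store; run run_extraction first",
                 "oartex_config_error")
  }
  store <- collector_load(collector)
  session <- open_session(config_transport(config), config$token)
  details <- list()
  for (i in seq_len(nrow(store$lookback))) {
    pid <- store$lookback$source_patient_id[i]
    uid <- store$lookback$patient_uid[i]
    last_seen <- store$last_seen[[uid]] %||% ""
    checks <- list_plan_checks(session, pid)
    if (!nrow(checks)) { details[[pid]] <- list(status = "empty", sessions = 0L, plans = 0L); next }
    known_plans <- store$rows$plan_name[store$rows$patient_uid == uid]
    is_new <- checks$timestamp > last_seen
    skew <- !is_new & !(checks$plan_name %in% known_plans) &
      checks$check_kind == "pretreatment"
    if (any(skew)) {
      oartex_warn(sprintf("patient %s has unseen checks at or before the last-seen mark; re-fetching the full course",
                          pid), "oartex_clock_skew")
      res <- extract_one_patient(session, config, store, pid)
      details[[pid]] <- res
      next
    }
    if (!any(is_new)) { details[[pid]] <- list(status = "current", sessions = 0L, plans = 0L); next }

    # fractions touched by new checks, via their plan names
    new_pre <- checks[is_new & checks$check_kind == "pretreatment", , drop = FALSE]
    touched <- unique(vapply(new_pre$plan_name, function(nm) {
      id <- tryCatch(parse_plan_name(nm), oartex_malformed_name = function(e) NULL)
      if (is.null(id) || is.na(id$fraction)) NA_integer_ else id$fraction
    }, integer(1)))
    touched <- touched[!is.na(touched)]
    pre <- checks[checks$check_kind == "pretreatment", , drop = FALSE]
    fetch_ids <- vapply(seq_len(nrow(pre)), function(j) {
      id <- tryCatch(parse_plan_name(pre$plan_name[j]),
                     oartex_malformed_name = function(e) NULL)
      if (is.null(id)) return(NA_character_)
      if (id$plan_type == "reference" || id$fraction %in% touched) pre$check_id[j]
      else NA_character_
    }, character(1))
    fetch_ids <- fetch_ids[!is.na(fetch_ids)]
    docs <- lapply(fetch_ids, function(id) fetch_check(session, id))
    delivered <- resolve_delivered(checks)
    course <- build_course(docs, delivered)
    new_rows <- course_to_rows(course, uid, objectives = config$objectives,
                               registry = config$registry,
                               target_dose_levels = config$target_dose_levels)
    old_rows <- store$rows[store$rows$patient_uid == uid, , drop = FALSE]
    keep <- !(paste(old_rows$plan_name, old_rows$structure, sep = "\r") %in%
                paste(new_rows$plan_name, new_rows$structure, sep = "\r"))
    combined <- rbind_fill(old_rows[keep, , drop = FALSE], new_rows)
    append_patient(store, combined)
    store$last_seen[[uid]] <- max(checks$timestamp)
    details[[pid]] <- list(status = "updated",
                           sessions = length(course$fractions),
                           plans = length(docs))
    if (config$log_level == "info") {
      log_json("info", "patient_updated", patient = pid,
               new_checks = sum(is_new))
    }
  }
  collector_save(collector, store)
  statuses <- vapply(details, `[[`, character(1), "status")
  structure(list(
    n_patients = length(details),
    n_ok = sum(statuses %in% c("updated", "ok")),
    n_empty = sum(statuses == "empty"),
    n_failed = sum(statuses == "failed"),
    n_current = sum(statuses == "current"),
    n_sessions = sum(vapply(details, `[[`, integer(1), "sessions")),
    n_plans = sum(vapply(details, `[[`, integer(1), "plans")),
    n_warnings = 0L,
    details = details
  ), class = "run_report")
}
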