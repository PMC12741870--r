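# De-identified, mergeable cohort store.
#
# Long format: one row per (patient, plan, structure). Patients get a
# protocol-style unique ID "<institution>-<00001>" — an institution prefix
# (e.g. an NCI site number) plus a zero-padded sequential index — so cohorts
# from different institutions can be merged without identifier collisions.
# The mapping from source patient IDs to study UIDs lives in a private
# lookback index that is stored with the collector but never exported, which
# lets the treating institution re-identify its own patients for chart
# review while shared cohorts stay de-identified. Exported timestamps are
# shifted by a per-patient day offset (derived deterministically from the
# UID) that preserves intra-patient fraction spacing.

core_columns <- c("patient_uid", "site", "fraction", "plan_name", "plan_type",
                  "revision", "delivered", "adapted", "structure", "role",
                  "volume_cm3", "delta_cm3", "delta_rel", "centroid_shift_cm",
                  "total_mu", "modulation_factor", "n_control_points",
                  "n_beams", "timestamp")

empty_cohort_rows <- function() {
  df <- data.frame(patient_uid = character(), site = character(),
                   fraction = integer(), plan_name = character(),
                   plan_type = character(), revision = integer(),
                   delivered = logical(), adapted = logical(),
                   structure = character(), role = character(),
                   volume_cm3 = numeric(), delta_cm3 = numeric(),
                   delta_rel = numeric(), centroid_shift_cm = numeric(),
                   total_mu = numeric(), modulation_factor = numeric(),
                   n_control_points = integer(), n_beams = integer(),
                   timestamp = character(), stringsAsFactors = FALSE)
  df
}

#' Create an empty cohort store
#'
#' The store is an environment (mutable in place): appends and UID
#' assignment modify it directly, as one would expect of a database handle.
#'
#' @param institution_id Institution prefix stamped into every patient UID
#'   (e.g. an NCI site number such as `"1234"`). Required before any UID can
#'   be assigned.
#' @param schema_version Schema tag carried into exports; merges require
#'   equal versions.
#' @return An object of class `cohort_store`.
#' @export
cohort_store <- function(institution_id = NULL, schema_version = "1") {
  store <- new.env(parent = emptyenv())
  store$institution_id <- institution_id
  store$schema_version <- schema_version
  store$rows <- empty_cohort_rows()
  store$lookback <- data.frame(source_patient_id = character(),
                               patient_uid = character(),
                               stringsAsFactors = FALSE)
  store$column_registry <- list()   # extensible column -> list(unit, description)
  store$last_seen <- list()         # patient_uid -> max source timestamp
  class(store) <- "cohort_store"
  store
}

#' @export
print.cohort_store <- function(x, ...) {
  cat(sprintf("<cohort_store> institution %s, schema v%s: %d rows, %d patients, %d extensible columns\n",
              x$institution_id %||% "<unset>", x$schema_version, nrow(x$rows),
              length(unique(x$rows$patient_uid)), length(x$column_registry)))
  invisible(x)
}

#' Assign (or recall) a de-identified patient UID
#'
#' A previously seen source patient ID returns its existing UID (idempotent,
#' via the private lookback index); a new one gets the next sequential index,
#' zero-padded to width 5 (wider past 99999).
#'
#' @param store A `cohort_store` with `institution_id` set.
#' @param source_patient_id The source-system patient identifier. Never
#'   leaves the store's private lookback index.
#' @return The UID string, e.g. `"1234-00019"`.
#' @export
assign_uid <- function(store, source_patient_id) {
  stopifnot(inherits(store, "cohort_store"))
  if (is.null(store$institution_id) || !nzchar(store$institution_id)) {
    oartex_error("institution_id must be set before assigning patient UIDs",
                 "oartex_config_error")
  }
  hit <- store$lookback$patient_uid[store$lookback$source_patient_id == source_patient_id]
  if (length(hit)) return(hit[1])
  idx <- nrow(store$lookback) + 1L
  uid <- if (idx <= 99999L) sprintf("%s-%05d", store$institution_id, idx)
         else sprintf("%s-%d", store$institution_id, idx)
  store$lookback <- rbind(store$lookback,
                          data.frame(source_patient_id = source_patient_id,
                                     patient_uid = uid, stringsAsFactors = FALSE))
  uid
}

#' Register an extensible cohort column
#'
#' Extra analysis columns (e.g. a dosimetric objective) must be registered
#' with a unit so merges can detect semantic collisions. Core columns cannot
#' be shadowed.
#'
#' @param store A `cohort_store`.
#' @param name Column name.
#' @param unit Unit string (e.g. `"%"`, `"Gy"`).
#' @param description Free-text description.
#' @export
register_column <- function(store, name, unit, description = "") {
  stopifnot(inherits(store, "cohort_store"))
  if (name %in% core_columns) {
    oartex_error(sprintf("'%s' is a core column and cannot be redefined", name),
                 "oartex_config_error")
  }
  store$column_registry[[name]] <- list(unit = unit, description = description)
  invisible(store)
}

#' Append (or replace) one patient's rows
#'
#' Rows for an already-present patient UID are replaced atomically —
#' re-extraction supersedes. Unregistered non-core columns raise an error;
#' a key collision (same `(patient_uid, plan_name, structure)` appearing
#' twice within the incoming rows) is an integrity error.
#'
#' @param store A `cohort_store`.
#' @param rows Data.frame of cohort rows (see [course_to_rows()]).
#' @return The store, invisibly.
#' @export
append_patient <- function(store, rows) {
  stopifnot(inherits(store, "cohort_store"), is.data.frame(rows))
  extra <- setdiff(names(rows), core_columns)
  unknown <- setdiff(extra, names(store$column_registry))
  if (length(unknown)) {
    oartex_error(sprintf("unregistered extensible column(s): %s — call register_column() first",
                         paste(unknown, collapse = ", ")),
                 "oartex_config_error")
  }
  key <- paste(rows$patient_uid, rows$plan_name, rows$structure, sep = "\r")
  if (anyDuplicated(key)) {
    oartex_error("duplicate (patient_uid, plan_name, structure) key in appended rows",
                 "oartex_integrity_error")
  }
  uids <- unique(rows$patient_uid)
  keep <- !(store$rows$patient_uid %in% uids)
  store$rows <- rbind_fill(store$rows[keep, , drop = FALSE], rows)
  for (u in uids) {
    ts <- rows$timestamp[rows$patient_uid == u]
    store$last_seen[[u]] <- max(c(ts, store$last_seen[[u]]), na.rm = TRUE)
  }
  invisible(store)
}

# rbind two data.frames, filling absent columns with NA and keeping core
# columns first.
rbind_fill <- function(a, b) {
  all_cols <- union(names(a), names(b))
  for (nm in setdiff(all_cols, names(a))) a[[nm]] <- rep(NA, nrow(a))
  for (nm in setdiff(all_cols, names(b))) b[[nm]] <- rep(NA, nrow(b))
  ordered <- c(intersect(core_columns, all_cols),
               setdiff(all_cols, core_columns))
  out <- rbind(a[, ordered, drop = FALSE], b[, ordered, drop = FALSE])
  rownames(out) <- NULL
  out
}

# Deterministic per-patient day offset in [-182, 182] from the UID text;
# one offset per patient keeps intra-patient intervals intact.
uid_day_offset <- function(uid) {
  codes <- utf8ToInt(uid)
  h <- sum(codes * (seq_along(codes) * 131)) %% 365L
  as.integer(h) - 182L
}

shift_timestamps <- function(rows) {
  if (!nrow(rows)) return(rows)
  offs <- vapply(rows$patient_uid, uid_day_offset, integer(1))
  has_ts <- !is.na(rows$timestamp) & nzchar(rows$timestamp)
  dates <- as.Date(substr(rows$timestamp[has_ts], 1, 10))
  times <- substr(rows$timestamp[has_ts], 11, nchar(rows$timestamp[has_ts]))
  rows$timestamp[has_ts] <- paste0(format(dates + offs[has_ts], "%Y-%m-%d"), times)
  rows
}

#' Export a de-identified cohort archive
#'
#' Writes a single compressed archive (gzip tar) containing `table.csv`
#' (cohort rows with shifted timestamps and no source identifiers),
#' `manifest.json` (schema version, institution manifest, column registry
#' with units, per-patient last-seen state) and `checksums.json` (MD5 of the
#' table). The private lookback index is never exported.
#'
#' @param store A `cohort_store`.
#' @param path Output archive path (e.g. `cohort.tar.gz`).
#' @param filter Optional quoted expression over cohort columns, e.g.
#'   `quote(site == "pelvis")`. Referencing an unknown column is an error
#'   listing the available columns.
#' @return `path`, invisibly.
#' @export
export_cohort <- function(store, path, filter = NULL) {
  stopifnot(inherits(store, "cohort_store"))
  rows <- store$rows
  if (!is.null(filter)) {
    vars <- all.vars(filter)
    bad <- setdiff(vars, names(rows))
    if (length(bad)) {
      oartex_error(sprintf("filter references unknown column(s) %s; available: %s",
                           paste(bad, collapse = ", "),
                           paste(names(rows), collapse = ", ")),
                   "oartex_config_error")
    }
    keep <- eval(filter, rows, baseenv())
    rows <- rows[keep %in% TRUE, , drop = FALSE]
  }
  rows <- shift_timestamps(rows)

  stage <- tempfile("cohort-export-")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  utils::write.csv(rows, file.path(stage, "table.csv"), row.names = FALSE)
  manifest <- list(
    format = "oartex-cohort",
    schema_version = store$schema_version,
    institutions = unique(sub("-[0-9]+$", "", rows$patient_uid)),
    column_registry = store$column_registry,
    last_seen = store$last_seen,
    n_rows = nrow(rows)
  )
  write_json_file(manifest, file.path(stage, "manifest.json"))
  sums <- list(table.csv = unname(tools::md5sum(file.path(stage, "table.csv"))))
  write_json_file(sums, file.path(stage, "checksums.json"))

  # fixed mtimes so identical content always yields an identical archive
  for (f in list.files(stage, full.names = TRUE)) {
    Sys.setFileTime(f, "2000-01-01 00:00:00 UTC")
  }
  old <- setwd(stage); on.exit(setwd(old), add = TRUE)
  # tar via R's internal implementation: deterministic, no system tar needed
  utils::tar(file.path(old_to_abs(old, path)), files = c("table.csv", "manifest.json", "checksums.json"),
             compression = "gzip", tar = "internal")
  invisible(path)
}

old_to_abs <- function(old, path) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(old, path)
}

#' Import a cohort archive
#'
#' @param path Archive written by [export_cohort()].
#' @return A `cohort_store` (with an empty lookback index — imported cohorts
#'   are de-identified).
#' @export
import_cohort <- function(path) {
  stage <- tempfile("cohort-import-")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  utils::untar(path, exdir = stage, tar = "internal")
  manifest <- read_json_file(file.path(stage, "manifest.json"))
  if (!identical(manifest$format, "oartex-cohort")) {
    oartex_error("not an oartex cohort archive", "oartex_parse_error")
  }
  sums <- read_json_file(file.path(stage, "checksums.json"))
  actual <- unname(tools::md5sum(file.path(stage, "table.csv")))
  if (!identical(actual, sums$table.csv)) {
    oartex_error("cohort table checksum mismatch", "oartex_integrity_error")
  }
  rows <- utils::read.csv(file.path(stage, "table.csv"), stringsAsFactors = FALSE,
                          colClasses = c(timestamp = "character"))
  inst <- if (length(manifest$institutions)) manifest$institutions[[1]] else NULL
  store <- cohort_store(institution_id = inst,
                        schema_version = manifest$schema_version)
  store$rows <- if (nrow(rows)) rows else empty_cohort_rows()
  store$column_registry <- manifest$column_registry %||% list()
  store$last_seen <- manifest$last_seen %||% list()
  store
}

#' Merge two cohort stores
#'
#' UIDs from distinct institutions cannot collide (the institution prefix is
#' part of the UID). Identical rows for the same institution (a re-import)
#' are deduplicated; conflicting rows for the same key are a merge error
#' listing the offending keys. Extensible columns registered with different
#' units in the two stores are kept apart under institution-suffixed names,
#' with a warning.
#'
#' @param a,b `cohort_store` objects with equal schema versions.
#' @return A new merged `cohort_store` (no lookback index).
#' @export
merge_cohorts <- function(a, b) {
  stopifnot(inherits(a, "cohort_store"), inherits(b, "cohort_store"))
  if (!identical(a$schema_version, b$schema_version)) {
    oartex_error(sprintf("incompatible schema versions: %s vs %s",
                         a$schema_version, b$schema_version),
                 "oartex_config_error")
  }
  rows_a <- a$rows; rows_b <- b$rows
  reg <- a$column_registry
  for (nm in names(b$column_registry)) {
    if (!is.null(reg[[nm]]) &&
        !identical(reg[[nm]]$unit, b$column_registry[[nm]]$unit)) {
      inst_a <- a$institution_id %||% "A"; inst_b <- b$institution_id %||% "B"
      new_a <- paste(nm, inst_a, sep = "_"); new_b <- paste(nm, inst_b, sep = "_")
      oartex_warn(sprintf("extensible column '%s' has conflicting units ('%s' vs '%s'); kept as '%s' and '%s'",
                          nm, reg[[nm]]$unit, b$column_registry[[nm]]$unit,
                          new_a, new_b),
                  "oartex_column_collision")
      names(rows_a)[names(rows_a) == nm] <- new_a
      names(rows_b)[names(rows_b) == nm] <- new_b
      reg[[new_a]] <- reg[[nm]]; reg[[nm]] <- NULL
      reg[[new_b]] <- b$column_registry[[nm]]
    } else if (is.null(reg[[nm]])) {
      reg[[nm]] <- b$column_registry[[nm]]
    }
  }
  merged_rows <- rbind_fill(rows_a, rows_b)
  key <- paste(merged_rows$patient_uid, merged_rows$plan_name,
               merged_rows$structure, sep = "\r")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    groups <- split(seq_len(nrow(merged_rows)), key)
    drop <- integer()
    conflicts <- character()
    for (k in dup_keys) {
      idx <- groups[[k]]
      sub <- merged_rows[idx, , drop = FALSE]
      if (nrow(unique(sub)) == 1L) drop <- c(drop, idx[-1L])
      else conflicts <- c(conflicts, gsub("\r", " / ", k))
    }
    if (length(conflicts)) {
      oartex_error(paste0("merge conflict: differing rows for key(s): ",
                          paste(conflicts, collapse = "; ")),
                   "oartex_merge_conflict", keys = conflicts)
    }
    if (length(drop)) merged_rows <- merged_rows[-drop, , drop = FALSE]
  }
  out <- cohort_store(institution_id = NULL, schema_version = a$schema_version)
  out$rows <- merged_rows
  out$column_registry <- reg
  out$last_seen <- utils::modifyList(a$last_seen, b$last_seen)
  out
}

# ---- data collectors (pluggable persistence) -------------------------------

#' Pluggable persistence for cohort stores
#'
#' A data collector unifies how a store is persisted so different storage
#' backends are interchangeable. Two backends ship: `dir_collector()` keeps
#' plain-text files (CSV table, JSON manifest, private lookback CSV) in a
#' directory; `rds_collector()` keeps a single serialized snapshot file.
#' Both round-trip the store losslessly, including extensible columns and
#' the private lookback index.
#'
#' @param location Directory (for `dir_collector`) or file path (for
#'   `rds_collector`).
#' @return A collector object for [collector_save()] / [collector_load()].
#' @export
dir_collector <- function(location) {
  structure(list(location = location, backend = "dir"),
            class = c("oartex_dir_collector", "oartex_collector"))
}

#' @rdname dir_collector
#' @export
rds_collector <- function(location) {
  structure(list(location = location, backend = "rds"),
            class = c("oartex_rds_collector", "oartex_collector"))
}

#' Save / load a cohort store through a collector
#' @param collector A collector from [dir_collector()] or [rds_collector()].
#' @param store A `cohort_store`.
#' @export
collector_save <- function(collector, store) UseMethod("collector_save")

#' @rdname collector_save
#' @export
collector_load <- function(collector) UseMethod("collector_load")

#' @export
collector_save.oartex_dir_collector <- function(collector, store) {
  dir.create(collector$location, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(store$rows, file.path(collector$location, "table.csv"),
                   row.names = FALSE)
  utils::write.csv(store$lookback, file.path(collector$location, "lookback.csv"),
                   row.names = FALSE)
  write_json_file(list(format = "oartex-store",
                       schema_version = store$schema_version,
                       institution_id = store$institution_id,
                       column_registry = store$column_registry,
                       last_seen = store$last_seen),
                  file.path(collector$location, "manifest.json"))
  invisible(collector)
}

#' @export
collector_load.oartex_dir_collector <- function(collector) {
  manifest <- read_json_file(file.path(collector$location, "manifest.json"))
  store <- cohort_store(institution_id = manifest$institution_id,
                        schema_version = manifest$schema_version)
  rows <- utils::read.csv(file.path(collector$location, "table.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(timestamp = "character"))
  store$rows <- if (nrow(rows)) rows else empty_cohort_rows()
  store$lookback <- utils::read.csv(file.path(collector$location, "lookback.csv"),
                                    stringsAsFactors = FALSE,
                                    colClasses = "character")
  store$column_registry <- manifest$column_registry %||% list()
  store$last_seen <- manifest$last_seen %||% list()
  store
}

#' @export
collector_save.oartex_rds_collector <- function(collector, store) {
  snapshot <- list(schema_version = store$schema_version,
                   institution_id = store$institution_id,
                   rows = store$rows, lookback = store$lookback,
                   column_registry = store$column_registry,
                   last_seen = store$last_seen)
  saveRDS(snapshot, collector$location)
  invisible(collector)
}

#' @export
collector_load.oartex_rds_collector <- function(collector) {
  snapshot <- readRDS(collector$location)
  store <- cohort_store(institution_id = snapshot$institution_id,
                        schema_version = snapshot$schema_version)
  store$rows <- snapshot$rows
  store$lookback <- snapshot$lookback
  store$column_registry <- snapshot$column_registry
  store$last_seen <- snapshot$last_seen
  store
}
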