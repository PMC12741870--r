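# Authenticated plan-check client.
#
# The source system keys every record by an opaque check ID and exposes
# per-patient lists of checks plus full documents per check. The transport
# is injectable: an HTTP transport (loopback or remote endpoint, driven
# through the system curl binary) and a file-backed transport reading a
# fixture directory share one interface, so every downstream module can be
# exercised without a network. The client never mutates fetched documents.

# ---- low-level HTTP via the system curl binary -----------------------------

http_request <- function(method, url, body = NULL, headers = character()) {
  curl_bin <- Sys.which("curl")
  if (!nzchar(curl_bin)) oartex_error("system curl binary not found",
                                      "oartex_connection_error")
  args <- c("-s", "-S", "-X", method, "-w", "\n%{http_code}",
            "--max-time", "10")
  for (h in headers) args <- c(args, "-H", h)
  if (!is.null(body)) {
    args <- c(args, "-H", "Content-Type: application/json", "--data", body)
  }
  args <- c(args, url)
  out <- suppressWarnings(system2(curl_bin, shQuote(args), stdout = TRUE, stderr = TRUE))
  code <- attr(out, "status")
  if (!is.null(code) && code != 0) {
    oartex_error(sprintf("connection to %s failed: %s", url,
                         paste(out, collapse = " ")),
                 "oartex_connection_error")
  }
  status <- suppressWarnings(as.integer(out[length(out)]))
  payload <- paste(out[-length(out)], collapse = "\n")
  list(status = status, body = payload)
}

parse_json_body <- function(body, context) {
  tryCatch(
    jsonlite::fromJSON(body, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) {
      oartex_error(sprintf("malformed JSON response for %s: %s", context,
                           conditionMessage(e)),
                   "oartex_parse_error")
    })
}

# ---- transports ------------------------------------------------------------

#' HTTP transport for a plan-check endpoint
#'
#' @param base_url Endpoint base URL, e.g. `"http://127.0.0.1:8123"`.
#' @return A transport object consumed by [open_session()].
#' @export
http_transport <- function(base_url) {
  structure(list(base_url = sub("/+$", "", base_url)),
            class = c("oartex_http_transport", "oartex_transport"))
}

#' File-backed transport reading a fixture directory
#'
#' Reads the same dialect the HTTP endpoint serves, straight from a directory
#' written by [write_fixture()] — the substitution point that makes the whole
#' pipeline testable offline.
#'
#' @param dir Directory containing `index.json` and `checks/`.
#' @return A transport object consumed by [open_session()].
#' @export
file_transport <- function(dir) {
  if (!file.exists(file.path(dir, "index.json"))) {
    oartex_error(sprintf("no index.json under '%s'", dir),
                 "oartex_connection_error")
  }
  structure(list(dir = dir),
            class = c("oartex_file_transport", "oartex_transport"))
}

transport_auth <- function(transport, token) UseMethod("transport_auth")
transport_list <- function(transport, session, patient_id) UseMethod("transport_list")
transport_fetch <- function(transport, session, check_id) UseMethod("transport_fetch")

#' @export
transport_auth.oartex_http_transport <- function(transport, token) {
  resp <- http_request("POST", paste0(transport$base_url, "/auth"),
                       body = as.character(to_json(list(token = token))))
  if (identical(resp$status, 401L)) {
    oartex_error("authentication rejected by endpoint", "oartex_auth_error")
  }
  if (!identical(resp$status, 200L)) {
    oartex_error(sprintf("authentication failed with status %s", resp$status),
                 "oartex_connection_error")
  }
  parse_json_body(resp$body, "auth")$session_id
}

#' @export
transport_list.oartex_http_transport <- function(transport, session, patient_id) {
  resp <- http_request("GET",
                       sprintf("%s/patients/%s/checks", transport$base_url, patient_id),
                       headers = paste0("X-Session: ", session))
  if (!identical(resp$status, 200L)) {
    oartex_error(sprintf("listing checks for '%s' failed with status %s",
                         patient_id, resp$status), "oartex_connection_error")
  }
  parse_json_body(resp$body, sprintf("check list of %s", patient_id))
}

#' @export
transport_fetch.oartex_http_transport <- function(transport, session, check_id) {
  resp <- http_request("GET", sprintf("%s/checks/%s", transport$base_url, check_id),
                       headers = paste0("X-Session: ", session))
  if (identical(resp$status, 404L)) {
    oartex_error(sprintf("check '%s' not found", check_id), "oartex_missing_check")
  }
  if (!identical(resp$status, 200L)) {
    oartex_error(sprintf("fetching check '%s' failed with status %s",
                         check_id, resp$status), "oartex_connection_error")
  }
  parse_json_body(resp$body, sprintf("check %s", check_id))
}

#' @export
transport_auth.oartex_file_transport <- function(transport, token) {
  index <- read_json_file(file.path(transport$dir, "index.json"))
  if (!identical(index$token, token)) {
    oartex_error("authentication rejected by fixture directory", "oartex_auth_error")
  }
  "file-session"
}

#' @export
transport_list.oartex_file_transport <- function(transport, session, patient_id) {
  index <- read_json_file(file.path(transport$dir, "index.json"))
  index$patients[[patient_id]] %||% list()
}

#' @export
transport_fetch.oartex_file_transport <- function(transport, session, check_id) {
  path <- file.path(transport$dir, "checks", paste0(check_id, ".json"))
  if (!file.exists(path)) {
    oartex_error(sprintf("check '%s' not found", check_id), "oartex_missing_check")
  }
  tryCatch(read_json_file(path), error = function(e) {
    oartex_error(sprintf("malformed JSON for check %s: %s", check_id,
                         conditionMessage(e)), "oartex_parse_error")
  })
}

# ---- session ---------------------------------------------------------------

#' Open an authenticated session against a plan-check source
#'
#' Exchanges the access token for a session handle. Connection-level failures
#' are retried with exponential backoff (3 attempts); an explicit
#' authentication rejection is not retried.
#'
#' @param transport An [http_transport()] or [file_transport()].
#' @param token Access token.
#' @param retries Connection attempts before giving up.
#' @return A `mobius_session` object.
#' @export
open_session <- function(transport, token, retries = 3L) {
  stopifnot(inherits(transport, "oartex_transport"))
  delay <- 0.2
  for (attempt in seq_len(retries)) {
    session_id <- tryCatch(transport_auth(transport, token),
                           oartex_error = function(e) e)
    if (!inherits(session_id, "error")) {
      return(structure(list(transport = transport, session_id = session_id),
                       class = "mobius_session"))
    }
    # an explicit rejection is definitive; only connection-level failures retry
    if (inherits(session_id, "oartex_auth_error")) stop(session_id)
    if (attempt < retries) { Sys.sleep(delay); delay <- delay * 2 }
  }
  oartex_error(sprintf("could not reach plan-check source after %d attempts: %s",
                       retries, conditionMessage(session_id)),
               "oartex_connection_error")
}

#' @export
print.mobius_session <- function(x, ...) {
  kind <- if (inherits(x$transport, "oartex_http_transport")) x$transport$base_url
          else sprintf("file:%s", x$transport$dir)
  cat(sprintf("<mobius_session> %s\n", kind))
  invisible(x)
}

# ---- operations ------------------------------------------------------------

summary_fields <- c("check_id", "patient_id", "plan_name", "check_kind",
                    "timestamp", "linked_check_id")

#' List a patient's plan checks
#'
#' Returns every check summary stored for the patient, sorted by timestamp
#' ascending. An unknown patient yields an empty data.frame (with a message),
#' not an error — absent patients must not abort a cohort run.
#'
#' @param session A `mobius_session` from [open_session()].
#' @param patient_id Source-system patient identifier.
#' @return A data.frame with columns `check_id`, `patient_id`, `plan_name`,
#'   `check_kind`, `timestamp`, `linked_check_id` (`NA` except on log-file
#'   checks).
#' @export
list_plan_checks <- function(session, patient_id) {
  stopifnot(inherits(session, "mobius_session"))
  raw <- transport_list(session$transport, session$session_id, patient_id)
  if (length(raw) == 0L) {
    message(sprintf("no plan checks found for patient '%s'", patient_id))
    return(empty_check_summaries())
  }
  rows <- lapply(raw, function(s) {
    for (f in c("check_id", "patient_id", "plan_name", "check_kind", "timestamp")) {
      if (is.null(s[[f]])) {
        oartex_error(sprintf("malformed check summary: missing field '%s'", f),
                     "oartex_parse_error", field = f)
      }
    }
    data.frame(check_id = s$check_id, patient_id = s$patient_id,
               plan_name = s$plan_name, check_kind = s$check_kind,
               timestamp = s$timestamp,
               linked_check_id = s$linked_check_id %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$timestamp, out$check_id), , drop = FALSE]
}

empty_check_summaries <- function() {
  data.frame(check_id = character(), patient_id = character(),
             plan_name = character(), check_kind = character(),
             timestamp = character(), linked_check_id = character(),
             stringsAsFactors = FALSE)
}

#' Fetch one full plan-check document
#'
#' Parses the known dialect fields; any fields the dialect does not define
#' are preserved untouched in an `extras` element for forward compatibility.
#' Doses stored in cGy (dialect flag `dose_unit == "cGy"`) are converted to
#' Gy on read — all downstream analytics work in Gy.
#'
#' @param session A `mobius_session`.
#' @param check_id Check ID obtained from [list_plan_checks()].
#' @return The parsed document (a list), with class `plan_check_document`.
#' @export
fetch_check <- function(session, check_id) {
  stopifnot(inherits(session, "mobius_session"))
  raw <- transport_fetch(session$transport, session$session_id, check_id)
  known <- c("check_id", "patient_id", "check_kind", "planName_str",
             "timestamp", "site", "dose_unit", "prescription_cgy",
             "linked_check_id", "structures", "beams", "dvh")
  doc <- raw[intersect(known, names(raw))]
  extras <- raw[setdiff(names(raw), known)]
  if (length(extras)) doc$extras <- extras
  if (identical(doc$dose_unit, "cGy") && !is.null(doc$dvh)) {
    for (src in names(doc$dvh)) {
      for (st in names(doc$dvh[[src]])) {
        doc$dvh[[src]][[st]]$dose_gy <-
          as.numeric(doc$dvh[[src]][[st]]$dose_gy) / 100
      }
    }
    doc$dose_unit <- "Gy"
  }
  class(doc) <- "plan_check_document"
  doc
}

#' @export
print.plan_check_document <- function(x, ...) {
  cat(sprintf("<plan_check_document> %s  [%s] patient %s, %s\n",
              x$check_id, x$check_kind, x$patient_id, x$planName_str))
  invisible(x)
}

#' Resolve which plan was delivered for each fraction
#'
#' A pre-treatment plan counts as delivered precisely when a delivery
#' log-file check links to it — the signature the delivery system leaves
#' behind. At most one plan per fraction is marked delivered; if several
#' log-file checks link into the same fraction, the one with the latest
#' timestamp wins (a re-delivery supersedes) and a warning is raised. A
#' log-file check linking to an absent pre-treatment check is ignored with a
#' dangling-link warning.
#'
#' @param checks Check-summary data.frame from [list_plan_checks()] (one
#'   patient).
#' @return A data.frame with one row per fraction that has a delivered plan:
#'   columns `fraction`, `plan_name`, `check_id` (the delivered plan's
#'   pre-treatment check), `adapted` (delivered plan type is adaptive).
#' @export
resolve_delivered <- function(checks) {
  pre <- checks[checks$check_kind == "pretreatment", , drop = FALSE]
  logs <- checks[checks$check_kind == "logfile", , drop = FALSE]
  out <- list()
  if (nrow(logs)) {
    logs <- logs[order(logs$timestamp, logs$check_id), , drop = FALSE]
    for (i in seq_len(nrow(logs))) {
      target <- logs$linked_check_id[i]
      if (is.na(target) || !target %in% pre$check_id) {
        oartex_warn(sprintf("log-file check %s links to absent pre-treatment check '%s'; ignored",
                            logs$check_id[i], target %||% "<none>"),
                    "oartex_dangling_link")
        next
      }
      plan <- pre[pre$check_id == target, , drop = FALSE]
      id <- tryCatch(parse_plan_name(plan$plan_name[1]),
                     oartex_malformed_name = function(e) NULL)
      if (is.null(id) || id$plan_type == "reference") next
      key <- as.character(id$fraction)
      if (!is.null(out[[key]])) {
        oartex_warn(sprintf("multiple delivery log-file checks for fraction %d; keeping the latest (%s)",
                            id$fraction, logs$check_id[i]),
                    "oartex_duplicate_delivery")
      }
      out[[key]] <- data.frame(fraction = id$fraction,
                               plan_name = plan$plan_name[1],
                               check_id = target,
                               adapted = id$plan_type == "adaptive",
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(fraction = integer(), plan_name = character(),
                      check_id = character(), adapted = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$fraction), , drop = FALSE]
  rownames(res) <- NULL
  res
}
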