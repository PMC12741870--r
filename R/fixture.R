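# Synthetic plan-check fixture service.
#
# No clinical data source ships with this package, so a generator produces
# whole adaptive courses in the same JSON dialect the client consumes, with a
# ground-truth record alongside. The dialect is defined by this repository
# (see the schema notes in inst/fixtureserver/DIALECT.md); the plan-name
# field keeps the vendor's "planName_str" key. DVH curves are synthesized as
# shifted logistic (sigmoid) cumulative curves parameterized per structure by
# (d50, slope):
#
#     V(d) = 100 / (1 + exp((d - d50) / slope))
#
# which yields realistic monotone curves with a closed form for oracle tests.
# The emitted point lists are truncated the way the clinical source truncates
# them: the flat 100% head and the 0% tail are dropped, so every listed
# volume is strictly inside (0, 100).

# Per-site structure templates: targets carry a prescribed (course) dose in
# Gy for role tiering; OARs carry DVH shape parameters on the course-dose
# scale and a reference volume in cm3.
.site_templates <- list(
  pelvis = list(
    prescription_cgy = 250,  # per-fraction prescription, cGy
    course_dose_gy = 62.5,
    structures = list(
      list(name = "PTV_High", target_dose_gy = 62.5, d50 = 61.5, slope = 1.0, volume = 90),
      list(name = "PTV_Int",  target_dose_gy = 55.0, d50 = 54.2, slope = 1.1, volume = 250),
      list(name = "PTV_Low",  target_dose_gy = 45.0, d50 = 44.3, slope = 1.2, volume = 700),
      list(name = "Bladder",   d50 = 32, slope = 7, volume = 180),
      list(name = "Rectum",    d50 = 36, slope = 6, volume = 65),
      list(name = "BowelSpace", d50 = 16, slope = 7, volume = 900)
    )
  ),
  thorax = list(
    prescription_cgy = 200,
    course_dose_gy = 60,
    structures = list(
      list(name = "PTV_High", target_dose_gy = 60, d50 = 59, slope = 1.0, volume = 120),
      list(name = "Lung_L",   d50 = 14, slope = 6, volume = 1300),
      list(name = "Lung_R",   d50 = 15, slope = 6, volume = 1500),
      list(name = "Heart",    d50 = 10, slope = 5, volume = 600),
      list(name = "Esophagus", d50 = 22, slope = 8, volume = 40),
      list(name = "SpinalCord", d50 = 12, slope = 5, volume = 50)
    )
  ),
  head_and_neck = list(
    prescription_cgy = 212,
    course_dose_gy = 70,
    structures = list(
      list(name = "PTV_High", target_dose_gy = 70, d50 = 69, slope = 1.0, volume = 110),
      list(name = "PTV_Int",  target_dose_gy = 63, d50 = 62, slope = 1.0, volume = 220),
      list(name = "PTV_Low",  target_dose_gy = 56, d50 = 55, slope = 1.1, volume = 350),
      list(name = "Parotid_L", d50 = 24, slope = 9, volume = 28),
      list(name = "Parotid_R", d50 = 25, slope = 9, volume = 30),
      list(name = "SpinalCord", d50 = 18, slope = 6, volume = 45),
      list(name = "Larynx",   d50 = 30, slope = 8, volume = 35)
    )
  )
)

# Deterministic per-fraction bladder volume drift (fractional change per
# fraction); other OARs vary with zero-mean session noise.
.bladder_drift <- 0.02
.fixture_dose_step <- 0.1  # Gy, synthesis sampling grid

#' Fixture generator configuration
#'
#' Parameters of the synthetic plan-check generator. Defaults emulate a
#' pelvic adaptive course: contour re-edits (extra structure-set revisions)
#' on about 1 in 10 sessions, and the adaptive plan chosen for delivery on
#' 70% of sessions — adaptation rates reported for pelvic CBCT-guided
#' adaptive programs are high, and the pelvic organ set (bladder, rectum,
#' bowel space) matches the shipped registry defaults.
#'
#' @param institution_label Short label stamped into generated patient IDs.
#' @param n_patients Number of patients (positive integer).
#' @param fractions_per_patient Fractions per course (positive integer).
#' @param revision_probability Probability, per fraction, of one extra
#'   structure-set revision (a second scheduled/adaptive plan pair).
#' @param adapt_probability Probability that the delivered plan is the
#'   adaptive one (else the scheduled plan is delivered).
#' @param site Treatment site template: `"pelvis"`, `"thorax"` or
#'   `"head_and_neck"`.
#' @param seed Integer random seed; identical `(config, seed)` pairs give
#'   byte-identical document sets.
#' @return A validated `fixture_config` object.
#' @export
fixture_config <- function(institution_label = "FIX", n_patients = 3L,
                           fractions_per_patient = 5L,
                           revision_probability = 0.1,
                           adapt_probability = 0.7,
                           site = c("pelvis", "thorax", "head_and_neck"),
                           seed = 1L) {
  site <- match.arg(site)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || is.na(n_patients) ||
      n_patients < 1 || n_patients != floor(n_patients)) {
    oartex_error("n_patients must be a positive integer", "oartex_config_error")
  }
  if (!is.numeric(fractions_per_patient) || length(fractions_per_patient) != 1L ||
      is.na(fractions_per_patient) || fractions_per_patient < 1 ||
      fractions_per_patient != floor(fractions_per_patient)) {
    oartex_error("fractions_per_patient must be a positive integer", "oartex_config_error")
  }
  assert_probability(revision_probability, "revision_probability")
  assert_probability(adapt_probability, "adapt_probability")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    oartex_error("seed must be an integer", "oartex_config_error")
  }
  structure(list(
    institution_label = institution_label,
    n_patients = as.integer(n_patients),
    fractions_per_patient = as.integer(fractions_per_patient),
    revision_probability = revision_probability,
    adapt_probability = adapt_probability,
    site = site,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

# Sample a sigmoid DVH onto the synthesis grid and truncate the flat head
# and zero tail, keeping volumes strictly inside (0, 100).
synth_dvh_points <- function(d50, slope, dmax) {
  dose <- seq(0, dmax, by = .fixture_dose_step)
  vol <- 100 / (1 + exp((dose - d50) / slope))
  keep <- vol > 1e-4 & vol < 100 - 1e-4
  list(dose_gy = round(dose[keep], 6), volume_pct = vol[keep])
}

#' Generate synthetic adaptive courses with ground truth
#'
#' Produces, per patient and fraction: one reference-plan check (before
#' fraction 1), one pre-treatment check per scheduled/adaptive plan (one pair
#' per structure-set revision), and exactly one delivery log-file check whose
#' `linked_check_id` names the delivered plan's pre-treatment check. DVH
#' point lists are truncated sigmoid curves (see the package vignette);
#' bladder volume drifts linearly over the course while other organs vary
#' with session noise.
#'
#' @param config A [fixture_config()].
#' @return A list of class `fixture_set` with elements `documents` (list of
#'   plan-check documents in the JSON dialect), `ground_truth` (delivered
#'   plans, adapted flags, per-structure volume trajectories and the DVH
#'   parameters used for synthesis — never passed through the client path)
#'   and `config`.
#' @export
generate_course <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  tpl <- .site_templates[[config$site]]
  dmax <- tpl$course_dose_gy * 1.25
  documents <- list()
  truth <- list()

  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("%s-PAT%03d", config$institution_label, p)
    reference_id <- sprintf("IM%03d", 100 + p)
    chk_counter <- 0L
    next_check_id <- function() {
      chk_counter <<- chk_counter + 1L
      sprintf("chk-%03d-%04d", p, chk_counter)
    }
    start_date <- as.Date("2024-01-08") + (p - 1L) * 60L

    # Reference structure set: template volumes with a little per-patient
    # anatomy scatter; centroids near a site-nominal position.
    ref_structs <- lapply(tpl$structures, function(s) {
      s$volume <- s$volume * stats::runif(1, 0.85, 1.15)
      s$centroid <- round(stats::rnorm(3, mean = c(0, 2, -10), sd = 2), 3)
      s
    })
    names(ref_structs) <- vapply(ref_structs, `[[`, character(1), "name")

    truth_volumes <- list()   # fraction 0 = reference
    truth_delivered <- list()
    truth_params <- list()

    structure_entries <- function(vols, shifts = NULL) {
      lapply(names(ref_structs), function(nm) {
        s <- ref_structs[[nm]]
        shift <- if (is.null(shifts)) c(0, 0, 0) else shifts[[nm]]
        list(name = nm,
             volume_cm3 = round(vols[[nm]], 3),
             density_override_g_cm3 = if (nm == "Bladder") 1.0 else NULL,
             centroid_cm = round(as.numeric(s$centroid) + shift, 3))
      })
    }

    dvh_sets <- function(plan_name, jitter_sd) {
      tp <- list(); sec <- list()
      for (nm in names(ref_structs)) {
        s <- ref_structs[[nm]]
        d50_t <- s$d50 * (1 + stats::rnorm(1, 0, jitter_sd))
        d50_s <- d50_t * (1 + stats::rnorm(1, 0, 0.003))
        tp[[nm]] <- synth_dvh_points(d50_t, s$slope, dmax)
        sec[[nm]] <- synth_dvh_points(d50_s, s$slope, dmax)
        truth_params[[length(truth_params) + 1L]] <<- list(
          plan_name = plan_name, structure = nm,
          d50_tpms = d50_t, d50_secondary = d50_s, slope = s$slope)
      }
      list(tpms = tp, secondary = sec)
    }

    make_beams <- function() {
      n_beams <- 9L
      lapply(seq_len(n_beams), function(b) {
        list(isocenter_cm = round(stats::rnorm(3, c(0, 2, -10), 0.05), 3),
             n_control_points = 20L,
             gantry_angles_deg = round((b - 1L) * 360 / n_beams, 1),
             collimator_angle_deg = round(stats::runif(1, 0, 15), 1),
             mu = round(stats::runif(1, 70, 130), 2))
      })
    }

    make_doc <- function(check_id, kind, plan_name, timestamp, vols = NULL,
                         jitter_sd = 0, linked = NULL, shifts = NULL) {
      doc <- list(
        check_id = check_id,
        patient_id = patient_id,
        check_kind = kind,
        planName_str = plan_name,
        timestamp = timestamp,
        site = config$site,
        dose_unit = "Gy",
        prescription_cgy = tpl$prescription_cgy
      )
      if (kind == "logfile") {
        doc$linked_check_id <- linked
      } else {
        doc$structures <- structure_entries(vols, shifts)
        doc$beams <- make_beams()
        doc$dvh <- dvh_sets(plan_name, jitter_sd)
      }
      doc
    }

    # reference plan check, a week before fraction 1
    ref_vols <- lapply(ref_structs, `[[`, "volume")
    truth_volumes[[1L]] <- list(fraction = 0L, volumes = ref_vols)
    documents[[length(documents) + 1L]] <- make_doc(
      next_check_id(), "pretreatment", reference_id,
      iso_timestamp(start_date - 7L, 9L), vols = ref_vols, jitter_sd = 0)

    for (f in seq_len(config$fractions_per_patient)) {
      day <- start_date + (f - 1L)
      # session volumes: bladder drifts linearly, other OARs jitter,
      # targets stay fixed; constant across revisions within a fraction
      vols <- lapply(names(ref_structs), function(nm) {
        v <- ref_vols[[nm]]
        if (nm == "Bladder") v * (1 + .bladder_drift * f)
        else if (is.null(ref_structs[[nm]]$target_dose_gy)) {
          v * max(0.5, 1 + stats::rnorm(1, 0, 0.08))
        } else v
      })
      names(vols) <- names(ref_structs)
      truth_volumes[[length(truth_volumes) + 1L]] <- list(fraction = f, volumes = vols)
      # daily anatomy displacement of each structure's center of mass
      shifts <- lapply(names(ref_structs), function(nm) {
        if (is.null(ref_structs[[nm]]$target_dose_gy)) round(stats::rnorm(3, 0, 0.3), 3)
        else round(stats::rnorm(3, 0, 0.1), 3)
      })
      names(shifts) <- names(ref_structs)

      n_rev <- 1L + stats::rbinom(1L, 1L, config$revision_probability)
      pretreat_ids <- list()
      for (r in seq_len(n_rev)) {
        sch_name <- sprintf("%s/SCH%02d%02d", reference_id, f, 2L * r - 1L)
        adp_name <- sprintf("%s/ADP%02d%02d", reference_id, f, 2L * r)
        sch_id <- next_check_id(); adp_id <- next_check_id()
        documents[[length(documents) + 1L]] <- make_doc(
          sch_id, "pretreatment", sch_name,
          iso_timestamp(day, 8L, (r - 1L) * 20L), vols = vols, jitter_sd = 0.05,
          shifts = shifts)
        documents[[length(documents) + 1L]] <- make_doc(
          adp_id, "pretreatment", adp_name,
          iso_timestamp(day, 8L, (r - 1L) * 20L + 5L), vols = vols, jitter_sd = 0.02,
          shifts = shifts)
        pretreat_ids[[r]] <- list(scheduled = list(id = sch_id, name = sch_name),
                                  adaptive = list(id = adp_id, name = adp_name))
      }
      adapted <- stats::runif(1) < config$adapt_probability
      last <- pretreat_ids[[n_rev]]
      delivered <- if (adapted) last$adaptive else last$scheduled
      documents[[length(documents) + 1L]] <- make_doc(
        next_check_id(), "logfile", delivered$name,
        iso_timestamp(day, 10L), linked = delivered$id)
      truth_delivered[[f]] <- list(fraction = f, plan_name = delivered$name,
                                   adapted = adapted)
    }

    truth[[patient_id]] <- list(
      patient_id = patient_id,
      reference_id = reference_id,
      site = config$site,
      bladder_drift_per_fraction = .bladder_drift,
      delivered = truth_delivered,
      volumes = truth_volumes,
      dvh_params = truth_params
    )
  }

  structure(list(documents = documents, ground_truth = truth, config = config),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> %d documents, %d patients, site %s, seed %d\n",
              length(x$documents), x$config$n_patients, x$config$site,
              x$config$seed))
  invisible(x)
}

#' Write a fixture set to a directory (file-backed source mode)
#'
#' Lays out one JSON file per check under `checks/`, an `index.json` with
#' per-patient check summaries and the access token, and the ground truth in
#' a separate `ground_truth.json` (the ground truth is never served through
#' the client path).
#'
#' @param fixture A `fixture_set` from [generate_course()].
#' @param dir Output directory (created if missing).
#' @param token Access token the endpoint will require (default
#'   `"fixture-token"`).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir, token = "fixture-token") {
  stopifnot(inherits(fixture, "fixture_set"))
  dir.create(file.path(dir, "checks"), recursive = TRUE, showWarnings = FALSE)
  patients <- list()
  for (doc in fixture$documents) {
    write_json_file(doc, file.path(dir, "checks", paste0(doc$check_id, ".json")))
    s <- list(check_id = doc$check_id, patient_id = doc$patient_id,
              plan_name = doc$planName_str, check_kind = doc$check_kind,
              timestamp = doc$timestamp)
    if (!is.null(doc$linked_check_id)) s$linked_check_id <- doc$linked_check_id
    patients[[doc$patient_id]] <- c(patients[[doc$patient_id]], list(s))
  }
  write_json_file(list(token = token, patients = patients),
                  file.path(dir, "index.json"))
  write_json_file(fixture$ground_truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Serve a written fixture directory over HTTP
#'
#' Starts the bundled loopback HTTP endpoint (a Python standard-library
#' script shipped under `inst/fixtureserver/`) answering the three request
#' shapes the client issues: `POST /auth` (static token exchange),
#' `GET /patients/{id}/checks` (summaries) and `GET /checks/{check_id}`
#' (full document; unknown IDs get a 404). Stop it with [stop_fixture()].
#'
#' @param dir Directory written by [write_fixture()].
#' @param port TCP port on 127.0.0.1.
#' @param timeout Seconds to wait for the endpoint to come up.
#' @return A `fixture_server` handle with `base_url`, `port` and `pid`.
#' @export
serve_fixture <- function(dir, port = 8123L, timeout = 10) {
  script <- system.file("fixtureserver", "fixture_server.py", package = "oartex")
  if (!nzchar(script)) oartex_error("bundled fixture server script not found",
                                    "oartex_config_error")
  logfile <- tempfile("fixture-server-", fileext = ".log")
  pid <- sys_spawn("python", c(script, "--dir", normalizePath(dir),
                               "--port", as.character(port)), logfile)
  base_url <- sprintf("http://127.0.0.1:%d", port)
  up <- FALSE
  for (i in seq_len(as.integer(timeout * 20))) {
    Sys.sleep(0.05)
    status <- tryCatch(http_request("GET", paste0(base_url, "/ping"))$status,
                       error = function(e) NA_integer_)
    if (identical(status, 200L)) { up <- TRUE; break }
    if (!is.na(status) && status != 200L) break
  }
  if (!up) {
    log <- tryCatch(paste(readLines(logfile, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    tools::pskill(pid)
    oartex_error(sprintf("fixture endpoint failed to start on port %d%s", port,
                         if (grepl("in use", log)) " (port in use)" else ""),
                 "oartex_server_error", log = log)
  }
  structure(list(base_url = base_url, port = port, pid = pid, dir = dir,
                 logfile = logfile),
            class = "fixture_server")
}

#' Stop a running fixture endpoint
#' @param server Handle returned by [serve_fixture()].
#' @export
stop_fixture <- function(server) {
  stopifnot(inherits(server, "fixture_server"))
  tools::pskill(server$pid)
  invisible(NULL)
}

# Spawn a detached process, returning its PID.
sys_spawn <- function(cmd, args, logfile) {
  pidfile <- tempfile("pid-")
  full <- sprintf("%s %s > %s 2>&1 & echo $! > %s",
                  shQuote(Sys.which(cmd)),
                  paste(shQuote(args), collapse = " "),
                  shQuote(logfile), shQuote(pidfile))
  system2("sh", c("-c", shQuote(full)))
  for (i in 1:100) {
    if (file.exists(pidfile) && length(readLines(pidfile, warn = FALSE)) > 0) break
    Sys.sleep(0.02)
  }
  as.integer(readLines(pidfile, warn = FALSE)[1])
}
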