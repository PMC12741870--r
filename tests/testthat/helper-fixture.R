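# Shared fixture helpers: generate a course set, write it, open a
# file-backed session, and run the client path for one patient.

make_fixture <- function(n_patients = 1L, fractions = 2L,
                         revision_probability = 0, adapt_probability = 0.7,
                         seed = 1L, site = "pelvis", token = "fixture-token") {
  cfg <- fixture_config(n_patients = n_patients,
                        fractions_per_patient = fractions,
                        revision_probability = revision_probability,
                        adapt_probability = adapt_probability,
                        site = site, seed = seed)
  fx <- generate_course(cfg)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fixture(fx, dir, token = token)
  list(fx = fx, dir = dir, token = token)
}

fixture_patient_ids <- function(fx) {
  unique(vapply(fx$documents, function(d) d$patient_id, character(1)))
}

# Run list -> fetch -> resolve -> build for one fixture patient.
client_course <- function(dir, patient_id, token = "fixture-token") {
  session <- open_session(file_transport(dir), token)
  checks <- list_plan_checks(session, patient_id)
  docs <- lapply(checks$check_id[checks$check_kind == "pretreatment"],
                 fetch_check, session = session)
  delivered <- resolve_delivered(checks)
  build_course(docs, delivered)
}

# Random truncated monotone DVH point list for property tests.
random_dvh_points <- function() {
  n <- sample(2:40, 1)
  dose <- sort(runif(n, 0.1, 70))
  vol <- sort(runif(n, 0.5, 99.5), decreasing = TRUE)
  list(dose = dose, vol = vol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
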