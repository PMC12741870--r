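# Cohort store: UID assignment, append/replace, export/merge, de-identification.

make_rows <- function(uid, plans = c("IM900/SCH0101"), structures = c("Rectum"),
                      fraction = 1L, ts = "2024-02-01T08:00:00") {
  grid <- expand.grid(plan_name = plans, structure = structures,
                      stringsAsFactors = FALSE)
  data.frame(patient_uid = uid, site = "pelvis", fraction = fraction,
             plan_name = grid$plan_name, plan_type = "scheduled",
             revision = 1L, delivered = FALSE, adapted = NA,
             structure = grid$structure, role = "oar", volume_cm3 = 50,
             delta_cm3 = 0, delta_rel = 0, centroid_shift_cm = 0,
             total_mu = 700, modulation_factor = 2.8,
             n_control_points = 180L, n_beams = 9L,
             timestamp = ts, stringsAsFactors = FALSE)
}

test_that("UIDs are sequential, idempotent and institution-prefixed", {
  store <- cohort_store(institution_id = "1234")
  uids <- vapply(sprintf("MRN-%03d", 1:19), assign_uid, character(1),
                 store = store)
  expect_equal(unname(uids[19]), "1234-00019")
  expect_equal(unname(uids[1]), "1234-00001")
  # same source ID returns the same UID, no new index
  expect_equal(assign_uid(store, "MRN-007"), "1234-00007")
  expect_equal(nrow(store$lookback), 19L)

  expect_error(assign_uid(cohort_store(), "X"), class = "oartex_config_error")
})

test_that("append replaces a patient's rows atomically", {
  store <- cohort_store(institution_id = "1234")
  uid <- assign_uid(store, "MRN-1")
  append_patient(store, make_rows(uid, structures = c("Rectum", "Bladder")))
  expect_equal(nrow(store$rows), 2L)

  # re-append a modified course: old rows replaced, not duplicated
  append_patient(store, make_rows(uid, plans = c("IM900/SCH0101", "IM900/ADP0102"),
                                  structures = "Rectum"))
  expect_equal(nrow(store$rows), 2L)
  expect_setequal(store$rows$plan_name, c("IM900/SCH0101", "IM900/ADP0102"))

  # a second patient adds rows
  uid2 <- assign_uid(store, "MRN-2")
  append_patient(store, make_rows(uid2))
  expect_equal(nrow(store$rows), 3L)

  # duplicate key within an append is an integrity error
  bad <- rbind(make_rows(uid), make_rows(uid))
  expect_error(append_patient(store, bad), class = "oartex_integrity_error")

  # unregistered extensible column is rejected; registered one passes
  rows <- make_rows(uid); rows$myMetric <- 1
  expect_error(append_patient(store, rows), class = "oartex_config_error")
  register_column(store, "myMetric", unit = "Gy")
  append_patient(store, rows)
  expect_true("myMetric" %in% names(store$rows))
  # core columns cannot be shadowed in the registry
  expect_error(register_column(store, "volume_cm3", unit = "cm3"),
               class = "oartex_config_error")
})

test_that("collectors round-trip a store losslessly", {
  store <- cohort_store(institution_id = "1234")
  uid <- assign_uid(store, "MRN-1")
  register_column(store, "myMetric", unit = "%")
  rows <- make_rows(uid, structures = c("Rectum", "Bladder"))
  rows$myMetric <- c(12.5, 33.1)
  append_patient(store, rows)

  for (collector in list(dir_collector(withr::local_tempdir()),
                         rds_collector(withr::local_tempfile(fileext = ".rds")))) {
    collector_save(collector, store)
    back <- collector_load(collector)
    expect_equal(back$rows, store$rows)
    expect_equal(back$lookback, store$lookback)
    expect_equal(back$column_registry, store$column_registry)
    expect_equal(back$institution_id, store$institution_id)
  }
})

test_that("export is de-identified, filtered, and round-trips", {
  store <- cohort_store(institution_id = "1234")
  uid1 <- assign_uid(store, "SECRETMRN-881")
  uid2 <- assign_uid(store, "SECRETMRN-882")
  append_patient(store, make_rows(uid1, structures = c("Rectum", "Bladder")))
  rows2 <- make_rows(uid2); rows2$site <- "thorax"; rows2$structure <- "Heart"
  append_patient(store, rows2)

  path <- withr::local_tempfile(fileext = ".tar.gz")
  export_cohort(store, path)
  back <- import_cohort(path)
  expect_equal(nrow(back$rows), 3L)
  expect_setequal(back$rows$patient_uid, c(uid1, uid2))

  # timestamps are shifted per patient but intervals are preserved
  orig <- store$rows[store$rows$patient_uid == uid1, "timestamp"]
  got <- back$rows[back$rows$patient_uid == uid1, "timestamp"]
  expect_false(any(got == orig))
  expect_equal(substr(got, 11, 19), substr(orig, 11, 19))  # time of day kept

  # no source identifier appears anywhere in the archive bytes
  stage <- withr::local_tempdir()
  utils::untar(path, exdir = stage)
  blob <- paste(unlist(lapply(list.files(stage, recursive = TRUE,
                                         full.names = TRUE), readLines,
                              warn = FALSE)), collapse = "\n")
  expect_false(grepl("SECRETMRN", blob))
  expect_true(grepl(uid1, blob, fixed = TRUE))

  # filter: expression over columns; unknown columns are named in the error
  p2 <- withr::local_tempfile(fileext = ".tar.gz")
  export_cohort(store, p2, filter = quote(site == "pelvis"))
  pelvis <- import_cohort(p2)
  expect_true(all(pelvis$rows$site == "pelvis"))
  expect_equal(nrow(pelvis$rows), 2L)
  expect_error(export_cohort(store, p2, filter = quote(nope == 1)),
               "available", class = "oartex_config_error")

  # interval preservation across a patient's fractions
  store2 <- cohort_store(institution_id = "9")
  u <- assign_uid(store2, "A")
  r <- rbind(make_rows(u, ts = "2024-02-01T08:00:00"),
             make_rows(u, plans = "IM900/SCH0201", fraction = 2L,
                       ts = "2024-02-04T08:00:00"))
  append_patient(store2, r)
  p3 <- withr::local_tempfile(fileext = ".tar.gz")
  export_cohort(store2, p3)
  b2 <- import_cohort(p3)
  d <- sort(as.Date(substr(b2$rows$timestamp, 1, 10)))
  expect_equal(as.integer(diff(d)), 3L)
})

test_that("merging keeps institutions disjoint and detects conflicts", {
  a <- cohort_store(institution_id = "1111")
  ua <- assign_uid(a, "A-1")
  append_patient(a, make_rows(ua))
  b <- cohort_store(institution_id = "2222")
  ub <- assign_uid(b, "B-1")
  append_patient(b, make_rows(ub, structures = c("Rectum", "Bladder")))

  m <- merge_cohorts(a, b)
  expect_equal(nrow(m$rows), 3L)
  expect_setequal(unique(sub("-[0-9]+$", "", m$rows$patient_uid)),
                  c("1111", "2222"))

  # identity: merging with an empty store changes nothing
  empty <- cohort_store(institution_id = "3333")
  m2 <- merge_cohorts(a, empty)
  expect_equal(m2$rows, a$rows)

  # associativity up to row order on disjoint institutions
  c3 <- cohort_store(institution_id = "4444")
  uc <- assign_uid(c3, "C-1")
  append_patient(c3, make_rows(uc))
  left <- merge_cohorts(merge_cohorts(a, b), c3)$rows
  right <- merge_cohorts(a, merge_cohorts(b, c3))$rows
  key <- function(df) df[order(df$patient_uid, df$plan_name, df$structure), ]
  expect_equal(key(left), key(right), ignore_attr = TRUE)

  # re-import of identical rows deduplicates
  m3 <- merge_cohorts(a, a)
  expect_equal(nrow(m3$rows), 1L)

  # same institution, same key, different content: conflict naming the key
  a2 <- cohort_store(institution_id = "1111")
  ua2 <- assign_uid(a2, "A-1")
  conflicting <- make_rows(ua2); conflicting$volume_cm3 <- 99
  append_patient(a2, conflicting)
  expect_error(merge_cohorts(a, a2), class = "oartex_merge_conflict")

  # schema version mismatch
  v2 <- cohort_store(institution_id = "5555", schema_version = "2")
  expect_error(merge_cohorts(a, v2), class = "oartex_config_error")
})

test_that("extensible column unit collisions are suffixed with a warning", {
  a <- cohort_store(institution_id = "1111")
  ua <- assign_uid(a, "A-1")
  register_column(a, "myMetric", unit = "%")
  ra <- make_rows(ua); ra$myMetric <- 10
  append_patient(a, ra)

  b <- cohort_store(institution_id = "2222")
  ub <- assign_uid(b, "B-1")
  register_column(b, "myMetric", unit = "Gy")
  rb <- make_rows(ub); rb$myMetric <- 20
  append_patient(b, rb)

  expect_warning(m <- merge_cohorts(a, b), class = "oartex_column_collision")
  expect_true(all(c("myMetric_1111", "myMetric_2222") %in% names(m$rows)))
  expect_false("myMetric" %in% names(m$rows))
  expect_equal(m$column_registry$myMetric_1111$unit, "%")
  expect_equal(m$column_registry$myMetric_2222$unit, "Gy")

  # same unit: columns merge cleanly
  b2 <- cohort_store(institution_id = "2222")
  ub2 <- assign_uid(b2, "B-1")
  register_column(b2, "myMetric", unit = "%")
  rb2 <- make_rows(ub2); rb2$myMetric <- 20
  append_patient(b2, rb2)
  m2 <- merge_cohorts(a, b2)
  expect_true("myMetric" %in% names(m2$rows))
  expect_equal(sort(m2$rows$myMetric), c(10, 20))
})
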