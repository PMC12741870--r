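# End-to-end extraction runs, fault isolation and incremental updates.

quiet_config <- function(dir, store_dir, ...) {
  run_config(source = list(kind = "file", dir = dir), token = "fixture-token",
             institution_id = "1234", store_dir = store_dir,
             log_level = "quiet", ...)
}

# Write a reduced copy of a fixture containing only fractions <= keep
# (reference documents are always kept, as is each kept fraction's log-file
# check).
write_partial_fixture <- function(fx, dir, keep) {
  frac_of <- function(doc) {
    id <- parse_plan_name(doc$planName_str)
    if (id$plan_type == "reference") 0L else id$fraction
  }
  partial <- fx
  partial$documents <- Filter(function(d) frac_of(d) <= keep, fx$documents)
  write_fixture(partial, dir)
  dir
}

test_that("a run reports exactly what the generator put in the source", {
  fixture <- make_fixture(n_patients = 3, fractions = 3, seed = 501)
  store_dir <- file.path(withr::local_tempdir(), "store")
  cfg <- quiet_config(fixture$dir, store_dir,
                      objectives = list(objective_spec("V_at_dose", 42.5,
                                                       "Rectum")))
  report <- run_extraction(cfg, fixture_patient_ids(fixture$fx))

  expect_s3_class(report, "run_report")
  expect_equal(report$n_patients, 3L)
  expect_equal(report$n_ok, 3L)
  expect_equal(report$n_failed, 0L)
  expect_equal(report$n_sessions, 3L * 3L)
  # per patient: 1 reference + 2 pre-treatment plans per fraction
  expect_equal(report$n_plans, 3L * (1L + 2L * 3L))

  store <- collector_load(dir_collector(store_dir))
  # rows: per patient, 7 plans x 6 pelvis structures
  expect_equal(nrow(store$rows), 3L * 7L * 6L)
  expect_setequal(unique(store$rows$patient_uid),
                  sprintf("1234-%05d", 1:3))
  # no source patient identifier leaks into the row table
  expect_false(any(fixture_patient_ids(fixture$fx) %in%
                     unlist(store$rows)))
  # objective column present and populated exactly on Rectum rows
  expect_true(all(is.na(store$rows$V42.5Gy_Rectum) !=
                    (store$rows$structure == "Rectum")))
  # delivered flags: one delivered plan per fraction per patient
  del <- store$rows[store$rows$delivered & store$rows$structure == "Rectum", ]
  expect_equal(nrow(del), 3L * 3L)
  # ground truth agreement on which plan was delivered
  for (pid in fixture_patient_ids(fixture$fx)) {
    gt <- fixture$fx$ground_truth[[pid]]
    uid <- store$lookback$patient_uid[store$lookback$source_patient_id == pid]
    mine <- del[del$patient_uid == uid, ]
    for (g in gt$delivered) {
      expect_equal(mine$plan_name[mine$fraction == g$fraction], g$plan_name)
    }
  }
})

test_that("one failing patient is isolated; all failing aborts the run", {
  fixture <- make_fixture(n_patients = 3, fractions = 2, seed = 503)
  ids <- fixture_patient_ids(fixture$fx)
  # break patient 2: remove one of its pre-treatment documents from disk
  idx <- oartex:::read_json_file(file.path(fixture$dir, "index.json"))
  victim <- Filter(function(s) s$check_kind == "pretreatment",
                   idx$patients[[ids[2]]])[[1]]
  file.remove(file.path(fixture$dir, "checks",
                        paste0(victim$check_id, ".json")))

  store_dir <- file.path(withr::local_tempdir(), "store")
  report <- run_extraction(quiet_config(fixture$dir, store_dir), ids)
  expect_equal(report$n_ok, 2L)
  expect_equal(report$n_failed, 1L)
  expect_equal(report$details[[ids[2]]]$status, "failed")
  expect_match(report$details[[ids[2]]]$message, victim$check_id,
               fixed = TRUE)
  store <- collector_load(dir_collector(store_dir))
  expect_equal(length(unique(store$rows$patient_uid)), 2L)

  # unknown patients count as empty, not failures
  report2 <- run_extraction(quiet_config(fixture$dir,
                                         file.path(withr::local_tempdir(), "s")),
                            c(ids[1], "NOBODY"))
  expect_equal(report2$n_ok, 1L)
  expect_equal(report2$n_empty, 1L)

  # every patient failing is a run error
  unlink(list.files(file.path(fixture$dir, "checks"), full.names = TRUE))
  expect_error(
    run_extraction(quiet_config(fixture$dir,
                                file.path(withr::local_tempdir(), "s2")), ids),
    class = "oartex_run_error")
})

test_that("a rerun from the same source is byte-identical", {
  fixture <- make_fixture(n_patients = 2, fractions = 2, seed = 505)
  ids <- fixture_patient_ids(fixture$fx)
  base <- withr::local_tempdir()
  exports <- character(2)
  for (i in 1:2) {
    store_dir <- file.path(base, paste0("store", i))
    run_extraction(quiet_config(fixture$dir, store_dir,
                                objectives = list(objective_spec(
                                  "V_at_dose", 42.5, "Rectum"))), ids)
    exports[i] <- file.path(base, paste0("cohort", i, ".tar.gz"))
    export_cohort(collector_load(dir_collector(store_dir)), exports[i])
  }
  t1 <- readLines(file.path(base, "store1", "table.csv"))
  t2 <- readLines(file.path(base, "store2", "table.csv"))
  expect_identical(t1, t2)
  expect_identical(readBin(exports[1], "raw", file.size(exports[1])),
                   readBin(exports[2], "raw", file.size(exports[2])))
})

test_that("daily updates fetch only new fractions and are idempotent", {
  fixture <- make_fixture(n_patients = 2, fractions = 3, seed = 507)
  ids <- fixture_patient_ids(fixture$fx)
  src <- withr::local_tempdir()
  write_partial_fixture(fixture$fx, src, keep = 2L)

  store_dir <- file.path(withr::local_tempdir(), "store")
  cfg <- quiet_config(src, store_dir)
  run_extraction(cfg, ids)
  before <- collector_load(dir_collector(store_dir))$rows
  expect_equal(max(before$fraction), 2L)

  # nothing new at the source: every patient is current, rows untouched
  rep0 <- run_daily_update(cfg)
  expect_equal(rep0$n_current, 2L)
  expect_equal(rep0$n_plans, 0L)
  expect_identical(collector_load(dir_collector(store_dir))$rows, before)

  # fraction 3 arrives
  write_fixture(fixture$fx, src)
  rep1 <- run_daily_update(cfg)
  expect_equal(rep1$n_ok, 2L)
  # only the reference plan and the new fraction's plans were fetched
  expect_equal(rep1$n_plans, 2L * 3L)
  after <- collector_load(dir_collector(store_dir))$rows
  # exactly the new fraction's rows appended: 2 patients x 2 plans x 6 rois
  expect_equal(nrow(after) - nrow(before), 2L * 2L * 6L)
  expect_equal(max(after$fraction), 3L)
  # pre-existing fraction rows are unchanged
  key <- function(df) {
    df <- df[df$fraction <= 2, , drop = FALSE]
    df[order(df$patient_uid, df$plan_name, df$structure), , drop = FALSE]
  }
  expect_equal(key(after), key(before), ignore_attr = TRUE)
  # updated store equals a from-scratch extraction of the full source
  fresh_dir <- file.path(withr::local_tempdir(), "fresh")
  run_extraction(quiet_config(src, fresh_dir), ids)
  fresh <- collector_load(dir_collector(fresh_dir))$rows
  ord <- function(df) df[order(df$patient_uid, df$plan_name, df$structure), ]
  expect_equal(ord(after), ord(fresh), ignore_attr = TRUE)

  # and updating again is a no-op
  rep2 <- run_daily_update(cfg)
  expect_equal(rep2$n_current, 2L)
  expect_identical(collector_load(dir_collector(store_dir))$rows, after)

  # update without a prior store errors cleanly
  expect_error(run_daily_update(quiet_config(src, file.path(src, "nostore"))),
               class = "oartex_config_error")
})

test_that("a backdated unseen check triggers a full refetch with a warning", {
  fixture <- make_fixture(n_patients = 1, fractions = 2, seed = 509)
  ids <- fixture_patient_ids(fixture$fx)
  src <- withr::local_tempdir()
  write_partial_fixture(fixture$fx, src, keep = 2L)
  # drop fraction 1 from the initial snapshot, keep fraction 2: the
  # fraction-1 checks later appear with timestamps before the last-seen mark
  idx <- oartex:::read_json_file(file.path(src, "index.json"))
  keep2 <- Filter(function(s) {
    id <- parse_plan_name(s$plan_name)
    id$plan_type == "reference" || id$fraction == 2L
  }, idx$patients[[ids[1]]])
  idx$patients[[ids[1]]] <- keep2
  oartex:::write_json_file(idx, file.path(src, "index.json"))

  store_dir <- file.path(withr::local_tempdir(), "store")
  cfg <- quiet_config(src, store_dir)
  run_extraction(cfg, ids)
  expect_equal(max(collector_load(dir_collector(store_dir))$rows$fraction), 2L)

  # restore the full index: fraction 1 is now unseen but backdated
  write_fixture(fixture$fx, src)
  expect_warning(rep1 <- run_daily_update(cfg), class = "oartex_clock_skew")
  expect_equal(rep1$n_ok, 1L)
  rows <- collector_load(dir_collector(store_dir))$rows
  expect_setequal(unique(rows$fraction), 0:2)
})

test_that("run configuration is serializable and validated", {
  expect_error(run_config(source = list(kind = "carrier_pigeon"),
                          token = "t", institution_id = "1",
                          store_dir = "s"),
               class = "oartex_config_error")
  cfg <- quiet_config("somedir", "somestore", seed = 99L)
  json <- oartex:::to_json(cfg[c("source", "token", "institution_id",
                                 "store_dir", "seed", "log_level")])
  back <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  expect_equal(back$source$dir, "somedir")
  expect_equal(back$seed, 99L)
})
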