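# Figures are asserted through their exported series, never pixels.

test_that("volume trend series matches the analytics and writes its sidecar", {
  fixture <- make_fixture(n_patients = 1, fractions = 4, seed = 401)
  pid <- fixture_patient_ids(fixture$fx)[1]
  course <- client_course(fixture$dir, pid)

  spec <- plot_volume_trend(course, "Bladder", mode = "relative")
  expect_s3_class(spec, "figure_spec")
  trend <- volume_trend(course, "Bladder")
  expect_equal(nrow(spec$series), nrow(trend))  # one row per delivered fraction
  expect_equal(spec$series$value, 100 * trend$delta_rel)
  expect_equal(spec$options$baseline, 0)
  expect_setequal(unique(spec$series$session), c("adapted", "scheduled")[
    c(any(trend$adapted), any(!trend$adapted))])

  abs_spec <- plot_volume_trend(course, "Bladder", mode = "absolute")
  expect_equal(abs_spec$series$value, trend$volume_cm3)
  ref_vol <- Filter(function(s) s$name == "Bladder",
                    course$reference_doc$structures)[[1]]$volume_cm3
  expect_equal(abs_spec$options$baseline, ref_vol)

  # rendering writes image + series CSV
  img <- file.path(withr::local_tempdir(), "trend.png")
  plot_volume_trend(course, "Bladder", mode = "relative", file = img)
  expect_true(file.exists(img))
  side <- utils::read.csv(sub("\\.png$", "_series.csv", img))
  expect_equal(side$value, spec$series$value)

  # unknown structure: error lists what exists
  expect_error(plot_volume_trend(course, "Cochlea"), "Bladder",
               class = "oartex_missing_structure")
})

test_that("all-scheduled courses carry only the scheduled category", {
  fixture <- make_fixture(n_patients = 1, fractions = 3,
                          adapt_probability = 0, seed = 403)
  pid <- fixture_patient_ids(fixture$fx)[1]
  course <- client_course(fixture$dir, pid)
  spec <- plot_volume_trend(course, "Rectum", mode = "absolute")
  expect_true(all(spec$series$session == "scheduled"))

  # relative mode on constant volumes is flat at zero (targets do not move)
  spec2 <- plot_volume_trend(course, "PTV_High", mode = "relative")
  expect_equal(spec2$series$value, rep(0, nrow(spec2$series)))
})

test_that("DVH spread series reproduces the band arrays exactly", {
  fixture <- make_fixture(n_patients = 1, fractions = 3, seed = 405)
  pid <- fixture_patient_ids(fixture$fx)[1]
  course <- client_course(fixture$dir, pid)

  spec <- plot_dvh_spread(course, c("Rectum", "Bladder"), grid_step = 0.5)
  expect_setequal(unique(spec$series$panel), c("adaptive", "scheduled"))
  expect_setequal(unique(spec$series$structure), c("Rectum", "Bladder"))

  for (panel in c("adaptive", "scheduled")) {
    curves <- lapply(course$fractions, function(fs) {
      doc <- oartex:::select_fraction_plan(fs, panel)
      oartex:::document_dvh(doc, "Rectum", "tpms")
    })
    band <- dvh_band(curves,
                     reference = oartex:::document_dvh(course$reference_doc,
                                                       "Rectum", "tpms"),
                     grid_step = 0.5)
    sub <- spec$series[spec$series$structure == "Rectum" &
                         spec$series$panel == panel, ]
    expect_equal(sub$dose_gy, band$grid)
    expect_equal(sub$median, band$median)
    expect_equal(sub$p20, band$p20)
    expect_equal(sub$p80, band$p80)
    expect_equal(sub$lo, band$lo)
    expect_equal(sub$hi, band$hi)
    expect_equal(sub$reference, band$reference)
    # ordering invariant at every exported grid point
    expect_true(all(sub$lo <= sub$p20 & sub$p20 <= sub$median &
                      sub$median <= sub$p80 & sub$p80 <= sub$hi))
  }

  # single-fraction course: bands collapse onto the one curve
  f1 <- make_fixture(n_patients = 1, fractions = 1, seed = 406)
  c1 <- client_course(f1$dir, fixture_patient_ids(f1$fx)[1])
  s1 <- plot_dvh_spread(c1, "Rectum", grid_step = 0.5)
  adp <- s1$series[s1$series$panel == "adaptive", ]
  expect_equal(adp$lo, adp$hi)
  expect_equal(adp$lo, adp$median)

  # empty phase selection errors
  expect_error(plot_dvh_spread(course, "Rectum", phase = "boost"),
               class = "oartex_empty_phase")
  # boost split: primary gets fractions < boost_start
  s_pri <- plot_dvh_spread(course, "Rectum", phase = "primary", boost_start = 3,
                           grid_step = 1)
  s_all <- plot_dvh_spread(course, "Rectum", grid_step = 1)
  expect_false(identical(s_pri$series$median, s_all$series$median))
})

test_that("render is a pure function of the figure spec", {
  fixture <- make_fixture(n_patients = 1, fractions = 3, seed = 407)
  pid <- fixture_patient_ids(fixture$fx)[1]
  course <- client_course(fixture$dir, pid)
  dir <- withr::local_tempdir()
  plot_dvh_spread(course, "Rectum", grid_step = 1,
                  file = file.path(dir, "a.png"))
  plot_dvh_spread(course, "Rectum", grid_step = 1,
                  file = file.path(dir, "b.png"))
  a <- utils::read.csv(file.path(dir, "a_series.csv"))
  b <- utils::read.csv(file.path(dir, "b_series.csv"))
  expect_identical(a, b)
  # svg output is accepted too; other formats are not
  plot_dvh_spread(course, "Rectum", grid_step = 1,
                  file = file.path(dir, "c.svg"))
  expect_true(file.exists(file.path(dir, "c.svg")))
  expect_error(plot_dvh_spread(course, "Rectum", grid_step = 1,
                               file = file.path(dir, "c.pdf")),
               class = "oartex_config_error")
})

cohort_with_objective <- function(seed, n_patients = 2, fractions = 3) {
  fixture <- make_fixture(n_patients = n_patients, fractions = fractions,
                          revision_probability = 0, seed = seed)
  store <- cohort_store(institution_id = "1234")
  ob <- objective_spec("V_at_dose", 42.5, "Rectum")
  register_column(store, oartex:::objective_label(ob), unit = "%")
  for (pid in fixture_patient_ids(fixture$fx)) {
    course <- client_course(fixture$dir, pid)
    rows <- course_to_rows(course, assign_uid(store, pid),
                           objectives = list(ob))
    append_patient(store, rows)
  }
  list(store = store, spec = ob, fixture = fixture)
}

test_that("objective distributions export one row per contributing session", {
  ctx <- cohort_with_objective(409)
  fig <- plot_objective_distribution(ctx$store, ctx$spec,
                                     comparison = "adaptive_vs_scheduled")
  # one row per (patient, fraction)
  expect_equal(nrow(fig$series), 2 * 3)
  expect_equal(fig$series$diff, fig$series$adaptive - fig$series$scheduled)
  expect_equal(fig$series$ratio, fig$series$adaptive / fig$series$scheduled)

  fig2 <- plot_objective_distribution(ctx$store, ctx$spec,
                                      comparison = "vs_reference")
  # adaptive + scheduled rows per fraction per patient
  expect_equal(nrow(fig2$series), 2 * 3 * 2)
  expect_equal(fig2$series$diff, fig2$series$value - fig2$series$reference)

  # missing objective column in the cohort is an error
  other <- objective_spec("V_at_dose", 30, "Bladder")
  expect_error(plot_objective_distribution(ctx$store, other),
               class = "oartex_missing_objective")
})

test_that("degenerate distributions collapse to a point mass at zero", {
  ctx <- cohort_with_objective(411, n_patients = 1, fractions = 2)
  store <- ctx$store
  col <- oartex:::objective_label(ctx$spec)
  # force adaptive == scheduled and all == reference
  rect <- store$rows$structure == "Rectum"
  ref_val <- store$rows[[col]][rect & store$rows$plan_type == "reference"][1]
  store$rows[[col]][rect] <- ref_val

  paired <- plot_objective_distribution(store, ctx$spec,
                                        comparison = "adaptive_vs_scheduled")
  expect_true(all(paired$series$diff == 0))
  expect_true(all(paired$series$ratio == 1))

  vsref <- plot_objective_distribution(store, ctx$spec,
                                       comparison = "vs_reference")
  expect_true(all(vsref$series$diff == 0))

  # rendering degenerate data still works (binwidth fallback)
  img <- file.path(withr::local_tempdir(), "deg.png")
  plot_objective_distribution(store, ctx$spec,
                              comparison = "adaptive_vs_scheduled", file = img)
  expect_true(file.exists(img))
})
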