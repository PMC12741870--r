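# oartex

Extraction, analytics and cohort sharing for online adaptive radiotherapy
(oART) plan-check data.

## The scientific problem

In CBCT-guided online adaptive radiotherapy, every treatment session
produces two candidate plans on the day's anatomy — the *scheduled* plan
(the original plan recalculated) and the *adaptive* plan (re-optimized on
the couch) — and one of them is delivered. Both are pushed to a secondary
dose-verification system whose per-plan records ("checks") hold structures,
beams and dose-volume histograms from two independent dose engines, plus
log-file checks built from machine delivery logs. That store is a complete
session-by-session archive of the adaptive course, but it is only reachable
through a JSON API keyed by opaque check IDs.

`oartex` mines that archive into analyzable, de-identified cohort tables:

* **Plan lineage** — parses the adaptive naming grammar
  `"<RefID>/<SCH|ADP><fraction><suffix>"` (structure-set revision
  = ⌈suffix/2⌉) and resolves the *delivered* plan of each fraction from
  log-file check linkage, never from names.
* **DVH analytics** — rebuilds continuous cumulative DVHs from truncated
  point lists (exactly 100% below the first node, exactly 0% above the
  last, linear in between) and evaluates arbitrary V(D) / D(V) objectives
  and percentile bands across a course.
* **Anatomy tracking** — organ volumes, volume deltas and centroid shifts
  per session against the reference structure set, with role assignment
  (target tiers / OARs) from a configurable ROI registry.
* **Plan complexity** — total MU, modulation factor (MU per prescription
  cGy), control-point and beam counts.
* **Cohort store** — long-format rows (one per plan × structure) under
  sequential de-identified UIDs; export archives shift dates per patient
  while preserving intervals; archives from different institutions merge
  with disjoint UID namespaces and explicit conflict detection.
* **Visualization** — volume-trend, DVH-spread (percentile band) and
  objective-distribution figures; every image is written with its full
  numeric series as a CSV sidecar.
* **Synthetic fixture** — a generator of complete courses with known
  ground truth in the same JSON dialect, servable over loopback HTTP by a
  bundled Python standard-library script, so the entire pipeline runs and
  is tested offline.

## Worked example

Generate a one-patient synthetic course, run the client path against it,
and analyze the course:

```r
library(oartex)
cfg <- fixture_config(n_patients = 1, fractions_per_patient = 5, seed = 42)
fx  <- generate_course(cfg)
dir <- tempfile(); write_fixture(fx, dir)

session <- open_session(file_transport(dir), "fixture-token")
checks  <- list_plan_checks(session, "FIX-PAT001")
head(checks[, c("plan_name", "check_kind", "timestamp")], 4)
#>       plan_name   check_kind           timestamp
#> 1         IM101 pretreatment 2024-01-01T09:00:00
#> 2 IM101/SCH0101 pretreatment 2024-01-08T08:00:00
#> 3 IM101/ADP0102 pretreatment 2024-01-08T08:05:00
#> 4 IM101/ADP0102      logfile 2024-01-08T10:00:00

docs   <- lapply(checks$check_id[checks$check_kind == "pretreatment"],
                 fetch_check, session = session)
course <- build_course(docs, resolve_delivered(checks))
summary(course)
#>   fraction n_revisions     delivered adapted
#> 1        1           1 IM101/ADP0102    TRUE
#> 2        2           1 IM101/SCH0201   FALSE
#> 3        3           1 IM101/ADP0302    TRUE
#> 4        4           1 IM101/SCH0401   FALSE
#> 5        5           1 IM101/ADP0502    TRUE

parse_plan_name("IM103/ADP1403")
#> <plan_identity> IM103  adaptive plan, fraction 14, structure-set revision 2 (suffix 03)

volume_trend(course, "Bladder")[, c("fraction", "volume_cm3", "delta_rel", "adapted")]
#>   fraction volume_cm3  delta_rel adapted
#> 1        1    163.700 0.02000125    TRUE
#> 2        2    166.910 0.04000249   FALSE
#> 3        3    170.120 0.06000374    TRUE
#> 4        4    173.330 0.08000498   FALSE
#> 5        5    176.539 0.10000000    TRUE

spec <- objective_spec("V_at_dose", 42.5, "Rectum")
objective_series(course, spec, "delivered")[, c("fraction", "plan_name", "value", "reference_value")]
#>   fraction     plan_name    value reference_value
#> 1        1 IM101/ADP0102 25.72656        25.28757
#> 2        2 IM101/SCH0201 17.06842        25.28757
#> 3        3 IM101/ADP0302 25.52473        25.28757
#> 4        4 IM101/SCH0401 30.40147        25.28757
#> 5        5 IM101/ADP0502 26.05433        25.28757
```

The generator's bladder drift (+2% of the reference volume per fraction)
is visible directly in `delta_rel`. Full cohort runs — extraction over many
patients with fault isolation, incremental daily updates, export/merge —
go through `run_config()` / `run_extraction()` / `run_daily_update()`, or
the command-line front end at `inst/cli/oartex-cli.R` (subcommands
`extract`, `update`, `export`, `merge`, `plot`, `fixture generate`).

See the vignette (`vignettes/oart-plan-check-mining.Rmd`) for the methods
and conventions: naming grammar, DVH padding/interpolation rules, fixture
generator design, and the de-identification scheme.

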