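---
title: "Mining adaptive-radiotherapy plan-check data: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adaptive-radiotherapy plan-check data: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oartex)
```

## The problem

In CBCT-guided online adaptive radiotherapy (oART), every treatment session
produces a *scheduled* plan (the original plan recalculated on the day's
anatomy) and an *adaptive* plan (re-optimized on the couch); one of the pair
is delivered. Each plan is pushed to a secondary dose-verification system
that stores per-plan records ("checks") — structures, beams, dose-volume
histograms from both the treatment planning system (TPMS) and the
verification system's own calculation, and delivery log-file checks built
from machine logs. That store is, in effect, a session-by-session archive of
the whole adaptive course, but it exposes only a JSON API keyed by check ID.

`oartex` turns that archive into analyzable, de-identified cohort tables:
it enumerates and fetches checks, reconstructs plan lineage from plan names,
resolves which plan of each pair was actually delivered, computes DVH,
volume and complexity analytics, and accumulates everything in a mergeable
long-format store with one row per (plan, structure).

## Plan lineage from the naming grammar

Adaptive plan names follow `"<ReferenceID>/<SCH|ADP><FF><SS>"`: a
two-digit fraction number and a two-digit suffix. Each re-edit of the daily
contours (a *structure-set revision*) spawns a fresh scheduled/adaptive
pair, advancing the suffix by two, so revision = `ceiling(suffix / 2)`.
A name with no `/SCH`/`/ADP` token is the reference plan.

```{r naming}
parse_plan_name("IM103/SCH1401")   # fraction 14, revision 1
parse_plan_name("IM103/ADP1403")   # fraction 14, revision 2
```

Parsing accepts four *or more* trailing digits (the last two are always the
suffix) so courses beyond 99 fractions would not be misread; formatting
refuses fraction or suffix above 99 rather than emit an ambiguous name.
Malformed names raise a structured condition, and during course assembly
they are quarantined with a warning instead of corrupting the fraction
grouping.

The delivered plan of a fraction is *not* derivable from names: it is the
pre-treatment check referenced by that fraction's log-file check
(`resolve_delivered()`). When forged or duplicated log-file checks point at
the same fraction, the latest by timestamp wins, with a warning; dangling
links are dropped with a warning.

## DVH conventions

Checks store cumulative DVHs as truncated point lists: the flat 100% head
and the 0% tail are omitted. `build_dvh()` restores the continuous curve
with these fixed conventions:

* piecewise-linear interpolation between nodes;
* exactly 100% below the first dose and exactly 0% above the last dose
  (identical padding, not approximate);
* duplicate doses collapse keeping the maximum volume, volumes are clipped
  to [0, 100], and non-monotone inputs are repaired by cumulative minimum
  with a logged warning.

`dose_at_volume(v)` returns the smallest dose at which the curve has
dropped to `v` (flat segments resolve to their left endpoint; `v >= 100`
gives 0; `v` below the tail gives the last dose). Percentile bands for DVH
spread plots are computed on a regular dose grid (default 0.1 Gy) from 0 to
the common maximum, using quantile type 7 for the 20th/80th percentiles and
the median; tests verify these against per-grid-point recomputation. A plot
never mixes TPMS and secondary-calculation curves.

## Plan complexity

`plan_complexity()` sums monitor units over beams and reports the
modulation factor as total MU divided by the fraction prescription in cGy —
a deliberately simple surrogate (an override of the prescription is
accepted for other conventions). Control-point and beam counts are carried
along as additional complexity covariates.

## The synthetic fixture

Because the clinical source cannot ship with the package, `generate_course()`
emits complete synthetic courses in the same JSON dialect, together with a
ground-truth record that never passes through the client path. Defaults are
study conditions, fixed before any test outcomes were observed:

* per-structure DVHs are logistic sigmoids
  $V(d) = 100 / (1 + e^{(d - d_{50})/s})$ sampled at 0.1 Gy and truncated
  to the open interval (0, 100) — their closed form gives exact oracles;
* the TPMS and secondary curves of a plan differ by a small relative
  perturbation of $d_{50}$ (sd 0.3%), mimicking two dose engines;
* bladder volume drifts linearly at +2% of the reference volume per
  fraction; other OARs jitter (sd 8%), targets stay fixed;
* each fraction has one structure-set revision with probability 0.1 a
  second one, and the adaptive plan is delivered with probability 0.7;
* site templates (pelvis, thorax, head-and-neck) fix structure names,
  prescriptions and target tiers.

The fixture emulates the *data shapes and linkage semantics* of the
verification API — it does not emulate dose calculation, optimizer
behaviour, anatomical deformation, or DICOM transfer. A bundled
standard-library Python script serves a written fixture directory over
loopback HTTP with the same three request shapes the client issues, so the
full network path is testable offline; a file-backed transport covers
environments without a free port.

## De-identification and cohort sharing

`assign_uid()` maps source patient IDs to sequential UIDs
(`<institution>-<00001>`); the lookback table linking the two stays inside
the store and is never exported. `export_cohort()` writes a compressed
archive (CSV table, manifest with schema version and column registry,
checksums) in which all timestamps are shifted by a per-patient
deterministic offset of up to ±182 days — intervals within a patient, and
time of day, are preserved, so longitudinal analyses survive while absolute
dates do not. Archives from different institutions merge with disjoint UID
namespaces; identical re-imports deduplicate, genuine conflicts raise an
error naming the offending keys, and extensible columns registered with
different units are suffixed per institution with a warning rather than
silently pooled.

## Problem sizes and runtime

The test-suite problem sizes are desk-scale by design: 1–3 patients and
1–12 fractions per course (a course of *n* fractions is 2 + 3·*n*
documents at one revision per fraction), 50 seeded courses for
delivered-plan recovery, and 100–1000 random curves for the DVH property
suites. The entire suite runs in about a minute on one CPU; clinical-scale
cohorts differ only in patient count, since every step is per-patient.

## Limitations and open decisions

* Checks carry no contour geometry, so spatial overlap measures (Dice,
  Hausdorff) are out of scope; anatomy tracking is limited to volumes and
  centroid shifts.
* Roles are inferred from ROI names and per-site target dose levels;
  unnamed conventions (e.g. a bare "PTV") fall back to alphabetical
  tie-breaking with a warning.
* The delivered-plan rule trusts log-file linkage entirely; a fraction
  without a log-file check is reported as planned-but-not-treated rather
  than guessed.
* Timestamps are compared lexicographically as ISO-8601 strings; sources
  emitting heterogeneous time zones would need normalization upstream.
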