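# Plan-check JSON dialect

The vendor's raw-data dialect is proprietary, so this repository defines its
own dialect carrying the documented content. Field names are descriptive;
`planName_str` is kept verbatim as the plan-name key.

## Check document (`GET /checks/{check_id}`)

```json
{
  "check_id": "chk-001-0002",
  "patient_id": "FIX-PAT001",
  "check_kind": "pretreatment",            // or "logfile"
  "planName_str": "IM101/SCH0101",
  "timestamp": "2024-01-08T08:00:00",      // ISO-8601, lexicographic == chronological
  "site": "pelvis",
  "dose_unit": "Gy",                       // "cGy" inputs are converted on read
  "prescription_cgy": 250,                 // per-fraction prescription
  "linked_check_id": "chk-001-0002",       // logfile checks only: the delivered
                                           // plan's pre-treatment check id
  "structures": [
    {"name": "Bladder", "volume_cm3": 181.2,
     "density_override_g_cm3": 1.0,        // optional
     "centroid_cm": [0.1, 2.3, -9.8]}      // patient-based cm, right-handed
  ],
  "beams": [
    {"isocenter_cm": [0.0, 2.0, -10.0], "n_control_points": 20,
     "gantry_angles_deg": 0.0, "collimator_angle_deg": 5.0, "mu": 95.2}
  ],
  "dvh": {
    "tpms":      {"Bladder": {"dose_gy": [...], "volume_pct": [...]}},
    "secondary": {"Bladder": {"dose_gy": [...], "volume_pct": [...]}}
  }
}
```

DVH point lists are truncated: the flat 100% head and 0% tail are omitted, so
every listed volume is strictly inside (0, 100), sorted by increasing dose.
Log-file checks carry no structures/beams/DVH — only the link that marks the
referenced pre-treatment plan as delivered.

## Index (`index.json`, file-backed mode; also drives the HTTP endpoint)

```json
{
  "token": "fixture-token",
  "patients": {
    "FIX-PAT001": [
      {"check_id": "...", "patient_id": "...", "plan_name": "...",
       "check_kind": "pretreatment", "timestamp": "...",
       "linked_check_id": "..."}           // logfile summaries only
    ]
  }
}
```

Ground truth (`ground_truth.json`) sits next to the index but is never served
through the client routes.

## HTTP routes

- `POST /auth` with body `{"token": "..."}` → `{"session_id": "..."}`, 401 on
  a wrong token. All other routes require the `X-Session` header.
- `GET /patients/{id}/checks` → array of summaries (empty for unknown ids).
- `GET /checks/{check_id}` → full document, 404 when unknown.
- `GET /ping` → liveness probe, unauthenticated.
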