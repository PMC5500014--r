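# Session file formats

All on-disk coordinates and radii are in **millimetres** (flagged by the
`units` field); the package converts to metres on read. Target ids are
0-based (0–14); id 15 denotes the start position.

## JSON lines (`write_session(..., format = "jsonl")`)

Line 1 — header object:

```json
{"schema": "seqforage-session", "schema_version": 1, "units": "mm",
 "effector": "hand", "constrained": false, "agent_kind": "model", "seed": 1,
 "movement_model": {"effector": "hand",
   "slope": {"5": 1, "8": 1, "11": 1},
   "intercept": {"5": 0.2, "8": 0.2, "11": 0.2},
   "sigma": {"5": 0, "8": 0, "11": 0}}}
```

Movement-model coefficients are keyed by radius tier in mm; slopes are s/m
and intercepts seconds (these are not rescaled by the units flag).

Lines 2..N — one trial per line:

```json
{"trial_id": 1, "condition": "size", "start_x": 0, "start_y": 0,
 "targets": [{"id": 0, "x": -120.3, "y": 63.1, "radius": 8, "value": 12}, ...],
 "harvests": [{"trial_id": 1, "harvest_index": 1, "chosen": 7,
               "origin": 15, "time": 0.31}, ...]}
```

Exactly 15 targets per trial; `harvests` is ordered by `harvest_index`
(1-based) and `origin` is the previous harvest's target id (15 = start).

## CSV pair (`write_session(stem, format = "csv-pair")`)

* `<stem>_displays.csv`: `trial_id, condition, units, target_id, x, y,
  radius, value` — 15 rows per trial.
* `<stem>_harvests.csv`: `trial_id, harvest_index, chosen, origin, time`.

The `units` column ("mm" or "m") drives the coordinate conversion on read.
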