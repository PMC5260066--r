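---
title: "Tracking MRS processing provenance with spectratrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking MRS processing provenance with spectratrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectratrack)
```

## The problem

Metabolite quantitation from in-vivo magnetic resonance spectroscopy (MRS)
is rarely a one-shot computation. A free induction decay (FID) is loaded,
apodized, phased, perhaps zero-filled, and finally fitted against a
metabolite basis set — and because the fit is sensitive to the
preprocessing and to prior-knowledge files, analysts iterate: many trials,
many parameter files, many result files. Months later the question "which
exact steps, parameters and files produced this result?" is usually
unanswerable from the file system alone.

spectratrack answers it by recording every operation in an append-only
relational store and by identifying every file by the SHA-256 hash of its
content rather than by its path. Content addressing means a file that has
been renamed, copied or moved is still recognized as *the same data*, and
a result can always be traced to the exact bytes of the basis set and
options it was computed from.

## The store model

A store is one directory: a SQLite database plus two managed
subdirectories, `param_files/` and `results/`, into which every parameter
and result file is copied under its own content hash as file name. The
database has nine tables:

* five history tables — `ACTIONS` (one row per operation: id, timestamp,
  macro key), `PARAMS` (the operation's parameters, each with a mandatory
  description and, for file parameters, the file's hash), `RESULTS`
  (quantitation outputs; the hash is always recorded), `FILES` (one row
  per distinct data-file content: path at registration, hash, and a
  lineage pointer), and `FILES_ACTIONS` (the N–1 link between operations
  and the files they touched, whose auto-incremented id defines history
  order);
* two comment tables — `ACTIONS_comment` and `RESULTS_comment`;
* two macro tables — `MACRO` (name, comment) and `MACRO_contents`
  (ordered references to past actions).

Three conventions are worth spelling out.

**The lineage pointer.** When a processed file is saved, its `FILES` row
stores the id of the file it was derived from in the `child` column; a
freshly loaded file stores the sentinel `-1`. Walking these pointers from
any file terminates at a root ancestor, and `history_with_parents()`
concatenates the per-ancestor histories root-first. We keep the literal
`-1` sentinel (rather than SQL `NULL`) so the default is directly
observable in the table.

**Deduplication wins over paths.** Loading bytes the store already knows
returns the existing id and does not update the recorded path; the path
column may therefore go stale, deliberately — identity is the hash. The
same rule applies when a save produces bytes that are already registered:
the existing record is returned rather than violating hash uniqueness.
Every load is still an auditable event: a `LOAD_FILE` action is appended
even for known content.

**Append-only.** No public operation deletes or edits history. Two
consequences: macro "modification" is implemented as replay-time parameter
overrides that are recorded as *new* actions, and approval of an action is
stored as appended status rows in `ACTIONS_comment` with latest-wins
semantics (status rows carry empty comment text; user comments must be
non-empty, so the two can never be confused).

## Sessions, rendering and bundles

The "open files" registry is in-memory only and defines the session
boundary: `session_actions()` in data mode lists everything recorded since
the file's id last entered the registry, including the triggering
`LOAD_FILE` or `SAVE` event. In result mode a result hash is resolved to
the action that produced it and the file's history is truncated at, and
including, that quantitation.

Histories render to a deterministic line-oriented batch dialect
(`render_batch()` / `parse_batch()`): a header, `ACTION <key> <time>`
lines, `PARAM <description> = <value>` lines with a ` HASH <hex>` suffix
for file parameters, and `RESULT <name> HASH <hex>` lines. The parser
splits parameter lines on the first `" = "`, so descriptions must not
contain that separator (`param_spec()` enforces this). Rendering the same
items twice is byte-identical; rendering two *runs* of the same pipeline
is identical only up to the recorded wall-clock timestamps and any
absolute paths, which is why bundle determinism is stated over content
files, not over the rendered history.

`export_result_bundle()` packs everything needed to reproduce a
quantitation into one zip: the root ancestor's data file, the truncated
history as `processing.batch`, every file parameter (taken from managed
storage, i.e. the exact original bytes), the result file, and a
`MANIFEST.txt` of name→hash→role. Name collisions between members are
resolved by prefixing the first eight hash characters. `verify_store()`
closes the loop by re-hashing every managed file and checking every hash
referenced from `PARAMS`/`RESULTS` against disk.

## Macros and replay

A macro stores ordered *references* to past actions, never copies, so it
can always be traced back to its origin, and deleting history out from
under it is impossible. Replay resolves each action's key against a plugin
registry, binds the recorded parameter values positionally (file
parameters prefer the managed copy over the recorded path), applies any
overrides, executes, and re-records each step through the same
`record_action()` path as live processing. The bookkeeping keys
`LOAD_FILE` and `SAVE` are reserved: they cannot name plugins and cannot
be placed in macros.

## The toy pipeline

The synthetic layer exists so every tracking feature can be exercised
end-to-end without scanner data. It emulates the *shape* of an MRS
workflow, not its physics:

* `generate_fid()` samples $s(t_k) = \sum_m a_m e^{(2\pi i f_m - d_m)
  t_k} + \varepsilon_k$ with $t_k = k\,\Delta t$ ($\Delta t$ in ms,
  converted to seconds for the frequency math) and i.i.d. complex Gaussian
  noise of standard deviation `noise_sd` per component.
* The operators are the standard deterministic transforms: zero-filling,
  exponential apodization by $e^{-\pi\,\mathrm{lb}\,t}$, zero-order
  phasing by $e^{i\varphi}$, and scaling.
* `mock_quantitation()` is a transparent linear least-squares fit of the
  FID on the basis signals (complex QR solve; the real parts of the
  amplitudes are reported), after applying the zero-order phase from the
  options file. A design whose smallest singular value falls below
  $10^{-10}$ times the largest is refused as singular. To the tracker a
  quantitation is a black box that consumes two parameter files and emits
  one result file — which is exactly what the mock reproduces; it is not
  a substitute for a real fitter with lineshape models, baselines and
  constraints.

The canonical FID text format pins number rendering to 17 significant
digits in lowercase scientific notation with `\n` endings, so serializing
the same dataset always produces the same bytes and hence the same hash —
the property all the reproducibility checks rest on. Replay determinism
is a statement about these deterministic operators on identical input
bytes on one platform; it is not a claim about real quantitation
algorithms with stochastic optimizers.

### Demo-session conditions

`run_demo_session()` fixes the conditions used throughout the tests and
the acceptance script: a three-metabolite basis mimicking a short-echo
proton brain spectrum at 3 T (NAA, Cr, Cho at −331.5, −205.8 and
−184.9 Hz from the water carrier at 123.25 MHz — their usual chemical
shifts — with Lorentzian dampings of 8, 7 and 6 Hz), amplitudes
2.0 : 1.0 : 0.5, 512 complex points at 0.4 ms dwell (2.5 kHz bandwidth),
and complex noise of standard deviation 0.01 (about 0.3 % of the initial
signal magnitude). These are ordinary values for the setting rather than
tuned ones; problem sizes (512 points, chains of depth 10) keep every
check well under a second while still exercising non-trivial structure.
The demo quantifies the apodized, phased data against the raw basis, so
its amplitude estimates are deliberately biased by the extra line
broadening — the demo demonstrates *tracking*, while the estimator's
accuracy is checked separately on unprocessed FIDs, where the noiseless
fit recovers the generating amplitudes to machine precision.

## Degenerate inputs and numerical choices

* Hashes are stored and compared lowercase; lookups normalize case and
  reject malformed strings.
* Timestamps are ISO 8601 UTC at second precision; equal-second ties are
  ordered by the auto-incremented ids, which are the authoritative order
  everywhere.
* `record_action()` validates everything (targets open, key legal, files
  readable) before writing, ingests managed copies first, and wraps the
  row inserts in one transaction — a failed recording changes no row
  counts. Managed copies left behind by a failure are harmless: they are
  content-addressed and identical to what a successful recording would
  have stored.
* Empty histories cannot be rendered; empty macros cannot be created;
  a save against a file that is not open is refused.

## Known limitations

* Single-writer, per-study stores; no server mode, no encryption, and no
  migration of foreign schemas.
* The recorded `path` column is informational and may go stale by design.
* The rendered batch text embeds timestamps and absolute paths, so it is
  reproducible across runs only up to those fields.
* The toy format readers parse only this package's canonical formats; real
  scanner formats (DICOM MRS, RDA, SDAT) are out of scope.
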