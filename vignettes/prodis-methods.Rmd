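---
title: "Managing proteomics experiments with prodis: data model, provenance and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing proteomics experiments with prodis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodis)
```

## The problem

A bottom-up proteomics study is a chain of bench and instrument steps:
protein extraction, separation by liquid chromatography (LC) or
two-dimensional gel electrophoresis (2D-PAGE), mass-spectrometric (MS)
acquisition of the separated material, and database search for
identification. Each step produces a file in its own dialect — LC peak
tables, gel spot-quantitation tables, m/z peak lists, search-engine CSV
exports — and the scientific questions that matter later ("which sample
produced this m/z list?", "which gel spot sits in well B7 of the MALDI
plate?") cut *across* those steps. prodis is a desk-scale data-management
engine for exactly this situation: a multi-project store in which every
experiment is a first-class record, experiments are cross-linked into a
provenance graph, instrument files are parsed into normalized tables, and
reports embed the resulting *experiment tree*.

## Data model

The store is an embedded single-file SQLite database plus a sibling
`files/` directory. Structured content (projects, users, samples,
protocols, experiments, conditions, provenance edges, plate layouts,
identifications, the audit trail) lives in the database; bulk instrument
files (gel images, chromatograms, peak lists) live outside it, each
recorded with its byte size and SHA-256 checksum so the link can always be
re-verified. The experiment is the central entity. Every experiment
receives an **internal id** from a store-global sequence — strictly
increasing over creation order and never reused — so records can be
cross-linked unambiguously across projects and years.

Four experiment types exist. Three are instrument types and carry a typed
condition set:

| type | conditions | result files parsed |
|------|------------|---------------------|
| `LC` | instrument, column, solvents, gradient, flow rate (mL/min), temperature (°C), detection wavelength (nm) | CSV peak tables (retention time, height, area) |
| `GEL2D` | first-dimension pI range, focusing Vh, gel %T, second-dimension voltage and run time, stain | tab-delimited spot tables (position, intensity, volume, %Vol, pI, MW) |
| `MS` | instrument, ionization, analyzer mode, MALDI matrix, m/z range (Th) | peak lists in pkl, MGF, mzML, mzXML, mzData |

The fourth, `PREP`, carries sample and protocol only: it exists so that a
chain can start at a bench step such as a protein extraction, which is
where the sample information lives. Constructors (`lc_conditions()`,
`gel_conditions()`, `ms_conditions()`) validate the physical invariants
(positive flow rate, `strip_pi_low < strip_pi_high`, `mz_low < mz_high`),
and `create_experiment()` rejects a conditions variant that does not match
the declared type.

The schema here (17 tables) is normalized around the types above; it is
not a table-for-table reconstruction of any particular laboratory
system's schema, which matters less than preserving the contract: ACID
single-writer semantics and referential integrity at desk scale.

## Provenance: a DAG rendered as a tree

`link_experiments(store, parent, child)` records that the products of one
experiment were used in another. Links form a **directed acyclic graph**,
not a strict tree: one extraction can feed several gels, and one MS run
can pool spots from several gels, so multiple parents are allowed. Every
link is checked eagerly with a reachability query and rejected if it would
close a cycle; self-links, duplicate edges and cross-project links are
rejected too (the latter to keep the access-control model coherent). A
child dated before its parent only warns — instrument clock errors are
common and the temporal hint is advisory.

Queries are the obvious graph operations: `parents()`/`children()` (direct
neighbours), `ancestors()`/`descendants()` (transitive closure),
`trace_origin()` (walk up to every parentless ancestor and return its
samples — the first experiment in a chain is where sample information is
recorded), and `build_tree()`, a depth-first expansion following child
edges with children ordered by internal id. When the sub-graph below a
root shares nodes (pooling), the shared node is repeated under each parent
— tree semantics, which is what a report reader expects. Acyclicity bounds
the expansion depth, so rendering always terminates.

The demonstration store (`make_demo_store()`) encodes the worked example
the package is tested against: extraction experiment 1 feeds experiments
100, 146 and 174, whose products feed 101 and 148. Which of the two gels
produced which MS run is not determined by the example itself; the
fixture fixes 100→101 and 146→148, an explicitly arbitrary choice. The literal ids
are produced through an id-override hook on `create_experiment()` used
only by fixture builders; the experiments are created in ascending id
order so the monotone-assignment invariant holds even there.

## Instrument-file dialects

All five peak-list dialects normalize into one container: spectra with
optional precursor m/z and charge, and peaks as `(mz, intensity)` pairs
sorted by m/z. Only peak-list content and instrument metadata are
extracted from the XML dialects; chromatogram arrays and vendor extensions
are ignored, because the store keeps m/z *lists*, not raw runs.

Dialect decisions, declared normative for this artifact where the
ecosystem is genuinely ambiguous:

* **pkl** — blank-line-separated blocks; header `precursor_mz intensity
  charge`, then `mz intensity` lines. (Vendor pkl flavours differ in
  whitespace details; this layout is the one the generators emit and the
  parser is tested against.)
* **MGF** — `BEGIN IONS`/`END IONS` with `TITLE`, `PEPMASS`, `CHARGE`.
  Writing is bit-exact by rule: m/z with 4 decimal places, intensity with
  1, charge as `n+`/`n-`. Unknown header lines are preserved as instrument
  metadata rather than dropped.
* **mzML** — separate little-endian base64 float arrays, 32- or 64-bit,
  identified by their controlled-vocabulary accessions. The writer's
  output is cross-checked in the test suite against an independent reader
  (mzR/proteowizard).
* **mzXML** — interleaved m/z–intensity pairs in network (big-endian)
  byte order, per that standard.
* **mzData** — separate arrays with explicit `precision` and `endian`
  attributes.
* Compressed binary arrays are out of scope and raise an
  unsupported-feature error naming the feature — a deliberate boundary
  that keeps the dialect surface fully testable without codec conformance.
* **Spot tables** are modeled on Image-Master-style tab-delimited exports
  with required columns Spot/X/Y/Intensity/Volume/Area and optional
  %Vol/pI/MW, matched case-insensitively for resilience; the original
  system names the program but not the column layout, so this column set
  is this artifact's declared dialect.
* **Search-engine exports**: Mascot ion scores are taken as-is; X!Tandem
  and OMSSA expectation values are transformed to `-log10(E)` so every
  engine shares a "larger is better" score convention.

A float64 value survives text formatting and binary encoding exactly, so
round trips are tested as *identities*; 32-bit binary encodings are tested
as identities up to one float32 rounding, the best any parser can do.

## Access control and audit

Users authenticate by login/password (stored as salted, iterated SHA-256
hashes; authentication failure is deliberately opaque about which field
was wrong). Permissions are per project with three totally ordered roles:

* **GUEST** — sees only a stub (id, type, title) of experiments, and only
  in projects flagged guest-visible. Any user, member or not, gets this
  stub view of a guest-visible project; the demo store ships the
  conventional `guest`/`guest` account.
* **RESEARCHER** — full view of all experiments of their projects,
  including teammates'; edits only experiments they performed.
* **COORDINATOR** — full view and edit of everything in their projects,
  and sole access to the project's audit trail.

Non-members of a non-guest-visible project see nothing at all. Every rule
is monotone in the role order, a property the test suite checks cell by
cell. Each mutating operation (create, link, attach, ingest) appends
exactly one immutable audit entry; denied views are audited too. A store
handle without a bound actor runs in *local mode* — full rights, actions
audited as `local` — which is the natural embedding for library use; the
CLI requires credentials unless `--local` is passed explicitly.

One known asymmetry, chosen deliberately: coordinators read only their own
projects' audit logs; there is no cross-project superuser.

## Plate mapping

A MALDI target plate (any geometry up to 26 rows; 96- and 384-well are the
common cases) binds to an MS experiment. Each well holds at most one
source — a gel spot, a sample, or a calibrant — while one spot may occupy
several wells (technical replicates), so the well→source direction is a
function and the inverse (`find_spot()`) is a one-to-many image, returned
in row-major well order. A gel-spot assignment is validated against the
gel experiment's stored spot table and automatically creates the
provenance edge gel → MS run if absent, which is exactly what makes
"which spot produced this m/z list?" answerable later. Layouts round-trip
through a four-column CSV.

## Minimum-information checking and reports

The published system claims coverage of minimum-information reporting
guidelines without listing fields, so the required-field lists here are an
explicit, versioned concretization, shipped as editable JSON data
(`inst/extdata/miape_requirements.json`) rather than code: every type
requires performer, date, samples and protocol; MS adds instrument,
ionization, analyzer mode; GEL2D adds the pI range, gel concentration and
stain; LC adds instrument, column and first solvent. `miape_check()`
reports missing paths in requirement order; populating a field can only
shrink the list (a property tested over random partial records).

Reports render in plain text, print-ready well-formed HTML, and XML, and
are byte-deterministic for a given store. The tree block renders one tree
per parentless ancestor of the reported experiment (sorted by root id)
whenever the experiment has any edge. PDF output was consciously replaced
by print-ready HTML — PDF generation is presentation plumbing, not data
management. `export_record()` emits a re-importable `prodisExperiment` XML
document whose element order is fixed (requirement-field order), making
export → import → export byte-idempotent. Attachment *bytes* are not
transported, only name, kind, size and checksum; imported references are
flagged `external` and excluded from checksum re-verification, since there
are no local bytes to verify.

## Search-engine gateway

`prepare_submission()` merges an MS experiment's peak-list attachments
into one MGF (written with the bit-exact rules above), stores it in the
managed file store with a JSON manifest (engine, free-form parameter map,
input checksum, timestamp), and never invokes an engine: the original
system's submission scripts were environment-specific, so the contract
here deliberately ends at files out / records in. A `runner` hook is
declared for callers that drive an engine themselves; the shipped default
is a no-op. `ingest_result()` accepts an engine CSV export and attaches
normalized identification records; a missing or mismatched manifest warns
rather than fails, because result files are evidence regardless of how the
search was launched.

## Synthetic data: what it emulates and what it does not

Every input dialect has a seeded generator that returns both the rendered
file and the ground truth it came from, giving the parser tests an exact
oracle. A single integer seed drives a named pseudorandom stream per
generator, so adding a generator never perturbs another's output, and the
same seed always reproduces the same bytes. Values are structural, not
physico-chemical: m/z uniform in [100, 2000] Th rounded to 4 decimals,
intensities uniform in [1, 10^5] rounded to 1 decimal, precursors in
[400, 1200] Th with charge 1–3, spot %Vol scaled to sum to 90, LC
retention times as sorted cumulative sums. There are no isotope patterns,
no noise model, no correlation between spot volume and MS intensity.
Passing tests therefore demonstrate that parsing, storage, provenance and
permissions are correct over the full structural space of these dialects —
not that the package handles every vendor's formatting quirks, encodings
beyond the declared subsets, or malformed real-world exports beyond the
error paths tested.

## Numerical and scale choices

* Text writers format numbers with fixed decimal places and no scientific
  notation, so generator output is byte-stable across platforms.
* SQLite runs with referential integrity on and durability relaxed
  (`synchronous = OFF`, in-memory journal): the store is single-writer and
  rebuildable from the instrument files, so insert speed is worth more
  than per-statement fsync. There is no schema migration tooling and no
  concurrent multi-writer support.
* Graph property checks run on 200 random DAGs with 2–50 nodes (edge
  probability 0.15) against a brute-force transitive-closure oracle, plus
  600 random edge-stream decisions against a brute-force cycle detector;
  dialect round trips on 100 seeded spectrum sets across all five formats
  and both binary precisions; minimum-information monotonicity on 100
  random partial records; plate inversion on 50 random geometries. These
  sizes exercise every code path (empty spectra, isolated nodes,
  single-row tables are covered by dedicated degenerate-input tests) while
  keeping the whole suite in a few minutes on one core.
* Password hashing iterates SHA-256 5 000 times over a 16-byte random
  salt. No password-strength policy is imposed.

## Known limitations

On-line LC-MS acquisition setups are unsupported, as in the original
system. Vendor raw formats, mzIdentML/mzTab, compressed binary arrays,
spectral processing (centroiding, deisotoping), decoy/FDR handling and
protein inference are all out of scope. Edge deletion and re-parenting
have no UI semantics and no history. Whether an experiment may join
several projects' trees was left open by the original description; it is
forbidden here, which keeps permissions simple at the cost of modeling
genuinely shared material.
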