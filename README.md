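# prodis

Desk-scale data management for proteomics laboratories working with
liquid chromatography (LC), two-dimensional gel electrophoresis
(2D-PAGE) and mass spectrometry (MS).

A bottom-up proteomics study is a chain of experiments — protein
extraction, separations, MS acquisition, database search — and the
questions that matter later cut across the chain: *which sample
originated this m/z list? which gel spot was spotted into well B7 of
the MALDI target plate? under which conditions was the gel that fed
this identification run?* prodis answers them by making the
**experiment** the central entity of an embedded relational store
(SQLite plus a checksummed managed file directory), giving every
experiment a globally unique internal id, and cross-linking ids into a
provenance **DAG** that reports render as an *experiment tree*.

For researchers and facility managers it provides:

* typed experiments (`PREP`, `LC`, `GEL2D`, `MS`) with validated
  instrument condition sets;
* parsers normalizing the field's peak-list dialects (pkl, MGF, mzML,
  mzXML, mzData) into one container, plus 2D-gel spot tables, LC peak
  tables and Mascot/X!Tandem/OMSSA result exports (expectation values
  mapped to `-log10 E` so all engines score "larger is better");
* provenance queries (`parents()`, `children()`, `ancestors()`,
  `descendants()`, `trace_origin()`, `build_tree()`) with eager cycle
  rejection;
* MALDI plate mapping correlating target wells with gel spots, with
  `find_spot()` as the exact inverse;
* minimum-information (MIAPE-style) completeness checking from an
  editable requirement list;
* per-project role-based access control (guest < researcher <
  coordinator) with salted-hash logins and a full audit trail;
* deterministic reports (text / print-ready HTML / re-importable XML)
  and a search-submission gateway that emits bit-exact MGF plus a JSON
  manifest;
* seeded synthetic generators for every input dialect, including a demo
  store reproducing the package's worked example.

## Worked example

```r
library(prodis)

dir <- tempfile(); dir.create(dir)
st <- make_demo_store(dir, seed = 1)

children(st, 1)
#> [1] 100 146 174
descendants(st, 1)
#> [1] 100 101 146 148 174

build_tree(st, 1)
#> 1 [PREP] Protein extraction
#>   100 [GEL2D] 2D gel, pH 4-7 replicate A
#>     101 [MS] MALDI-TOF of gel A spots
#>   146 [GEL2D] 2D gel, pH 4-7 replicate B
#>     148 [MS] MALDI-TOF of gel B spots
#>   174 [LC] Cation exchange fractionation

trace_origin(st, 148)
#> # A tibble: 1 × 5
#>    root root_title         sample_id sample_name                organism
#>   <int> <chr>                  <int> <chr>                      <chr>
#> 1     1 Protein extraction         1 adult worm soluble extract Schistosoma mansoni
```

The demo store is a protein extraction (internal id 1) feeding two 2D
gels (100, 146) and an LC run (174); the gels' spots feed two MALDI-TOF
runs (101, 148). `build_tree(st, 1)` prints the provenance tree embedded
in experiment reports: one line per experiment, indented by depth, so
the three separations sit at depth 1 and the two MS runs at depth 2.
`trace_origin(148)` walks the graph up to the parentless root and
returns the sample the whole chain started from — here the *S. mansoni*
soluble extract.

Permissions follow the store's role model; the demo ships the
conventional read-only account:

```r
guest <- prodis_login(st, "guest", "guest")
get_experiment(guest, 148)
#> <experiment 148> [MS] MALDI-TOF of gel B spots (restricted view)
```

The same functionality is available from a shell via the thin
`inst/cli/prodis` script (`init`, `experiment add/view`, `link`, `tree`,
`import`, `plate new/assign/export`, `miape-check`, `report`, `submit`,
`ingest`, `demo`), with stable exit codes: 1 usage, 2 permission,
3 data/format, 4 not found.

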