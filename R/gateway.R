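#' Prepare a search-engine submission
#'
#' Collects the normalized spectra from every peak-list attachment of an
#' MS experiment, writes them as a single MGF into the managed file
#' store, and records a submission manifest (engine, free-form parameter
#' map, input-file checksum, creation time) as JSON alongside the MGF.
#' No engine is ever invoked: the contract ends at a bit-exact MGF plus
#' manifest out, and normalized identification records back in via
#' [ingest_result()]. A pluggable `runner` hook is accepted for callers
#' that drive an engine themselves; the shipped default is a no-op.
#'
#' @param store A `prodis_store` handle.
#' @param ms_experiment Internal id of an MS experiment with at least
#'   one `peak_list` attachment.
#' @param engine One of `"mascot"`, `"xtandem"`, `"omssa"`.
#' @param params Named list of engine parameters (database, enzyme,
#'   tolerances, ...), stored verbatim.
#' @param runner Optional function called as `runner(manifest, mgf_path)`
#'   after the manifest is written.
#' @return One-row tibble describing the manifest.
#' @export
prepare_submission <- function(store, ms_experiment, engine, params = list(),
                               runner = submission_runner_noop) {
  check_store(store)
  ms_experiment <- check_known(store, ms_experiment)
  if (!engine %in% c("mascot", "xtandem", "omssa")) {
    stop_usage(sprintf("unknown engine tag: %s", engine))
  }
  e <- db_get(store, "SELECT type FROM experiments WHERE id = ?", ms_experiment)
  if (e$type != "MS") {
    stop_usage(sprintf("submissions require an MS experiment; %d is %s",
                       ms_experiment, e$type))
  }
  enforce_edit(store, ms_experiment)
  att <- db_get(store,
    "SELECT * FROM files WHERE experiment_id = ? AND kind = 'peak_list' AND external = 0
     ORDER BY file_id", ms_experiment)
  if (!nrow(att)) {
    stop_usage(sprintf("experiment %d has no peak-list attachment to submit", ms_experiment))
  }
  lists <- purrr::map(seq_len(nrow(att)), function(i) {
    read_peaklist(attachment_path(store, att[i, ]))
  })
  spectra <- bind_rows(purrr::map(lists, function(x) x$spectra))
  merged <- new_mzlist("mgf", spectra)
  mgf_text <- write_mgf(merged)

  manifest_id <- next_id(store, "manifests", "manifest_id")
  tmp <- file.path(tempdir(), sprintf("submission_%d_%s.mgf", manifest_id, engine))
  writeLines(mgf_text, tmp, sep = "")
  ref <- attach_file(store, ms_experiment, tmp, kind = "other")
  unlink(tmp)
  created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  db_exec(store,
    "INSERT INTO manifests (manifest_id, ms_experiment, engine, params, input_file, created)
     VALUES (?, ?, ?, ?, ?, ?)",
    manifest_id, ms_experiment, engine,
    as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)),
    ref$file_id, created)
  manifest <- tibble(manifest_id = manifest_id, ms_experiment = ms_experiment,
                     engine = engine, params = list(params),
                     input_file = ref$file_id, checksum = ref$checksum,
                     created = created)
  # Serialized manifest lives next to the MGF in the managed store.
  manifest_path <- file.path(dirname(store$path), "files", ms_experiment,
                             sprintf("manifest_%d.json", manifest_id))
  jsonlite::write_json(list(manifest_id = manifest_id, ms_experiment = ms_experiment,
                            engine = engine, params = params,
                            input_file = ref$file_id, input_checksum = ref$checksum,
                            created = created),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(runner)) runner(manifest, attachment_path(store, ref))
  manifest
}

#' @rdname prepare_submission
#' @param manifest,mgf_path Arguments passed to a runner hook.
#' @export
submission_runner_noop <- function(manifest, mgf_path) invisible(NULL)

#' Ingest a search-engine result file
#'
#' Parses an engine's CSV export with [parse_ident_table()] and attaches
#' the normalized identification records to the MS experiment, where the
#' report module lists them. Ingesting without a prior manifest, or for
#' a different engine than the manifest's, warns but proceeds — result
#' files are evidence regardless of how the search was launched.
#'
#' @inheritParams prepare_submission
#' @param text The result file content as a character scalar.
#' @return Tibble of the attached identification records.
#' @export
ingest_result <- function(store, ms_experiment, engine, text) {
  check_store(store)
  ms_experiment <- check_known(store, ms_experiment)
  enforce_edit(store, ms_experiment)
  recs <- parse_ident_table(text, engine)
  man <- db_get(store, "SELECT engine FROM manifests WHERE ms_experiment = ?", ms_experiment)
  if (!nrow(man)) {
    warn(sprintf("experiment %d has no submission manifest; ingesting anyway", ms_experiment))
  } else if (!engine %in% man$engine) {
    warn(sprintf("manifest engine (%s) differs from ingested engine (%s)",
                 paste(unique(man$engine), collapse = "/"), engine))
  }
  for (i in seq_len(nrow(recs))) {
    db_exec(store,
      "INSERT INTO identifications (experiment_id, engine, spectrum_ref, accession,
         description, score) VALUES (?, ?, ?, ?, ?, ?)",
      ms_experiment, recs$engine[i], recs$spectrum_ref[i], recs$accession[i],
      recs$description[i], recs$score[i])
  }
  record_action(store, actor_or_local(store), "update", ms_experiment)
  recs
}
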