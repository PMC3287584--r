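#' Create a project
#'
#' A project groups experiments, members and publications. The
#' coordinator must be a registered user and is automatically added as a
#' member with the COORDINATOR role. Project names are unique per store.
#'
#' @param store A `prodis_store` handle.
#' @param name Unique, nonempty project name.
#' @param description Free-text description.
#' @param coordinator Login of the coordinating user.
#' @param guest_visible Whether guests may see experiment stubs
#'   (id/type/title) of this project.
#' @param publications Character vector of free-text citations.
#' @return One-row tibble with the stored project.
#' @export
create_project <- function(store, name, description, coordinator,
                           guest_visible = FALSE, publications = character()) {
  check_store(store)
  check_scalar_chr(name, "project name")
  if (!user_exists(store, coordinator)) {
    stop_not_found(sprintf("unknown coordinator: %s", coordinator))
  }
  if (nrow(db_get(store, "SELECT project_id FROM projects WHERE name = ?", name))) {
    stop_usage(sprintf("duplicate project name: %s", name))
  }
  pid <- next_id(store, "projects", "project_id")
  db_exec(store,
    "INSERT INTO projects (project_id, name, description, coordinator, guest_visible)
     VALUES (?, ?, ?, ?, ?)",
    pid, name, description, coordinator, as.integer(guest_visible))
  for (cite in publications) {
    db_exec(store, "INSERT INTO publications (project_id, citation) VALUES (?, ?)", pid, cite)
  }
  db_exec(store,
    "INSERT INTO memberships (user, project_id, role) VALUES (?, ?, 'COORDINATOR')",
    coordinator, pid)
  tibble(project_id = pid, name = name, description = description,
         coordinator = coordinator, guest_visible = guest_visible)
}

project_exists <- function(store, project_id) {
  nrow(db_get(store, "SELECT project_id FROM projects WHERE project_id = ?", project_id)) == 1L
}

#' Register a sample
#'
#' @inheritParams create_project
#' @param organism Source organism, free text.
#' @param origin_experiment Optional internal id of the experiment the
#'   sample came out of (e.g. a fraction collected from an LC run).
#' @export
create_sample <- function(store, name, organism = "", description = "",
                          origin_experiment = NULL) {
  check_store(store)
  check_scalar_chr(name, "sample name")
  if (!is.null(origin_experiment)) {
    origin_experiment <- check_id(origin_experiment, "origin_experiment")
    if (!experiment_exists(store, origin_experiment)) {
      stop_not_found(sprintf("unknown origin experiment: %d", origin_experiment))
    }
  }
  sid <- next_id(store, "samples", "sample_id")
  db_exec(store,
    "INSERT INTO samples (sample_id, name, organism, description, origin_experiment)
     VALUES (?, ?, ?, ?, ?)",
    sid, name, organism, description,
    if (is.null(origin_experiment)) NA_integer_ else origin_experiment)
  tibble(sample_id = sid, name = name, organism = organism)
}

#' Register a protocol
#'
#' @inheritParams create_project
#' @param body Full protocol text.
#' @param applies_to Experiment-type tag the protocol is written for.
#' @export
create_protocol <- function(store, name, body = "", applies_to = "") {
  check_store(store)
  check_scalar_chr(name, "protocol name")
  pid <- next_id(store, "protocols", "protocol_id")
  db_exec(store,
    "INSERT INTO protocols (protocol_id, name, body, applies_to) VALUES (?, ?, ?, ?)",
    pid, name, body, applies_to)
  tibble(protocol_id = pid, name = name, applies_to = applies_to)
}

# ---- condition variants -----------------------------------------------------

experiment_types <- function() c("PREP", "LC", "GEL2D", "MS")

#' Instrument condition variants
#'
#' Exactly three experiment types carry instrument conditions: LC
#' (chromatography), GEL2D (two-dimensional electrophoresis) and MS
#' (mass spectrometry). PREP experiments (e.g. protein extraction) carry
#' sample and protocol only. Each constructor validates the physical
#' invariants of its fields.
#'
#' @param instrument,column,solvent_a,solvent_b,gradient Free-text LC setup.
#' @param flow_rate Flow rate in mL/min (> 0 when present).
#' @param temperature Column temperature in degrees Celsius.
#' @param detection_wavelength Detector wavelength in nm.
#' @return A classed list tagged with its experiment type.
#' @export
lc_conditions <- function(instrument = NULL, column = NULL, solvent_a = NULL,
                          solvent_b = NULL, gradient = NULL, flow_rate = NULL,
                          temperature = NULL, detection_wavelength = NULL) {
  if (!is.null(flow_rate) && (!is.finite(flow_rate) || flow_rate <= 0)) {
    stop_usage("flow_rate must be > 0 mL/min")
  }
  if (!is.null(temperature) && !is.finite(temperature)) {
    stop_usage("temperature must be finite")
  }
  new_conditions("LC", list(
    instrument = instrument, column = column, solvent_a = solvent_a,
    solvent_b = solvent_b, gradient = gradient, flow_rate = flow_rate,
    temperature = temperature, detection_wavelength = detection_wavelength))
}

#' @rdname lc_conditions
#' @param strip_pi_low,strip_pi_high First-dimension IPG strip pI range
#'   (`strip_pi_low < strip_pi_high`).
#' @param focusing_volt_hours Isoelectric focusing in volt-hours.
#' @param gel_percent Second-dimension gel concentration (%T).
#' @param second_dim_voltage Second-dimension voltage (V).
#' @param run_time Second-dimension run time (min).
#' @param stain Staining method.
#' @export
gel_conditions <- function(strip_pi_low = NULL, strip_pi_high = NULL,
                           focusing_volt_hours = NULL, gel_percent = NULL,
                           second_dim_voltage = NULL, run_time = NULL,
                           stain = NULL) {
  if (!is.null(strip_pi_low) && !is.null(strip_pi_high) &&
      !(strip_pi_low < strip_pi_high)) {
    stop_usage("strip_pi_low must be < strip_pi_high")
  }
  new_conditions("GEL2D", list(
    strip_pi_low = strip_pi_low, strip_pi_high = strip_pi_high,
    focusing_volt_hours = focusing_volt_hours, gel_percent = gel_percent,
    second_dim_voltage = second_dim_voltage, run_time = run_time, stain = stain))
}

#' @rdname lc_conditions
#' @param ionization Ion source (e.g. MALDI, ESI).
#' @param analyzer_mode Analyzer and acquisition mode.
#' @param matrix MALDI matrix compound.
#' @param mz_low,mz_high Acquired m/z range in thomson
#'   (`mz_low < mz_high`).
#' @export
ms_conditions <- function(instrument = NULL, ionization = NULL,
                          analyzer_mode = NULL, matrix = NULL,
                          mz_low = NULL, mz_high = NULL) {
  if (!is.null(mz_low) && !is.null(mz_high) && !(mz_low < mz_high)) {
    stop_usage("mz_low must be < mz_high")
  }
  new_conditions("MS", list(
    instrument = instrument, ionization = ionization,
    analyzer_mode = analyzer_mode, matrix = matrix,
    mz_low = mz_low, mz_high = mz_high))
}

new_conditions <- function(type, fields) {
  structure(list(type = type, fields = fields[!vapply(fields, is.null, logical(1))]),
            class = "prodis_conditions")
}

conditions_to_json <- function(cond) {
  if (is.null(cond)) return(NA_character_)
  jsonlite::toJSON(list(type = cond$type, fields = cond$fields),
                   auto_unbox = TRUE, digits = NA)
}

conditions_from_json <- function(json) {
  if (is.na(json) || !nzchar(json)) return(NULL)
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(list(type = x$type, fields = as.list(x$fields)),
            class = "prodis_conditions")
}

# ---- experiments ------------------------------------------------------------

experiment_exists <- function(store, id) {
  nrow(db_get(store, "SELECT id FROM experiments WHERE id = ?", id)) == 1L
}

#' Create an experiment
#'
#' The experiment is the central entity of the store. Each one receives a
#' unique internal id, assigned strictly increasing over creation order
#' and never reused, so experiments can be cross-linked unambiguously
#' across projects and time. The conditions variant must match the
#' declared type: PREP experiments take none, LC/GEL2D/MS take their
#' respective constructor's value.
#'
#' @inheritParams create_project
#' @param project Project id the experiment belongs to.
#' @param type One of `"PREP"`, `"LC"`, `"GEL2D"`, `"MS"`.
#' @param title Experiment title.
#' @param performed_by Login of the performing member.
#' @param date ISO-8601 date string (`YYYY-MM-DD`).
#' @param conditions `NULL` for PREP, otherwise the matching
#'   [lc_conditions()], [gel_conditions()] or [ms_conditions()] object.
#' @param samples Integer vector of sample ids used.
#' @param protocol Optional protocol id.
#' @param notes Free text.
#' @param .id Internal-id override used only by fixture builders that
#'   must reproduce literal published ids; must be unused and larger ids
#'   must not exist if sequential assignment is to stay monotone.
#' @return The stored experiment, as returned by [get_experiment()].
#' @export
create_experiment <- function(store, project, type, title, performed_by, date,
                              conditions = NULL, samples = integer(),
                              protocol = NULL, notes = "", .id = NULL) {
  check_store(store)
  project <- check_id(project, "project")
  if (!project_exists(store, project)) stop_not_found(sprintf("unknown project: %d", project))
  if (!type %in% experiment_types()) stop_usage(sprintf("unknown experiment type: %s", type))
  check_scalar_chr(title, "title")
  check_iso_date(date)
  role <- membership_role(store, performed_by, project)
  if (is.na(role)) {
    stop_usage(sprintf("performer %s is not a member of project %d", performed_by, project))
  }
  if (!is.null(store$actor)) {
    actor_role <- membership_role(store, store$actor, project)
    if (is.na(actor_role) || role_rank(actor_role) < role_rank("RESEARCHER")) {
      stop_permission(sprintf("%s cannot create experiments in project %d",
                              store$actor, project))
    }
  }
  if (type == "PREP") {
    if (!is.null(conditions)) stop_usage("PREP experiments carry no instrument conditions")
  } else {
    if (is.null(conditions) || !inherits(conditions, "prodis_conditions") ||
        conditions$type != type) {
      stop_usage(sprintf("conditions variant does not match experiment type %s", type))
    }
  }
  samples <- vapply(samples, check_id, integer(1), what = "sample id")
  for (s in samples) {
    if (!nrow(db_get(store, "SELECT sample_id FROM samples WHERE sample_id = ?", s))) {
      stop_not_found(sprintf("unknown sample: %d", s))
    }
  }
  if (!is.null(protocol)) {
    protocol <- check_id(protocol, "protocol")
    if (!nrow(db_get(store, "SELECT protocol_id FROM protocols WHERE protocol_id = ?", protocol))) {
      stop_not_found(sprintf("unknown protocol: %d", protocol))
    }
  }
  id <- if (is.null(.id)) next_id(store, "experiments", "id") else check_id(.id, ".id")
  if (!is.null(.id) && experiment_exists(store, id)) {
    stop_usage(sprintf("internal id already assigned: %d", id))
  }
  db_exec(store,
    "INSERT INTO experiments (id, project_id, type, title, performed_by, date,
       protocol_id, conditions, notes) VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?)",
    id, project, type, title, performed_by, date,
    if (is.null(protocol)) NA_integer_ else protocol,
    conditions_to_json(conditions), notes)
  for (s in samples) {
    db_exec(store, "INSERT INTO experiment_samples (experiment_id, sample_id) VALUES (?, ?)",
            id, s)
  }
  record_action(store, actor_or_local(store), "create", id)
  get_experiment_unchecked(store, id)
}

#' Retrieve a full experiment record
#'
#' Returns the complete record: metadata, condition set, sample and
#' protocol references, and all file attachments. Under a bound actor
#' with guest-level access the record is reduced to the id/type/title
#' stub.
#'
#' @inheritParams create_project
#' @param id Experiment internal id (positive integer).
#' @return A `prodis_experiment` list.
#' @export
get_experiment <- function(store, id) {
  check_store(store)
  id <- check_id(id, "experiment id")
  if (!experiment_exists(store, id)) stop_not_found(sprintf("unknown experiment: %d", id))
  scope <- enforce_view(store, id)
  rec <- get_experiment_unchecked(store, id)
  if (identical(scope, "stub")) {
    rec <- structure(list(id = rec$id, type = rec$type, title = rec$title, stub = TRUE),
                     class = "prodis_experiment")
  }
  rec
}

get_experiment_unchecked <- function(store, id) {
  e <- db_get(store, "SELECT * FROM experiments WHERE id = ?", id)
  smp <- db_get(store,
    "SELECT s.sample_id, s.name, s.organism, s.description, s.origin_experiment
     FROM experiment_samples es JOIN samples s ON es.sample_id = s.sample_id
     WHERE es.experiment_id = ? ORDER BY s.sample_id", id)
  prot <- if (!is.na(e$protocol_id)) {
    db_get(store, "SELECT * FROM protocols WHERE protocol_id = ?", e$protocol_id)
  } else NULL
  att <- db_get(store,
    "SELECT file_id, relative_path, original_name, byte_size, checksum, kind, external
     FROM files WHERE experiment_id = ? ORDER BY file_id", id)
  idents <- db_get(store,
    "SELECT engine, spectrum_ref, accession, description, score
     FROM identifications WHERE experiment_id = ? ORDER BY rowid", id)
  structure(list(
    id = as.integer(e$id), project_id = as.integer(e$project_id), type = e$type,
    title = e$title, performed_by = e$performed_by, date = e$date,
    protocol = prot, samples = smp,
    conditions = conditions_from_json(e$conditions),
    attachments = att, identifications = idents,
    notes = e$notes, stub = FALSE
  ), class = "prodis_experiment")
}

#' @export
print.prodis_experiment <- function(x, ...) {
  if (isTRUE(x$stub)) {
    cat(sprintf("<experiment %d> [%s] %s (restricted view)\n", x$id, x$type, x$title))
    return(invisible(x))
  }
  cat(sprintf("<experiment %d> [%s] %s\n  project %d, by %s on %s\n",
              x$id, x$type, x$title, x$project_id, x$performed_by, x$date))
  if (!is.null(x$conditions)) {
    f <- x$conditions$fields
    cat("  conditions:", paste(names(f), unlist(f), sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$samples)) cat("  samples:", paste(x$samples$name, collapse = ", "), "\n")
  if (nrow(x$attachments)) {
    cat(sprintf("  attachments: %d file(s)\n", nrow(x$attachments)))
  }
  invisible(x)
}

#' List a project's experiments
#'
#' @inheritParams create_project
#' @param project Project id.
#' @param type Optional experiment-type filter.
#' @return Tibble of experiment summaries ordered by internal id.
#' @export
list_experiments <- function(store, project, type = NULL) {
  check_store(store)
  project <- check_id(project, "project")
  if (!project_exists(store, project)) stop_not_found(sprintf("unknown project: %d", project))
  out <- db_get(store,
    "SELECT id, type, title, performed_by, date FROM experiments
     WHERE project_id = ? ORDER BY id", project)
  if (!is.null(type)) {
    if (!type %in% experiment_types()) stop_usage(sprintf("unknown experiment type: %s", type))
    out <- dplyr::filter(out, .data$type == !!type)
  }
  out
}

#' Attach an instrument file to an experiment
#'
#' The bytes are copied into the managed file store under
#' `files/<experiment id>/<file_id>_<original name>` (the file-id prefix
#' makes the path collision-free), and a reference with byte size and
#' SHA-256 checksum is recorded. Spot-quantitation tables
#' (`kind = "spot_table"`) are additionally parsed and their spot records
#' stored, so plate mapping can validate spot ids later.
#'
#' @inheritParams get_experiment
#' @param experiment Experiment internal id.
#' @param source_path Readable file to ingest.
#' @param kind One of `gel_image`, `chromatogram`, `peak_list`,
#'   `spot_table`, `ident_result`, `other`.
#' @return One-row tibble with the new file reference.
#' @export
attach_file <- function(store, experiment, source_path, kind = "other") {
  check_store(store)
  experiment <- check_id(experiment, "experiment")
  if (!experiment_exists(store, experiment)) {
    stop_not_found(sprintf("unknown experiment: %d", experiment))
  }
  enforce_edit(store, experiment)
  if (!file.exists(source_path)) stop_not_found(sprintf("unreadable file: %s", source_path))
  kinds <- c("gel_image", "chromatogram", "peak_list", "spot_table", "ident_result", "other")
  if (!kind %in% kinds) stop_usage(sprintf("unknown attachment kind: %s", kind))
  file_id <- next_id(store, "files", "file_id")
  original <- basename(source_path)
  rel <- file.path("files", experiment, paste0(file_id, "_", original))
  dest <- file.path(dirname(store$path), rel)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  if (!file.copy(source_path, dest, overwrite = FALSE)) {
    stop_integrity(sprintf("could not copy into managed store: %s", source_path))
  }
  checksum <- sha256_file(dest)
  db_exec(store,
    "INSERT INTO files (file_id, experiment_id, relative_path, original_name,
       byte_size, checksum, kind, external) VALUES (?, ?, ?, ?, ?, ?, ?, 0)",
    file_id, experiment, rel, original, file.size(dest), checksum, kind)
  if (kind == "spot_table") {
    spots <- parse_spot_table(paste(readLines(dest, warn = FALSE), collapse = "\n"))
    for (i in seq_len(nrow(spots))) {
      db_exec(store,
        "INSERT OR REPLACE INTO spots (experiment_id, spot_id, x, y, intensity,
           volume, area, percent_volume, pi, mw) VALUES (?,?,?,?,?,?,?,?,?,?)",
        experiment, spots$spot_id[i], spots$x[i], spots$y[i], spots$intensity[i],
        spots$volume[i], spots$area[i], spots$percent_volume[i], spots$pi[i], spots$mw[i])
    }
  }
  record_action(store, actor_or_local(store), "attach", experiment)
  tibble(file_id = file_id, experiment_id = experiment, relative_path = rel,
         original_name = original, byte_size = file.size(dest),
         checksum = checksum, kind = kind)
}

# Resolve an attachment to its absolute path inside the managed store.
attachment_path <- function(store, file_row) {
  file.path(dirname(store$path), file_row$relative_path)
}

#' Verify managed-store checksums
#'
#' Recomputes the SHA-256 of every locally stored attachment and compares
#' it with the recorded value. Externally imported references (metadata
#' only, no bytes) are skipped.
#'
#' @inheritParams create_project
#' @return Tibble with one row per verified file and a logical `ok`.
#' @export
verify_attachments <- function(store) {
  check_store(store)
  f <- db_get(store, "SELECT file_id, relative_path, checksum, external FROM files ORDER BY file_id")
  f <- dplyr::filter(f, .data$external == 0L)
  if (!nrow(f)) return(tibble(file_id = integer(), ok = logical()))
  f$ok <- vapply(seq_len(nrow(f)), function(i) {
    p <- file.path(dirname(store$path), f$relative_path[i])
    file.exists(p) && identical(sha256_file(p), f$checksum[i])
  }, logical(1))
  select(f, "file_id", "relative_path", "ok")
}
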