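#' MALDI target-plate well names
#'
#' Wells are named by row letter (A..Z, so at most 26 rows) and column
#' number, enumerated row-major: A1, A2, ..., B1, ... A 96-well plate is
#' 8 x 12 (A1..H12), a 384-well plate 16 x 24 (A1..P24).
#'
#' @param rows,cols Plate geometry.
#' @return Character vector of `rows * cols` well names in row-major
#'   order.
#' @export
well_names <- function(rows, cols) {
  rows <- check_id(rows, "rows"); cols <- check_id(cols, "cols")
  if (rows > 26) stop_usage("at most 26 rows (single row letters A..Z)")
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
}

#' Create a MALDI plate bound to an MS experiment
#'
#' The plate correlates target wells with the gel spots (or samples)
#' that were spotted onto them, so the m/z lists acquired from the plate
#' can be traced back to the separation that produced them.
#'
#' @param store A `prodis_store` handle.
#' @param ms_experiment Internal id of an MS-typed experiment.
#' @param rows,cols Plate geometry (defaults: 384-well, 16 x 24).
#' @return One-row tibble with the new plate.
#' @export
new_plate <- function(store, ms_experiment, rows = 16, cols = 24) {
  check_store(store)
  ms_experiment <- check_known(store, ms_experiment)
  e <- db_get(store, "SELECT type FROM experiments WHERE id = ?", ms_experiment)
  if (e$type != "MS") {
    stop_usage(sprintf("plates attach to MS experiments; %d is %s", ms_experiment, e$type))
  }
  rows <- check_id(rows, "rows"); cols <- check_id(cols, "cols")
  if (rows > 26) stop_usage("at most 26 rows (single row letters A..Z)")
  pid <- next_id(store, "plates", "plate_id")
  db_exec(store, "INSERT INTO plates (plate_id, ms_experiment, rows, cols) VALUES (?, ?, ?, ?)",
          pid, ms_experiment, rows, cols)
  tibble(plate_id = pid, ms_experiment = ms_experiment, rows = rows, cols = cols)
}

get_plate <- function(store, plate) {
  plate <- check_id(plate, "plate")
  p <- db_get(store, "SELECT * FROM plates WHERE plate_id = ?", plate)
  if (!nrow(p)) stop_not_found(sprintf("unknown plate: %d", plate))
  p
}

#' Well sources
#'
#' A well holds exactly one source: a gel spot (identified by the gel
#' experiment's internal id and the spot id from its quantitation
#' table), a plain sample, or a calibrant.
#'
#' @param gel_experiment Internal id of the GEL2D experiment.
#' @param spot_id Spot identifier from that experiment's spot table.
#' @export
spot_source <- function(gel_experiment, spot_id) {
  list(type = "gel_spot", experiment = check_id(gel_experiment, "gel_experiment"),
       ref = as.character(spot_id))
}

#' @rdname spot_source
#' @param sample_id Sample id.
#' @export
sample_source <- function(sample_id) {
  list(type = "sample", experiment = NA_integer_, ref = as.character(check_id(sample_id, "sample_id")))
}

#' @rdname spot_source
#' @export
calibrant_source <- function() {
  list(type = "calibrant", experiment = NA_integer_, ref = NA_character_)
}

#' Assign a source to a plate well
#'
#' Each well takes at most one source; a spot may be assigned to several
#' wells (technical replicates). A gel-spot source must name a spot that
#' exists in the gel experiment's stored spot table, and assigning it
#' creates the provenance edge gel experiment -> MS experiment if it is
#' not already present.
#'
#' @inheritParams new_plate
#' @param plate Plate id.
#' @param well Well name valid for the plate's geometry.
#' @param source A [spot_source()], [sample_source()] or
#'   [calibrant_source()].
#' @return One-row tibble with the assignment.
#' @export
assign_well <- function(store, plate, well, source) {
  check_store(store)
  p <- get_plate(store, plate)
  valid <- well_names(p$rows, p$cols)
  if (!is.character(well) || length(well) != 1L || !well %in% valid) {
    stop_usage(sprintf("invalid well name '%s' for a %dx%d plate", well, p$rows, p$cols))
  }
  if (nrow(db_get(store, "SELECT 1 FROM wells WHERE plate_id = ? AND well = ?", p$plate_id, well))) {
    stop_usage(sprintf("well %s is already assigned", well))
  }
  stopifnot(is.list(source), source$type %in% c("gel_spot", "sample", "calibrant"))
  if (source$type == "gel_spot") {
    g <- check_known(store, source$experiment)
    known <- db_get(store, "SELECT 1 FROM spots WHERE experiment_id = ? AND spot_id = ?",
                    g, source$ref)
    if (!nrow(known)) {
      stop_not_found(sprintf("spot '%s' not found in experiment %d's spot table",
                             source$ref, g))
    }
  }
  if (source$type == "sample") {
    if (!nrow(db_get(store, "SELECT 1 FROM samples WHERE sample_id = ?", as.integer(source$ref)))) {
      stop_not_found(sprintf("unknown sample: %s", source$ref))
    }
  }
  db_exec(store,
    "INSERT INTO wells (plate_id, well, source_type, source_experiment, source_ref)
     VALUES (?, ?, ?, ?, ?)",
    p$plate_id, well, source$type, source$experiment, source$ref)
  if (source$type == "gel_spot" &&
      !nrow(db_get(store, "SELECT 1 FROM edges WHERE parent = ? AND child = ?",
                   source$experiment, p$ms_experiment))) {
    link_experiments(store, source$experiment, p$ms_experiment)
  }
  tibble(plate_id = p$plate_id, well = well, source_type = source$type,
         source_experiment = source$experiment, source_ref = source$ref)
}

#' @rdname assign_well
#' @export
lookup_well <- function(store, plate, well) {
  check_store(store)
  p <- get_plate(store, plate)
  db_get(store,
    "SELECT well, source_type, source_experiment, source_ref
     FROM wells WHERE plate_id = ? AND well = ?", p$plate_id, well)
}

#' Find the wells carrying a gel spot
#'
#' The inverse image of [assign_well()]: all wells of the plate holding
#' the given spot (replicates included), in row-major order. An
#' unassigned spot yields an empty vector; this never errors.
#'
#' @inheritParams assign_well
#' @param gel_experiment,spot_id Spot to look up.
#' @return Character vector of well names.
#' @export
find_spot <- function(store, plate, gel_experiment, spot_id) {
  check_store(store)
  p <- get_plate(store, plate)
  w <- db_get(store,
    "SELECT well FROM wells WHERE plate_id = ? AND source_type = 'gel_spot'
       AND source_experiment = ? AND source_ref = ?",
    p$plate_id, as.integer(gel_experiment), as.character(spot_id))$well
  order_wells(w, p$rows, p$cols)
}

order_wells <- function(wells, rows, cols) {
  if (!length(wells)) return(character())
  wells[order(match(wells, well_names(rows, cols)))]
}

#' Export or import a plate layout as CSV
#'
#' Columns `Well,SourceType,ExperimentId,SpotOrSampleId`, wells in
#' row-major order. `import_plate()` replays the rows through
#' [assign_well()], so all validation (and provenance-edge creation)
#' applies.
#'
#' @inheritParams assign_well
#' @export
export_plate <- function(store, plate) {
  check_store(store)
  p <- get_plate(store, plate)
  w <- db_get(store,
    "SELECT well, source_type, source_experiment, source_ref FROM wells WHERE plate_id = ?",
    p$plate_id)
  w <- w[order(match(w$well, well_names(p$rows, p$cols))), ]
  rows <- purrr::map_chr(seq_len(nrow(w)), function(i) {
    sprintf("%s,%s,%s,%s", w$well[i], w$source_type[i],
            ifelse(is.na(w$source_experiment[i]), "", w$source_experiment[i]),
            ifelse(is.na(w$source_ref[i]), "", w$source_ref[i]))
  })
  paste0(paste(c("Well,SourceType,ExperimentId,SpotOrSampleId", rows), collapse = "\n"), "\n")
}

#' @rdname export_plate
#' @param text CSV content as produced by [export_plate()].
#' @export
import_plate <- function(store, plate, text) {
  check_store(store)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(str_trim(lines))]
  if (!length(lines) || tolower(lines[[1]]) != "well,sourcetype,experimentid,spotorsampleid") {
    stop_format("plate CSV: expected header Well,SourceType,ExperimentId,SpotOrSampleId")
  }
  out <- purrr::map(lines[-1], function(ln) {
    cells <- str_trim(strsplit(ln, ",", fixed = TRUE)[[1]])
    length(cells) <- 4L
    src <- switch(cells[2],
      gel_spot = spot_source(as.integer(cells[3]), cells[4]),
      sample = sample_source(as.integer(cells[4])),
      calibrant = calibrant_source(),
      stop_format(sprintf("plate CSV: unknown source type '%s'", cells[2])))
    assign_well(store, plate, cells[1], src)
  })
  bind_rows(out)
}
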