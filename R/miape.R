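#' Minimum-information field requirements
#'
#' The required-field lists are this package's explicit, versioned
#' concretization of minimum-information reporting guidelines for
#' proteomics (MIAPE-style minima for MS, gel electrophoresis and
#' column chromatography). They are shipped as editable data
#' (`extdata/miape_requirements.json`), not code: every experiment type
#' requires performer, date, samples and protocol; MS adds instrument,
#' ionization and analyzer mode; GEL2D adds the first-dimension pI
#' range, gel concentration and stain; LC adds instrument, column and
#' the first solvent.
#'
#' @return Tibble with columns `type` and `field`, in requirement order.
#' @export
miape_requirements <- function() {
  path <- system.file("extdata", "miape_requirements.json", package = "prodis")
  spec <- jsonlite::fromJSON(path)
  spec$comment <- NULL
  common <- spec$all
  bind_rows(purrr::map(experiment_types(), function(ty) {
    tibble(type = ty, field = as.character(c(common, unlist(spec[[ty]]))))
  }))
}

field_populated <- function(exp, path) {
  if (startsWith(path, "conditions.")) {
    f <- sub("^conditions\\.", "", path)
    v <- exp$conditions$fields[[f]]
    return(!is.null(v) && !is.na(v) && (!is.character(v) || nzchar(v)))
  }
  switch(path,
    performed_by = nzchar(exp$performed_by %||% ""),
    date = nzchar(exp$date %||% ""),
    samples = nrow(exp$samples) > 0,
    protocol = !is.null(exp$protocol),
    notes = nzchar(exp$notes %||% ""),
    FALSE)
}

#' Check an experiment's minimum-information completeness
#'
#' Compares the populated fields of the experiment with the required
#' list for its type and reports the missing field paths in requirement
#' order. Populating a field can only shrink the missing list;
#' `complete` is true exactly when nothing is missing.
#'
#' @param store A `prodis_store` handle.
#' @param id Experiment internal id.
#' @return A `prodis_miape` list with `experiment`, `type`, `missing`
#'   (character vector of field paths) and `complete`.
#' @export
miape_check <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  exp <- get_experiment_unchecked(store, id)
  req <- dplyr::filter(miape_requirements(), .data$type == exp$type)$field
  missing <- req[!vapply(req, field_populated, logical(1), exp = exp)]
  structure(list(experiment = id, type = exp$type,
                 missing = unname(missing), complete = length(missing) == 0L),
            class = "prodis_miape")
}

#' @export
print.prodis_miape <- function(x, ...) {
  if (x$complete) {
    cat(sprintf("experiment %d (%s): minimum information complete\n", x$experiment, x$type))
  } else {
    cat(sprintf("experiment %d (%s): %d required field(s) missing:\n  %s\n",
                x$experiment, x$type, length(x$missing), paste(x$missing, collapse = "\n  ")))
  }
  invisible(x)
}
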