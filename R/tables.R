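#' Parse a 2D-gel spot quantitation table
#'
#' Tab-delimited export in the style of Image Master Platinum: a header
#' row with required columns `Spot`, `X`, `Y`, `Intensity`, `Volume`,
#' `Area` and optional `%Vol`, `pI`, `MW`, matched case-insensitively.
#' One record per data row, in file order. A missing required column is
#' named in the error; a non-numeric cell is reported with its row and
#' column.
#'
#' @param text File content as a character scalar.
#' @return Tibble with columns `spot_id`, `x`, `y`, `intensity`,
#'   `volume`, `area`, `percent_volume`, `pi`, `mw` (optional columns NA
#'   when absent).
#' @export
parse_spot_table <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(str_trim(lines))]
  if (!length(lines)) stop_format("spot table: empty file (header row required)")
  header <- str_trim(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  key <- tolower(header)
  colmap <- c(spot = "spot", x = "x", y = "y", intensity = "intensity",
              volume = "volume", area = "area")
  optmap <- c(percent_volume = "%vol", pi = "pi", mw = "mw")
  idx <- function(k) match(k, key)
  for (k in colmap) {
    if (is.na(idx(k))) stop_format(sprintf("spot table: missing required column '%s'", k))
  }
  num_cell <- function(cells, j, row, colname) {
    v <- suppressWarnings(as.numeric(cells[j]))
    if (is.na(v) && !identical(str_trim(cells[j]), "")) {
      stop_format(sprintf("spot table row %d, column '%s': non-numeric value '%s'",
                          row, colname, cells[j]))
    }
    v
  }
  rows <- purrr::map(seq_along(lines[-1]), function(r) {
    cells <- str_trim(strsplit(lines[[r + 1L]], "\t", fixed = TRUE)[[1]])
    get_opt <- function(name) {
      j <- idx(optmap[[name]])
      if (is.na(j) || j > length(cells)) NA_real_ else num_cell(cells, j, r, optmap[[name]])
    }
    tibble(
      spot_id = cells[idx("spot")],
      x = num_cell(cells, idx("x"), r, "x"),
      y = num_cell(cells, idx("y"), r, "y"),
      intensity = num_cell(cells, idx("intensity"), r, "intensity"),
      volume = num_cell(cells, idx("volume"), r, "volume"),
      area = num_cell(cells, idx("area"), r, "area"),
      percent_volume = get_opt("percent_volume"),
      pi = get_opt("pi"),
      mw = get_opt("mw"))
  })
  out <- bind_rows(tibble(spot_id = character(), x = numeric(), y = numeric(),
                          intensity = numeric(), volume = numeric(), area = numeric(),
                          percent_volume = numeric(), pi = numeric(), mw = numeric()),
                   rows)
  bad <- which(out$x < 0 | out$y < 0 | out$area < 0)
  if (length(bad)) {
    stop_format(sprintf("spot table row %d: x, y and area must be non-negative", bad[1]))
  }
  badv <- which(!is.na(out$percent_volume) &
                  (out$percent_volume < 0 | out$percent_volume > 100))
  if (length(badv)) {
    stop_format(sprintf("spot table row %d: %%Vol must lie in [0, 100]", badv[1]))
  }
  out
}

#' Parse an LC peak table
#'
#' CSV with header `Peak,RetentionTime,Height,Area` (case-insensitive).
#' Rows are returned sorted by retention time ascending; a negative
#' retention time is a format error.
#'
#' @inheritParams parse_spot_table
#' @return Tibble with `peak_no`, `retention_time` (min), `height`,
#'   `area`.
#' @export
parse_lc_peak_table <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(str_trim(lines))]
  if (!length(lines)) stop_format("LC peak table: empty file (header row required)")
  key <- tolower(str_trim(strsplit(lines[[1]], ",", fixed = TRUE)[[1]]))
  need <- c(peak_no = "peak", retention_time = "retentiontime",
            height = "height", area = "area")
  for (k in need) {
    if (!k %in% key) stop_format(sprintf("LC peak table: missing required column '%s'", k))
  }
  rows <- purrr::map(seq_along(lines[-1]), function(r) {
    cells <- str_trim(strsplit(lines[[r + 1L]], ",", fixed = TRUE)[[1]])
    val <- function(k, colname) {
      v <- suppressWarnings(as.numeric(cells[match(k, key)]))
      if (is.na(v)) {
        stop_format(sprintf("LC peak table row %d, column '%s': non-numeric value", r, colname))
      }
      v
    }
    tibble(peak_no = as.integer(val("peak", "Peak")),
           retention_time = val("retentiontime", "RetentionTime"),
           height = val("height", "Height"),
           area = val("area", "Area"))
  })
  out <- bind_rows(tibble(peak_no = integer(), retention_time = numeric(),
                          height = numeric(), area = numeric()), rows)
  if (any(out$retention_time < 0)) {
    stop_format("LC peak table: negative retention time")
  }
  arrange(out, .data$retention_time)
}

#' Parse a search-engine identification export
#'
#' Engine-specific CSV exports are normalized to a common record with a
#' "larger is better" score: Mascot reports an ion score directly
#' (`pep_query`, `prot_acc`, `prot_desc`, `pep_score`); X!Tandem and
#' OMSSA report expectation values (`expect` / `E-value`), which are
#' transformed to `-log10(expectation)`.
#'
#' @inheritParams parse_spot_table
#' @param engine One of `"mascot"`, `"xtandem"`, `"omssa"`.
#' @return Tibble with `engine`, `spectrum_ref`, `accession`,
#'   `description`, `score`.
#' @export
parse_ident_table <- function(text, engine) {
  stopifnot(is.character(text), length(text) == 1L)
  maps <- list(
    mascot = c(spectrum_ref = "pep_query", accession = "prot_acc",
               description = "prot_desc", score = "pep_score"),
    xtandem = c(spectrum_ref = "id", accession = "label",
                description = "description", score = "expect"),
    omssa = c(spectrum_ref = "Spectrum number", accession = "Accession",
              description = "Defline", score = "E-value"))
  if (!engine %in% names(maps)) stop_usage(sprintf("unknown engine tag: %s", engine))
  map <- maps[[engine]]
  df <- utils::read.csv(text = text, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in map) {
    if (!col %in% names(df)) {
      stop_format(sprintf("%s export: missing mapped column '%s'", engine, col))
    }
  }
  score <- as.numeric(df[[map[["score"]]]])
  if (engine %in% c("xtandem", "omssa")) score <- -log10(score)
  tibble(engine = rep(engine, nrow(df)),
         spectrum_ref = as.character(df[[map[["spectrum_ref"]]]]),
         accession = as.character(df[[map[["accession"]]]]),
         description = as.character(df[[map[["description"]]]]),
         score = score)
}
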