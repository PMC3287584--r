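#' Normalized peak-list container
#'
#' Every peak-list dialect the system reads (pkl, MGF, mzML, mzXML,
#' mzData) is normalized into the same container: the source dialect
#' tag, free-form instrument metadata, and a tibble of spectra with a
#' list-column of `(mz, intensity)` peak tibbles. Peaks leave every
#' parser sorted by m/z ascending; m/z is in thomson and must be
#' positive, intensities are arbitrary units and non-negative.
#'
#' @param source_format Dialect tag.
#' @param spectra Tibble with columns `scan_id`, `precursor_mz`,
#'   `precursor_charge`, `peaks`.
#' @param instrument_meta Named list of free-text metadata.
#' @export
new_mzlist <- function(source_format, spectra, instrument_meta = list()) {
  stopifnot(is.data.frame(spectra))
  structure(list(source_format = source_format,
                 instrument_meta = instrument_meta,
                 spectra = as_tibble(spectra)),
            class = "mz_list")
}

#' @export
print.mz_list <- function(x, ...) {
  cat(sprintf("<mz_list> %s: %d spectra, %d peaks total\n",
              x$source_format, nrow(x$spectra),
              sum(vapply(x$spectra$peaks, nrow, integer(1)))))
  invisible(x)
}

empty_spectra <- function() {
  tibble(scan_id = character(), precursor_mz = numeric(),
         precursor_charge = integer(), peaks = list())
}

new_peaks <- function(mz, intensity) {
  if (length(mz) != length(intensity)) {
    stop_format(sprintf("m/z and intensity arrays differ in length (%d vs %d)",
                        length(mz), length(intensity)))
  }
  if (length(mz) && (any(!is.finite(mz)) || any(mz <= 0))) {
    stop_format("m/z values must be positive and finite")
  }
  if (length(intensity) && (any(!is.finite(intensity)) || any(intensity < 0))) {
    stop_format("intensities must be non-negative and finite")
  }
  ord <- order(mz)
  tibble(mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]))
}

#' Canonical form of a peak list for cross-dialect comparison
#'
#' Drops the dialect tag, metadata and scan identifiers (which differ
#' legitimately between dialects) and keeps precursor m/z, charge and
#' the sorted peak arrays, in spectrum order.
#'
#' @param x An `mz_list`.
#' @return Tibble with `precursor_mz`, `precursor_charge`, `peaks`.
#' @export
normalize_mzlist <- function(x) {
  stopifnot(inherits(x, "mz_list"))
  sp <- x$spectra
  tibble(precursor_mz = as.numeric(sp$precursor_mz),
         precursor_charge = as.integer(sp$precursor_charge),
         peaks = lapply(sp$peaks, function(p) new_peaks(p$mz, p$intensity)))
}

# ---- detection --------------------------------------------------------------

#' Detect the dialect of an instrument export
#'
#' XML dialects are distinguished by their root element name
#' (`mzML`/`indexedmzML`, `mzXML`, `mzData`); MGF by its `BEGIN IONS`
#' block marker; tab-delimited spot tables and CSV LC peak tables by
#' their header rows; pkl by its all-numeric 3-field header / 2-field
#' peak line shape. Anything else is `"unknown"` — detection never
#' throws.
#'
#' @param content File content: a character scalar or raw vector.
#' @return One of `"pkl"`, `"mzxml"`, `"mzdata"`, `"mzml"`, `"mgf"`,
#'   `"spot_table"`, `"lc_table"`, `"unknown"`.
#' @export
detect_format <- function(content) {
  if (is.raw(content)) content <- rawToChar(content)
  if (!is.character(content) || length(content) != 1L || !nzchar(content)) return("unknown")
  trimmed <- str_trim(content)
  if (startsWith(trimmed, "<")) {
    root <- xml_root_name(trimmed)
    return(switch(root,
      mzML = , indexedmzML = "mzml",
      mzXML = "mzxml",
      mzData = "mzdata",
      "unknown"))
  }
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- str_trim(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return("unknown")
  if (any(startsWith(lines, "BEGIN IONS"))) return("mgf")
  header_l <- tolower(lines[[1]])
  tsv_cols <- str_trim(strsplit(header_l, "\t", fixed = TRUE)[[1]])
  if (all(c("spot", "x", "y") %in% tsv_cols)) return("spot_table")
  csv_cols <- str_trim(strsplit(header_l, ",", fixed = TRUE)[[1]])
  if (all(c("peak", "retentiontime") %in% csv_cols)) return("lc_table")
  tok <- strsplit(lines, "[ \t]+")
  numeric_line <- vapply(tok, function(t) all(!is.na(suppressWarnings(as.numeric(t)))), logical(1))
  n_fields <- vapply(tok, length, integer(1))
  if (all(numeric_line) && n_fields[1] == 3L && all(n_fields %in% c(2L, 3L))) return("pkl")
  "unknown"
}

xml_root_name <- function(text) {
  # First element name after prolog/comments/doctype, namespace prefix stripped.
  m <- regmatches(text, gregexpr("<[^!?][^ \t\r\n>/]*", text))[[1]]
  if (!length(m)) return("")
  root <- sub("^<", "", m[[1]])
  sub("^.*:", "", root)
}

# ---- pkl --------------------------------------------------------------------

#' Parse a pkl peak list
#'
#' Dialect: blank-line separated blocks; each block starts with a header
#' line `precursor_mz precursor_intensity charge` followed by
#' `mz intensity` peak lines. Malformed lines are reported with their
#' line number.
#'
#' @param text File content as a character scalar.
#' @return An [new_mzlist()] container with `source_format = "pkl"`.
#' @export
parse_pkl <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  spectra <- empty_spectra()
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    if (!nzchar(str_trim(lines[i]))) { i <- i + 1L; next }
    block <- block + 1L
    hdr <- suppressWarnings(as.numeric(strsplit(str_trim(lines[i]), "[ \t]+")[[1]]))
    if (length(hdr) != 3L || any(is.na(hdr))) {
      stop_format(sprintf("pkl line %d: header must have 3 numeric fields", i))
    }
    i <- i + 1L
    mz <- numeric(); inten <- numeric()
    while (i <= length(lines) && nzchar(str_trim(lines[i]))) {
      pk <- suppressWarnings(as.numeric(strsplit(str_trim(lines[i]), "[ \t]+")[[1]]))
      if (length(pk) != 2L || any(is.na(pk))) {
        stop_format(sprintf("pkl line %d: peak line must have 2 numeric fields", i))
      }
      mz <- c(mz, pk[1]); inten <- c(inten, pk[2])
      i <- i + 1L
    }
    spectra <- bind_rows(spectra, tibble(
      scan_id = as.character(block), precursor_mz = hdr[1],
      precursor_charge = as.integer(hdr[3]), peaks = list(new_peaks(mz, inten))))
  }
  new_mzlist("pkl", spectra)
}

# ---- MGF --------------------------------------------------------------------

#' Read and write Mascot generic format
#'
#' MGF is the interchange dialect used for search-engine submission:
#' `BEGIN IONS`/`END IONS` blocks with `TITLE=`, `PEPMASS=`, `CHARGE=`
#' headers and `mz intensity` peak lines. `write_mgf()` is bit-exact:
#' m/z printed with 4 decimal places, intensities with 1, charge as
#' `<n>+`/`<n>-`; `parse_mgf()` inverts it. Header lines other than the
#' three known ones are preserved in `instrument_meta`.
#'
#' @param text MGF content as a character scalar.
#' @return `parse_mgf()` an `mz_list`; `write_mgf()` a character scalar.
#' @export
parse_mgf <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- str_trim(strsplit(text, "\n", fixed = TRUE)[[1]])
  spectra <- empty_spectra()
  meta <- list()
  in_block <- FALSE
  title <- NA_character_; pmz <- NA_real_; chg <- NA_integer_
  mz <- numeric(); inten <- numeric()
  block <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop_format(sprintf("mgf line %d: nested BEGIN IONS", i))
      in_block <- TRUE; block <- block + 1L
      title <- NA_character_; pmz <- NA_real_; chg <- NA_integer_
      mz <- numeric(); inten <- numeric()
    } else if (ln == "END IONS") {
      if (!in_block) stop_format(sprintf("mgf line %d: END IONS without BEGIN IONS", i))
      in_block <- FALSE
      spectra <- bind_rows(spectra, tibble(
        scan_id = if (is.na(title)) as.character(block) else title,
        precursor_mz = pmz, precursor_charge = chg, peaks = list(new_peaks(mz, inten))))
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") pmz <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
      else if (key == "CHARGE") chg <- parse_mgf_charge(val, i)
      else meta[[key]] <- val
    } else if (in_block) {
      pk <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (length(pk) != 2L || any(is.na(pk))) {
        stop_format(sprintf("mgf line %d: peak line must have 2 numeric fields", i))
      }
      mz <- c(mz, pk[1]); inten <- c(inten, pk[2])
    }
  }
  if (in_block) stop_format("mgf: unterminated BEGIN IONS block")
  new_mzlist("mgf", spectra, meta)
}

parse_mgf_charge <- function(val, line) {
  m <- regmatches(val, regexec("^([0-9]+)([+-]?)$", str_trim(val)))[[1]]
  if (length(m) != 3L) stop_format(sprintf("mgf line %d: bad CHARGE value '%s'", line, val))
  z <- as.integer(m[2])
  if (m[3] == "-") -z else z
}

#' @rdname parse_mgf
#' @param mzlist An `mz_list` to serialize.
#' @export
write_mgf <- function(mzlist) {
  stopifnot(inherits(mzlist, "mz_list"))
  blocks <- purrr::map_chr(seq_len(nrow(mzlist$spectra)), function(i) {
    sp <- mzlist$spectra[i, ]
    p <- sp$peaks[[1]]
    hdr <- c("BEGIN IONS",
             if (!is.na(sp$scan_id)) sprintf("TITLE=%s", sp$scan_id),
             if (!is.na(sp$precursor_mz)) sprintf("PEPMASS=%s", fmt_num(sp$precursor_mz, 4)),
             if (!is.na(sp$precursor_charge))
               sprintf("CHARGE=%d%s", abs(sp$precursor_charge),
                       if (sp$precursor_charge < 0) "-" else "+"))
    body <- if (nrow(p)) sprintf("%s %s", fmt_num(p$mz, 4), fmt_num(p$intensity, 1)) else character()
    paste(c(hdr, body, "END IONS"), collapse = "\n")
  })
  paste0(paste(blocks, collapse = "\n\n"), if (length(blocks)) "\n" else "")
}

# ---- XML peak-list dialects -------------------------------------------------

decode_b64_floats <- function(b64, size, endian, what) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (length(raw) %% size != 0L) {
    stop_format(sprintf("%s: binary array length %d is not a multiple of %d bytes",
                        what, length(raw), size))
  }
  readBin(raw, "double", n = length(raw) %/% size, size = size, endian = endian)
}

read_xml_doc <- function(x) {
  if (is.raw(x)) x <- rawToChar(x)
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop_format(sprintf("malformed XML: %s", conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  doc
}

cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

cv_present <- function(node, accession) {
  !inherits(xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession)),
            "xml_missing")
}

#' Parse mzML, mzXML and mzData peak lists
#'
#' Only the peak-list content and instrument description are extracted;
#' chromatogram arrays and vendor extensions are ignored. Binary arrays
#' must be base64-encoded uncompressed 32- or 64-bit IEEE-754 floats:
#' mzML uses separate little-endian m/z and intensity arrays, mzXML
#' interleaved m/z-intensity pairs in network (big-endian) byte order,
#' mzData separate arrays with an explicit `endian` attribute.
#' Compressed arrays raise an unsupported-feature error naming the
#' feature; an m/z / intensity length mismatch is a format error.
#'
#' @param x XML content: character scalar or raw vector.
#' @return An `mz_list` normalized container.
#' @export
parse_mzml <- function(x) {
  doc <- read_xml_doc(x)
  root <- xml2::xml_name(doc)
  if (!root %in% c("mzML", "indexedmzML")) {
    stop_format(sprintf("expected mzML root element, found '%s'", root))
  }
  meta <- list()
  instr <- xml2::xml_find_first(doc, ".//instrumentConfiguration/cvParam[@name]")
  if (!inherits(instr, "xml_missing")) {
    meta$instrument <- xml2::xml_attr(instr, "name")
  }
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  rows <- purrr::map(nodes, function(sp) {
    scan_id <- xml2::xml_attr(sp, "id")
    ion <- xml2::xml_find_first(sp, ".//selectedIon")
    pmz <- NA_real_; chg <- NA_integer_
    if (!inherits(ion, "xml_missing")) {
      pmz <- as.numeric(cv_value(ion, "MS:1000744"))
      cv <- cv_value(ion, "MS:1000041")
      chg <- if (is.na(cv)) NA_integer_ else as.integer(cv)
    }
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- numeric(0); inten <- numeric(0)
    for (arr in arrays) {
      if (cv_present(arr, "MS:1000574")) {
        stop_format("unsupported feature: zlib-compressed binary array")
      }
      size <- if (cv_present(arr, "MS:1000523")) 8L
              else if (cv_present(arr, "MS:1000521")) 4L
              else stop_format("binary array without a float-precision cvParam")
      vals <- decode_b64_floats(xml2::xml_text(xml2::xml_find_first(arr, "./binary")),
                                size, "little", "mzML")
      if (cv_present(arr, "MS:1000514")) mz <- vals
      else if (cv_present(arr, "MS:1000515")) inten <- vals
    }
    tibble(scan_id = scan_id, precursor_mz = pmz, precursor_charge = chg,
           peaks = list(new_peaks(mz, inten)))
  })
  new_mzlist("mzml", bind_rows(empty_spectra(), rows), meta)
}

#' @rdname parse_mzml
#' @export
parse_mzxml <- function(x) {
  doc <- read_xml_doc(x)
  if (xml2::xml_name(doc) != "mzXML") {
    stop_format(sprintf("expected mzXML root element, found '%s'", xml2::xml_name(doc)))
  }
  meta <- list()
  instr <- xml2::xml_find_first(doc, ".//msInstrument//msModel")
  if (!inherits(instr, "xml_missing")) meta$instrument <- xml2::xml_attr(instr, "value")
  nodes <- xml2::xml_find_all(doc, ".//scan")
  rows <- purrr::map(nodes, function(sc) {
    scan_id <- xml2::xml_attr(sc, "num")
    prec <- xml2::xml_find_first(sc, "./precursorMz")
    pmz <- NA_real_; chg <- NA_integer_
    if (!inherits(prec, "xml_missing")) {
      pmz <- as.numeric(xml2::xml_text(prec))
      ca <- xml2::xml_attr(prec, "precursorCharge")
      chg <- if (is.na(ca)) NA_integer_ else as.integer(ca)
    }
    pk <- xml2::xml_find_first(sc, "./peaks")
    if (inherits(pk, "xml_missing")) {
      return(tibble(scan_id = scan_id, precursor_mz = pmz, precursor_charge = chg,
                    peaks = list(new_peaks(numeric(0), numeric(0)))))
    }
    comp <- xml2::xml_attr(pk, "compressionType")
    if (!is.na(comp) && comp != "none") {
      stop_format(sprintf("unsupported feature: %s-compressed peaks in mzXML", comp))
    }
    prec_bits <- xml2::xml_attr(pk, "precision")
    size <- if (is.na(prec_bits) || prec_bits == "32") 4L else 8L
    bo <- xml2::xml_attr(pk, "byteOrder")
    endian <- if (is.na(bo) || bo == "network") "big" else "little"
    vals <- decode_b64_floats(xml2::xml_text(pk), size, endian, "mzXML")
    if (length(vals) %% 2L != 0L) {
      stop_format("mzXML: interleaved peak array has an odd number of values")
    }
    idx <- seq_len(length(vals) / 2L)
    tibble(scan_id = scan_id, precursor_mz = pmz, precursor_charge = chg,
           peaks = list(new_peaks(vals[2L * idx - 1L], vals[2L * idx])))
  })
  new_mzlist("mzxml", bind_rows(empty_spectra(), rows), meta)
}

#' @rdname parse_mzml
#' @export
parse_mzdata <- function(x) {
  doc <- read_xml_doc(x)
  if (xml2::xml_name(doc) != "mzData") {
    stop_format(sprintf("expected mzData root element, found '%s'", xml2::xml_name(doc)))
  }
  meta <- list()
  instr <- xml2::xml_find_first(doc, ".//instrumentName")
  if (!inherits(instr, "xml_missing")) meta$instrument <- xml2::xml_text(instr)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  rows <- purrr::map(nodes, function(sp) {
    scan_id <- xml2::xml_attr(sp, "id")
    ion <- xml2::xml_find_first(sp, ".//ionSelection")
    pmz <- NA_real_; chg <- NA_integer_
    if (!inherits(ion, "xml_missing")) {
      mznode <- xml2::xml_find_first(ion,
        "./cvParam[@name='MassToChargeRatio' or @accession='PSI:1000040']")
      if (!inherits(mznode, "xml_missing")) pmz <- as.numeric(xml2::xml_attr(mznode, "value"))
      chnode <- xml2::xml_find_first(ion,
        "./cvParam[@name='ChargeState' or @accession='PSI:1000041']")
      if (!inherits(chnode, "xml_missing")) chg <- as.integer(xml2::xml_attr(chnode, "value"))
    }
    read_arr <- function(xpath, what) {
      d <- xml2::xml_find_first(sp, xpath)
      if (inherits(d, "xml_missing")) return(numeric(0))
      size <- if (identical(xml2::xml_attr(d, "precision"), "64")) 8L else 4L
      endian <- if (identical(xml2::xml_attr(d, "endian"), "big")) "big" else "little"
      decode_b64_floats(xml2::xml_text(d), size, endian, what)
    }
    mz <- read_arr("./mzArrayBinary/data", "mzData m/z array")
    inten <- read_arr("./intenArrayBinary/data", "mzData intensity array")
    tibble(scan_id = scan_id, precursor_mz = pmz, precursor_charge = chg,
           peaks = list(new_peaks(mz, inten)))
  })
  new_mzlist("mzdata", bind_rows(empty_spectra(), rows), meta)
}

#' Read a peak-list file of any supported dialect
#'
#' Detects the dialect from the content and dispatches to the matching
#' parser.
#'
#' @param path Path to a peak-list file.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  fmt <- detect_format(txt)
  switch(fmt,
    pkl = parse_pkl(txt),
    mgf = parse_mgf(txt),
    mzml = parse_mzml(txt),
    mzxml = parse_mzxml(txt),
    mzdata = parse_mzdata(txt),
    stop_format(sprintf("not a recognized peak-list dialect: %s (detected '%s')", path, fmt)))
}
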