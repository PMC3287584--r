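#' Seeded synthetic fixture generators
#'
#' Deterministic generators for every input dialect the package parses,
#' each returning both the rendered file text and the ground truth it
#' was rendered from, so parser tests have an exact oracle. A single
#' integer seed drives a named pseudorandom stream per generator, so
#' adding a generator never perturbs the output of the others; the same
#' seed always yields byte-identical files. Values are structural, not
#' physico-chemical: m/z uniform in [100, 2000] Th rounded to 4
#' decimals, intensities uniform in [1, 1e5] rounded to 1 decimal,
#' precursors uniform in [400, 1200] Th with charge 1-3. No isotope
#' patterns or noise model is emulated.
#'
#' @param n_spectra Number of spectra (>= 0).
#' @param peaks_per_spectrum Peaks per spectrum.
#' @param seed Integer seed.
#' @return A list with `text` (the rendered file) and `truth` (an
#'   `mz_list` holding the generated spectra; its `spectra` tibble
#'   carries an extra `precursor_intensity` column used by the pkl
#'   dialect).
#' @export
synth_spectra <- function(n_spectra, peaks_per_spectrum, seed) {
  stopifnot(n_spectra >= 0, peaks_per_spectrum >= 0)
  with_stream(seed, "spectra", {
    rows <- purrr::map(seq_len(n_spectra), function(i) {
      mz <- sort(round(stats::runif(peaks_per_spectrum, 100, 2000), 4))
      inten <- round(stats::runif(peaks_per_spectrum, 1, 1e5), 1)
      tibble(scan_id = as.character(i),
             precursor_mz = round(stats::runif(1, 400, 1200), 4),
             precursor_intensity = round(stats::runif(1, 1e3, 1e6), 1),
             precursor_charge = sample(1:3, 1),
             peaks = list(tibble(mz = mz, intensity = inten)))
    })
    sp <- bind_rows(tibble(scan_id = character(), precursor_mz = numeric(),
                           precursor_intensity = numeric(),
                           precursor_charge = integer(), peaks = list()), rows)
    new_mzlist("truth", sp)
  })
}

#' @rdname synth_spectra
#' @export
synth_pkl <- function(n_spectra, peaks_per_spectrum, seed) {
  truth <- synth_spectra(n_spectra, peaks_per_spectrum, seed)
  blocks <- purrr::map_chr(seq_len(nrow(truth$spectra)), function(i) {
    sp <- truth$spectra[i, ]
    p <- sp$peaks[[1]]
    paste(c(sprintf("%s %s %d", fmt_num(sp$precursor_mz, 4),
                    fmt_num(sp$precursor_intensity, 1), sp$precursor_charge),
            sprintf("%s %s", fmt_num(p$mz, 4), fmt_num(p$intensity, 1))),
          collapse = "\n")
  })
  list(text = paste0(paste(blocks, collapse = "\n\n"), if (length(blocks)) "\n" else ""),
       truth = truth)
}

#' @rdname synth_spectra
#' @export
synth_mgf <- function(n_spectra, peaks_per_spectrum, seed) {
  truth <- synth_spectra(n_spectra, peaks_per_spectrum, seed)
  list(text = write_mgf(truth), truth = truth)
}

b64_floats <- function(x, size) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = size, endian = "little"))
}

b64_floats_big <- function(x, size) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = size, endian = "big"))
}

#' @rdname synth_spectra
#' @param precision Bit width of the encoded binary arrays: 64 (exact)
#'   or 32 (values rounded to float32 on encoding).
#' @export
synth_mzml <- function(n_spectra, peaks_per_spectrum, seed, precision = 64) {
  stopifnot(precision %in% c(32, 64))
  truth <- synth_spectra(n_spectra, peaks_per_spectrum, seed)
  size <- precision / 8
  acc <- if (precision == 64) "MS:1000523" else "MS:1000521"
  nm <- if (precision == 64) "64-bit float" else "32-bit float"
  spectra <- purrr::map_chr(seq_len(nrow(truth$spectra)), function(i) {
    sp <- truth$spectra[i, ]
    p <- sp$peaks[[1]]
    arr <- function(vals, arr_acc, arr_name) paste0(
      sprintf('        <binaryDataArray encodedLength="%d">\n',
              nchar(b64_floats(vals, size))),
      sprintf('          <cvParam cvRef="MS" accession="%s" name="%s"/>\n', acc, nm),
      '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
      sprintf('          <cvParam cvRef="MS" accession="%s" name="%s"/>\n', arr_acc, arr_name),
      sprintf('          <binary>%s</binary>\n', b64_floats(vals, size)),
      '        </binaryDataArray>\n')
    paste0(
      sprintf('    <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, i, nrow(p)),
      '      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '      <precursorList count="1">\n        <precursor>\n',
      '          <selectedIonList count="1">\n            <selectedIon>\n',
      sprintf('              <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%s"/>\n',
              fmt_num(sp$precursor_mz, 4)),
      sprintf('              <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>\n',
              sp$precursor_charge),
      '            </selectedIon>\n          </selectedIonList>\n',
      '        </precursor>\n      </precursorList>\n',
      '      <binaryDataArrayList count="2">\n',
      arr(p$mz, "MS:1000514", "m/z array"),
      arr(p$intensity, "MS:1000515", "intensity array"),
      '      </binaryDataArrayList>\n',
      '    </spectrum>\n')
  })
  text <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n    <fileContent>\n',
    '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>\n',
    '    </fileContent>\n  </fileDescription>\n',
    '  <softwareList count="1">\n    <software id="synth" version="0.1.0"/>\n  </softwareList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1">\n',
    '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/>\n',
    '    </instrumentConfiguration>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="dp1">\n      <processingMethod order="1" softwareRef="synth">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '      </processingMethod>\n    </dataProcessing>\n  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('  <spectrumList count="%d" defaultDataProcessingRef="dp1">\n',
            nrow(truth$spectra)),
    paste(spectra, collapse = ""),
    '  </spectrumList>\n',
    '  </run>\n</mzML>\n')
  list(text = text, truth = truth)
}

#' @rdname synth_spectra
#' @export
synth_mzxml <- function(n_spectra, peaks_per_spectrum, seed, precision = 64) {
  stopifnot(precision %in% c(32, 64))
  truth <- synth_spectra(n_spectra, peaks_per_spectrum, seed)
  size <- precision / 8
  scans <- purrr::map_chr(seq_len(nrow(truth$spectra)), function(i) {
    sp <- truth$spectra[i, ]
    p <- sp$peaks[[1]]
    interleaved <- as.numeric(rbind(p$mz, p$intensity))
    paste0(
      sprintf('    <scan num="%d" msLevel="2" peaksCount="%d">\n', i, nrow(p)),
      sprintf('      <precursorMz precursorCharge="%d">%s</precursorMz>\n',
              sp$precursor_charge, fmt_num(sp$precursor_mz, 4)),
      sprintf('      <peaks precision="%d" byteOrder="network" contentType="m/z-int" compressionType="none">%s</peaks>\n',
              precision, b64_floats_big(interleaved, size)),
      '    </scan>\n')
  })
  text <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    sprintf('  <msRun scanCount="%d">\n', nrow(truth$spectra)),
    paste(scans, collapse = ""),
    '  </msRun>\n</mzXML>\n')
  list(text = text, truth = truth)
}

#' @rdname synth_spectra
#' @export
synth_mzdata <- function(n_spectra, peaks_per_spectrum, seed, precision = 64) {
  stopifnot(precision %in% c(32, 64))
  truth <- synth_spectra(n_spectra, peaks_per_spectrum, seed)
  size <- precision / 8
  spectra <- purrr::map_chr(seq_len(nrow(truth$spectra)), function(i) {
    sp <- truth$spectra[i, ]
    p <- sp$peaks[[1]]
    paste0(
      sprintf('    <spectrum id="%d">\n', i),
      '      <spectrumDesc>\n',
      '        <spectrumSettings>\n          <spectrumInstrument msLevel="2"/>\n        </spectrumSettings>\n',
      '        <precursorList count="1">\n          <precursor msLevel="1" spectrumRef="0">\n',
      '            <ionSelection>\n',
      sprintf('              <cvParam cvLabel="psi" accession="PSI:1000040" name="MassToChargeRatio" value="%s"/>\n',
              fmt_num(sp$precursor_mz, 4)),
      sprintf('              <cvParam cvLabel="psi" accession="PSI:1000041" name="ChargeState" value="%d"/>\n',
              sp$precursor_charge),
      '            </ionSelection>\n            <activation/>\n',
      '          </precursor>\n        </precursorList>\n',
      '      </spectrumDesc>\n',
      sprintf('      <mzArrayBinary><data precision="%d" endian="little" length="%d">%s</data></mzArrayBinary>\n',
              precision, nrow(p), b64_floats(p$mz, size)),
      sprintf('      <intenArrayBinary><data precision="%d" endian="little" length="%d">%s</data></intenArrayBinary>\n',
              precision, nrow(p), b64_floats(p$intensity, size)),
      '    </spectrum>\n')
  })
  text <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzData version="1.05" accessionNumber="synthetic">\n',
    '  <description>\n    <admin><sampleName>synthetic</sampleName></admin>\n',
    '    <instrument><instrumentName>synthetic</instrumentName></instrument>\n',
    '    <dataProcessing><software><name>synth</name><version>0.1.0</version></software></dataProcessing>\n',
    '  </description>\n',
    sprintf('  <spectrumList count="%d">\n', nrow(truth$spectra)),
    paste(spectra, collapse = ""),
    '  </spectrumList>\n</mzData>\n')
  list(text = text, truth = truth)
}

#' Synthetic tabular fixtures
#'
#' Dialect-conformant spot-quantitation, LC peak and identification
#' tables with retained ground truth. LC retention times are sorted;
#' spot `%Vol` values sum to at most 100.
#'
#' @param n_spots,n_peaks,n_rows Number of data rows (>= 0).
#' @param seed Integer seed.
#' @return List with `text` and ground-truth tibble `truth`.
#' @export
synth_spot_table <- function(n_spots, seed) {
  stopifnot(n_spots >= 0)
  with_stream(seed, "spot_table", {
    volume <- round(stats::runif(n_spots, 1e3, 1e6), 1)
    pv <- if (n_spots) round(90 * volume / sum(volume), 3) else numeric()
    truth <- tibble(
      spot_id = sprintf("S%d", seq_len(n_spots)),
      x = round(stats::runif(n_spots, 0, 4000), 1),
      y = round(stats::runif(n_spots, 0, 4000), 1),
      intensity = round(stats::runif(n_spots, 10, 65535), 1),
      volume = volume,
      area = round(stats::runif(n_spots, 10, 500), 1),
      percent_volume = pv,
      pi = round(stats::runif(n_spots, 3, 10), 2),
      mw = round(stats::runif(n_spots, 10, 120), 1))
    header <- "Spot\tX\tY\tIntensity\tVolume\tArea\t%Vol\tpI\tMW"
    rows <- purrr::map_chr(seq_len(n_spots), function(i) {
      paste(truth$spot_id[i], fmt_num(truth$x[i], 1), fmt_num(truth$y[i], 1),
            fmt_num(truth$intensity[i], 1), fmt_num(truth$volume[i], 1),
            fmt_num(truth$area[i], 1), fmt_num(truth$percent_volume[i], 3),
            fmt_num(truth$pi[i], 2), fmt_num(truth$mw[i], 1), sep = "\t")
    })
    list(text = paste0(paste(c(header, rows), collapse = "\n"), "\n"), truth = truth)
  })
}

#' @rdname synth_spot_table
#' @export
synth_lc_table <- function(n_peaks, seed) {
  stopifnot(n_peaks >= 0)
  with_stream(seed, "lc_table", {
    truth <- tibble(
      peak_no = seq_len(n_peaks),
      retention_time = round(cumsum(stats::runif(n_peaks, 0.2, 5)), 2),
      height = round(stats::runif(n_peaks, 1, 2000), 1),
      area = round(stats::runif(n_peaks, 10, 5e4), 1))
    rows <- purrr::map_chr(seq_len(n_peaks), function(i) {
      paste(truth$peak_no[i], fmt_num(truth$retention_time[i], 2),
            fmt_num(truth$height[i], 1), fmt_num(truth$area[i], 1), sep = ",")
    })
    list(text = paste0(paste(c("Peak,RetentionTime,Height,Area", rows), collapse = "\n"), "\n"),
         truth = truth)
  })
}

#' @rdname synth_spot_table
#' @param engine One of `"mascot"`, `"xtandem"`, `"omssa"`.
#' @export
synth_ident_table <- function(engine, n_rows, seed) {
  stopifnot(n_rows >= 0)
  if (!engine %in% c("mascot", "xtandem", "omssa")) {
    stop_usage(sprintf("unknown engine tag: %s", engine))
  }
  with_stream(seed, paste0("ident_", engine), {
    acc <- sprintf("P%05d", sample(1:99999, n_rows, replace = TRUE))
    desc <- sprintf("synthetic protein %d", seq_len(n_rows))
    if (engine == "mascot") {
      score <- round(stats::runif(n_rows, 10, 120), 2)
      truth <- tibble(engine = rep(engine, n_rows),
                      spectrum_ref = as.character(seq_len(n_rows)),
                      accession = acc, description = desc, score = score)
      rows <- sprintf("%d,%s,%s,%s", seq_len(n_rows), acc, desc, fmt_num(score, 2))
      header <- "pep_query,prot_acc,prot_desc,pep_score"
    } else {
      # Expectation-value engines: ground-truth score is -log10(expect).
      score <- round(stats::runif(n_rows, 0, 6), 3)
      expect <- 10^(-score)
      truth <- tibble(engine = rep(engine, n_rows),
                      spectrum_ref = as.character(seq_len(n_rows)),
                      accession = acc, description = desc, score = score)
      ev <- formatC(expect, format = "e", digits = 12)
      if (engine == "xtandem") {
        header <- "id,label,description,expect"
      } else {
        header <- "Spectrum number,Accession,Defline,E-value"
      }
      rows <- sprintf("%d,%s,%s,%s", seq_len(n_rows), acc, desc, ev)
    }
    list(text = paste0(paste(c(header, rows), collapse = "\n"), "\n"), truth = truth)
  })
}

#' Random provenance DAG
#'
#' Generates an edge list that is acyclic by construction (edges only
#' run from lower to higher node label), used as ground truth against
#' the tracking module's reachability queries.
#'
#' @param n_nodes Number of nodes (labelled 1..n).
#' @param edge_prob Probability of each forward edge.
#' @param seed Integer seed.
#' @return Tibble with `parent` and `child` columns.
#' @export
random_dag <- function(n_nodes, edge_prob, seed) {
  stopifnot(n_nodes >= 0, edge_prob >= 0, edge_prob <= 1)
  with_stream(seed, "dag", {
    pairs <- if (n_nodes >= 2) {
      idx <- utils::combn(n_nodes, 2)
      keep <- stats::runif(ncol(idx)) < edge_prob
      tibble(parent = idx[1, keep], child = idx[2, keep])
    } else {
      tibble(parent = integer(), child = integer())
    }
    pairs
  })
}

#' Build the worked-example demo store
#'
#' Populates an empty store with the demonstration project: a protein
#' extraction (internal id 1) whose samples feed two 2D gels (ids 100
#' and 146) and an LC run (174); the gels' products feed two MS runs
#' (101 from gel 100, 148 from gel 146 — the assignment of grandchildren
#' to gels is an arbitrary, documented choice). Three accounts are
#' created: a coordinator (`gloria`), a researcher (`herbert`) and the
#' guest demo account `guest`/`guest`; the project is guest-visible.
#' Typed conditions and synthetic instrument attachments (spot tables,
#' peak lists, an LC peak table) are generated from the seed, so two
#' builds with the same seed produce identical stores and reports.
#'
#' @param dir Directory in which to create the store (`prodis.db` plus
#'   `files/`); must not already contain a store.
#' @param seed Integer seed for the synthetic attachments.
#' @return An open `prodis_store` handle.
#' @export
make_demo_store <- function(dir, seed = 1) {
  db <- file.path(dir, "prodis.db")
  if (file.exists(db)) stop_usage(sprintf("target store is not empty: %s", db))
  st <- prodis_create(db)
  with_stream(seed, "demo", {
    register_user(st, "gloria", "coordinator", "Gloria F.")
    register_user(st, "herbert", "researcher", "Herbert R.")
    register_user(st, "guest", "guest", "Guest")
    prj <- create_project(st, "SmProteome", "S. mansoni adult worm proteome survey",
                          "gloria", guest_visible = TRUE,
                          publications = "Adult worm 2D reference map (in preparation)")
    add_member(st, prj$project_id, "herbert", "RESEARCHER")
    add_member(st, prj$project_id, "guest", "GUEST")
    smp <- create_sample(st, "adult worm soluble extract", organism = "Schistosoma mansoni",
                         description = "pooled adult worms, soluble protein fraction")
    prot <- create_protocol(st, "TCA/acetone extraction", "standard TCA/acetone precipitation",
                            applies_to = "PREP")
    gel_prot <- create_protocol(st, "2D-PAGE pH 4-7", "IPG strip pH 4-7, 12%T SDS-PAGE",
                                applies_to = "GEL2D")

    create_experiment(st, prj$project_id, "PREP", "Protein extraction", "gloria",
                      "2011-03-01", samples = smp$sample_id,
                      protocol = prot$protocol_id, .id = 1L)
    create_experiment(st, prj$project_id, "GEL2D", "2D gel, pH 4-7 replicate A", "herbert",
                      "2011-03-10",
                      conditions = gel_conditions(strip_pi_low = 4, strip_pi_high = 7,
                                                  focusing_volt_hours = 32000,
                                                  gel_percent = 12.5,
                                                  second_dim_voltage = 200, run_time = 300,
                                                  stain = "colloidal Coomassie"),
                      samples = smp$sample_id, protocol = gel_prot$protocol_id, .id = 100L)
    create_experiment(st, prj$project_id, "MS", "MALDI-TOF of gel A spots", "herbert",
                      "2011-03-20",
                      conditions = ms_conditions(instrument = "Autoflex III",
                                                 ionization = "MALDI",
                                                 analyzer_mode = "TOF reflectron",
                                                 matrix = "CHCA",
                                                 mz_low = 700, mz_high = 3500),
                      samples = smp$sample_id, .id = 101L)
    create_experiment(st, prj$project_id, "GEL2D", "2D gel, pH 4-7 replicate B", "herbert",
                      "2011-04-02",
                      conditions = gel_conditions(strip_pi_low = 4, strip_pi_high = 7,
                                                  focusing_volt_hours = 32000,
                                                  gel_percent = 12.5,
                                                  second_dim_voltage = 200, run_time = 300,
                                                  stain = "silver"),
                      samples = smp$sample_id, protocol = gel_prot$protocol_id, .id = 146L)
    create_experiment(st, prj$project_id, "MS", "MALDI-TOF of gel B spots", "gloria",
                      "2011-04-12",
                      conditions = ms_conditions(instrument = "Autoflex III",
                                                 ionization = "MALDI",
                                                 analyzer_mode = "TOF reflectron",
                                                 matrix = "CHCA",
                                                 mz_low = 700, mz_high = 3500),
                      samples = smp$sample_id, .id = 148L)
    create_experiment(st, prj$project_id, "LC", "Cation exchange fractionation", "gloria",
                      "2011-04-20",
                      conditions = lc_conditions(instrument = "AKTA Explorer 100",
                                                 column = "Mono S 5/50",
                                                 solvent_a = "20 mM phosphate pH 6.8",
                                                 solvent_b = "A + 1 M NaCl",
                                                 gradient = "0-100% B over 40 min",
                                                 flow_rate = 1, temperature = 22,
                                                 detection_wavelength = 280),
                      samples = smp$sample_id, .id = 174L)

    tmp <- file.path(tempfile("prodis_demo_fix"), "src")
    dir.create(tmp, recursive = TRUE)
    put <- function(name, text) {
      p <- file.path(tmp, name)
      writeLines(text, p, sep = "")
      p
    }
    attach_file(st, 100, put("gelA_spots.tsv", synth_spot_table(25, seed + 1)$text), "spot_table")
    attach_file(st, 146, put("gelB_spots.tsv", synth_spot_table(25, seed + 2)$text), "spot_table")
    attach_file(st, 101, put("gelA_maldi.pkl", synth_pkl(5, 12, seed + 3)$text), "peak_list")
    attach_file(st, 148, put("gelB_maldi.mzML", synth_mzml(5, 12, seed + 4)$text), "peak_list")
    attach_file(st, 174, put("scx_peaks.csv", synth_lc_table(12, seed + 5)$text), "chromatogram")
    unlink(dirname(tmp), recursive = TRUE)

    link_experiments(st, 1, 100)
    link_experiments(st, 1, 146)
    link_experiments(st, 1, 174)
    link_experiments(st, 100, 101)
    link_experiments(st, 146, 148)
  })
  st
}
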