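test_that("detect_format recognizes every dialect signature and its own generator output", {
  expect_equal(detect_format("BEGIN IONS\nEND IONS"), "mgf")
  expect_equal(detect_format('<?xml version="1.0"?>\n<mzML xmlns="x"></mzML>'), "mzml")
  expect_equal(detect_format("<indexedmzML><mzML/></indexedmzML>"), "mzml")
  expect_equal(detect_format("<mzXML></mzXML>"), "mzxml")
  expect_equal(detect_format("<mzData/>"), "mzdata")
  expect_equal(detect_format("500.2 100 2\n100.1 5"), "pkl")
  expect_equal(detect_format("Spot\tX\tY\tIntensity\tVolume\tArea"), "spot_table")
  expect_equal(detect_format("Peak,RetentionTime,Height,Area"), "lc_table")
  expect_equal(detect_format("hello world"), "unknown")
  expect_equal(detect_format(""), "unknown")

  gens <- list(pkl = synth_pkl, mgf = synth_mgf, mzml = synth_mzml,
               mzxml = synth_mzxml, mzdata = synth_mzdata)
  for (seed in c(3, 14)) {
    for (fmt in names(gens)) {
      expect_equal(detect_format(gens[[fmt]](2, 4, seed)$text), fmt)
    }
    expect_equal(detect_format(synth_spot_table(3, seed)$text), "spot_table")
    expect_equal(detect_format(synth_lc_table(3, seed)$text), "lc_table")
  }
})

test_that("parse_pkl transcribes the dialect exactly and reports malformed lines", {
  x <- parse_pkl("500.25 10000 2\n100.1 50\n200.2 75\n")
  expect_equal(nrow(x$spectra), 1L)
  expect_equal(x$spectra$precursor_mz, 500.25)
  expect_equal(x$spectra$precursor_charge, 2L)
  expect_equal(x$spectra$peaks[[1]]$mz, c(100.1, 200.2))
  expect_equal(x$spectra$peaks[[1]]$intensity, c(50, 75))

  expect_equal(nrow(parse_pkl("")$spectra), 0L)
  expect_error(parse_pkl("500.25 10000\n100 5"), "line 1", class = "prodis_format_error")
  expect_error(parse_pkl("500.25 10000 2\n100 abc"), "line 2", class = "prodis_format_error")

  g <- synth_pkl(5, 10, 7)
  expect_spectra_equal(normalize_mzlist(parse_pkl(g$text)), normalize_mzlist(g$truth))
})

test_that("MGF writing is bit-stable and parse inverts it; unknown headers land in instrument_meta", {
  g <- synth_mgf(4, 6, 21)
  back <- parse_mgf(g$text)
  expect_spectra_equal(normalize_mzlist(back), normalize_mzlist(g$truth))
  expect_identical(write_mgf(back), g$text)  # writer is bit-exact on reparse

  no_prec <- new_mzlist("mgf", tibble::tibble(
    scan_id = "s1", precursor_mz = NA_real_, precursor_charge = NA_integer_,
    peaks = list(tibble::tibble(mz = c(110.5, 220.25), intensity = c(5, 6)))))
  txt <- write_mgf(no_prec)
  expect_false(grepl("PEPMASS", txt))
  reparsed <- parse_mgf(txt)
  expect_true(is.na(reparsed$spectra$precursor_mz))

  meta_txt <- "BEGIN IONS\nTITLE=t\nPEPMASS=500.0000\nCHARGE=2+\nINSTRUMENT=QTOF-2\n100.0000 1.0\nEND IONS\n"
  m <- parse_mgf(meta_txt)
  expect_equal(m$instrument_meta$INSTRUMENT, "QTOF-2")
  expect_error(parse_mgf("BEGIN IONS\n100 1\n"), "unterminated", class = "prodis_format_error")
})

test_that("parse_mzml decodes independently encoded binary arrays and flags unsupported or inconsistent ones", {
  # base64/IEEE-754 reference strings encoded with python struct+base64:
  # <2d little-endian [100.0, 200.0] and [10.0, 20.0]
  arr <- function(b64, which) sprintf(
    '<binaryDataArray encodedLength="%d">
       <cvParam accession="MS:1000523" name="64-bit float"/>
       <cvParam accession="MS:1000576" name="no compression"/>
       <cvParam accession="%s" name="array"/>
       <binary>%s</binary></binaryDataArray>', nchar(b64), which, b64)
  doc <- function(mzb, inb) sprintf(
    '<mzML><run><spectrumList count="1"><spectrum id="scan=1">
       <binaryDataArrayList count="2">%s%s</binaryDataArrayList>
     </spectrum></spectrumList></run></mzML>',
    arr(mzb, "MS:1000514"), arr(inb, "MS:1000515"))

  x <- parse_mzml(doc("AAAAAAAAWUAAAAAAAABpQA==", "AAAAAAAAJEAAAAAAAAA0QA=="))
  expect_equal(x$spectra$peaks[[1]]$mz, c(100, 200))
  expect_equal(x$spectra$peaks[[1]]$intensity, c(10, 20))

  empty <- parse_mzml(doc("", ""))
  expect_equal(nrow(empty$spectra$peaks[[1]]), 0L)

  # length mismatch between m/z and intensity arrays
  expect_error(parse_mzml(doc("AAAAAAAAWUAAAAAAAABpQA==", "AAAAAAAAJEA=")),
               class = "prodis_format_error")
  # zlib compression is declared unsupported by name
  zl <- gsub("MS:1000576", "MS:1000574",
             doc("AAAAAAAAWUAAAAAAAABpQA==", "AAAAAAAAJEAAAAAAAAA0QA=="))
  expect_error(parse_mzml(zl), "zlib", class = "prodis_format_error")
})

test_that("mzXML interleaved network-order arrays decode; compression is rejected", {
  # >4d big-endian [100.0, 10.0, 200.0, 20.0], python-encoded
  b64 <- "QFkAAAAAAABAJAAAAAAAAEBpAAAAAAAAQDQAAAAAAAA="
  doc <- sprintf(
    '<mzXML><msRun scanCount="1"><scan num="1" msLevel="2" peaksCount="2">
       <precursorMz precursorCharge="3">450.5</precursorMz>
       <peaks precision="64" byteOrder="network" contentType="m/z-int" compressionType="none">%s</peaks>
     </scan></msRun></mzXML>', b64)
  x <- parse_mzxml(doc)
  expect_equal(x$spectra$peaks[[1]]$mz, c(100, 200))
  expect_equal(x$spectra$peaks[[1]]$intensity, c(10, 20))
  expect_equal(x$spectra$precursor_mz, 450.5)
  expect_equal(x$spectra$precursor_charge, 3L)
  expect_error(parse_mzxml(gsub('compressionType="none"', 'compressionType="zlib"', doc)),
               "zlib", class = "prodis_format_error")
})

test_that("all five peak-list dialects normalize identically from shared ground truth", {
  for (seed in c(5, 42)) {
    truth <- normalize_mzlist(synth_spectra(3, 8, seed))
    expect_spectra_equal(normalize_mzlist(parse_pkl(synth_pkl(3, 8, seed)$text)), truth)
    expect_spectra_equal(normalize_mzlist(parse_mgf(synth_mgf(3, 8, seed)$text)), truth)
    expect_spectra_equal(normalize_mzlist(parse_mzml(synth_mzml(3, 8, seed)$text)), truth)
    expect_spectra_equal(normalize_mzlist(parse_mzxml(synth_mzxml(3, 8, seed)$text)), truth)
    expect_spectra_equal(normalize_mzlist(parse_mzdata(synth_mzdata(3, 8, seed)$text)), truth)
    # 32-bit encodings round through float32, no further loss
    expect_spectra_equal(
      normalize_mzlist(parse_mzml(synth_mzml(3, 8, seed, precision = 32)$text)),
      truth, float32 = TRUE)
    expect_spectra_equal(
      normalize_mzlist(parse_mzxml(synth_mzxml(3, 8, seed, precision = 32)$text)),
      truth, float32 = TRUE)
    expect_spectra_equal(
      normalize_mzlist(parse_mzdata(synth_mzdata(3, 8, seed, precision = 32)$text)),
      truth, float32 = TRUE)
  }
})

test_that("an independent mzML reader (mzR/proteowizard) agrees with our writer and parser", {
  m <- synth_mzml(3, 6, 11)
  f <- tempfile(fileext = ".mzML")
  writeLines(m$text, f, sep = "")
  h <- mzR::openMSfile(f)
  pk <- mzR::peaks(h)
  truth <- normalize_mzlist(m$truth)
  for (i in 1:3) {
    expect_equal(pk[[i]][, 1], truth$peaks[[i]]$mz)
    expect_equal(pk[[i]][, 2], truth$peaks[[i]]$intensity)
  }
  hd <- mzR::header(h)
  expect_equal(hd$precursorMZ, truth$precursor_mz)
  expect_equal(hd$precursorCharge, truth$precursor_charge)
  mzR::close(h)
})

test_that("every spectrum leaving any parser has non-decreasing m/z (parser totality over generator space)", {
  parsers <- list(parse_pkl = function(s) parse_pkl(synth_pkl(2, 6, s)$text),
                  parse_mgf = function(s) parse_mgf(synth_mgf(2, 6, s)$text),
                  parse_mzml = function(s) parse_mzml(synth_mzml(2, 6, s)$text),
                  parse_mzxml = function(s) parse_mzxml(synth_mzxml(2, 6, s)$text),
                  parse_mzdata = function(s) parse_mzdata(synth_mzdata(2, 6, s)$text))
  for (s in 101:110) {
    for (p in parsers) {
      out <- p(s)
      for (pk in out$spectra$peaks) expect_false(is.unsorted(pk$mz))
    }
  }
})

test_that("spot tables transcribe cell-exactly and errors name the offending column or cell", {
  txt <- "Spot\tX\tY\tIntensity\tVolume\tArea\t%Vol\tpI\tMW\nS1\t10\t20\t300\t4000\t50\t1.5\t5.2\t45\nS2\t11\t21\t301\t4001\t51\t2.5\t6.1\t46\n"
  out <- parse_spot_table(txt)
  expect_equal(nrow(out), 2L)
  expect_equal(out$spot_id, c("S1", "S2"))
  expect_equal(out$volume, c(4000, 4001))
  expect_equal(out$percent_volume, c(1.5, 2.5))

  expect_equal(nrow(parse_spot_table("Spot\tX\tY\tIntensity\tVolume\tArea\n")), 0L)
  expect_error(parse_spot_table("Spot\tX\tY\tIntensity\tVolume\n"), "area",
               class = "prodis_format_error")
  expect_error(parse_spot_table("Spot\tX\tY\tIntensity\tVolume\tArea\nS1\tbad\t1\t1\t1\t1\n"),
               "row 1.*'x'", class = "prodis_format_error")

  g <- synth_spot_table(50, 3)
  expect_equal(parse_spot_table(g$text), g$truth)
  expect_lte(sum(g$truth$percent_volume), 100)
})

test_that("LC peak tables sort by retention time and reject structural defects", {
  txt <- "Peak,RetentionTime,Height,Area\n1,12.4,5,50\n2,3.1,6,60\n"
  out <- parse_lc_peak_table(txt)
  expect_equal(out$retention_time, c(3.1, 12.4))
  expect_equal(nrow(parse_lc_peak_table("Peak,RetentionTime,Height,Area\n")), 0L)
  expect_error(parse_lc_peak_table("Peak,Height,Area\n"), "retentiontime",
               class = "prodis_format_error")
  expect_error(parse_lc_peak_table("Peak,RetentionTime,Height,Area\n1,-2,5,50\n"),
               "negative", class = "prodis_format_error")
  g <- synth_lc_table(20, 8)
  expect_equal(parse_lc_peak_table(g$text), g$truth)
})

test_that("identification exports normalize to higher-is-better scores per engine", {
  mascot <- "pep_query,prot_acc,prot_desc,pep_score\n1,P12345,some protein,45.2\n"
  m <- parse_ident_table(mascot, "mascot")
  expect_equal(m$score, 45.2)
  xt <- "id,label,description,expect\n7,Q99999,another protein,0.001\n"
  x <- parse_ident_table(xt, "xtandem")
  expect_equal(x$score, 3)
  om <- "Spectrum number,Accession,Defline,E-value\n3,O11111,defline,0.01\n"
  o <- parse_ident_table(om, "omssa")
  expect_equal(o$score, 2)
  expect_error(parse_ident_table(mascot, "sequest"), class = "prodis_usage_error")
  expect_error(parse_ident_table("a,b\n1,2\n", "mascot"), "pep_query",
               class = "prodis_format_error")
  for (eng in c("mascot", "xtandem", "omssa")) {
    g <- synth_ident_table(eng, 10, 4)
    expect_equal(parse_ident_table(g$text, eng), g$truth)
  }
})
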