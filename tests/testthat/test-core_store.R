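test_that("project creation enforces uniqueness, referential integrity and coordinator membership", {
  st <- tmp_store()
  register_user(st, "gloria", "pw", "Gloria")
  p <- create_project(st, "SmProteome", "S. mansoni 2D study", "gloria")
  expect_equal(p$coordinator, "gloria")
  expect_error(create_project(st, "SmProteome", "dup", "gloria"),
               class = "prodis_usage_error")
  expect_error(create_project(st, "Other", "x", "nobody"),
               class = "prodis_not_found_error")
  # coordinator can immediately act as a member
  e <- create_experiment(st, p$project_id, "PREP", "extraction", "gloria", "2020-05-01")
  expect_equal(e$performed_by, "gloria")
  prodis_close(st)
})

test_that("internal ids are unique, strictly increasing, and type/conditions variants must match", {
  fx <- seeded_store()
  e1 <- create_experiment(fx$store, fx$project, "PREP", "first", "ana", "2020-01-01")
  e2 <- create_experiment(fx$store, fx$project, "PREP", "second", "ana", "2020-01-02")
  expect_gt(e2$id, e1$id)

  expect_error(
    create_experiment(fx$store, fx$project, "MS", "bad", "ana", "2020-01-03",
                      conditions = gel_conditions(strip_pi_low = 3, strip_pi_high = 10)),
    class = "prodis_usage_error")
  expect_error(
    create_experiment(fx$store, fx$project, "PREP", "bad", "ana", "2020-01-03",
                      conditions = ms_conditions()),
    class = "prodis_usage_error")
  expect_error(create_experiment(fx$store, 99L, "PREP", "x", "ana", "2020-01-01"),
               class = "prodis_not_found_error")
  register_user(fx$store, "outsider", "pw")
  expect_error(
    create_experiment(fx$store, fx$project, "PREP", "x", "outsider", "2020-01-01"),
    class = "prodis_usage_error")

  ids <- vapply(seq_len(1000), function(i) {
    create_experiment(fx$store, fx$project, "PREP", sprintf("bulk %d", i),
                      "ana", "2020-02-01")$id
  }, integer(1))
  expect_equal(length(unique(ids)), 1000L)         # brute-force uniqueness
  expect_true(all(diff(ids) > 0))                  # monotone over creation order
  prodis_close(fx$store)
})

test_that("attach_file content-addresses bytes; checksum agrees with an independent SHA-256 tool", {
  fx <- seeded_store()
  e <- create_experiment(fx$store, fx$project, "PREP", "exp", "ana", "2020-01-01")
  src <- tempfile()
  writeBin(as.raw(c(0x61, 0x62, 0x63)), src)  # "abc", 3 bytes
  ref <- attach_file(fx$store, e$id, src, "other")
  expect_equal(ref$byte_size, 3)
  oracle <- system2("python",
    c("-c", shQuote(sprintf(
      "import hashlib; print(hashlib.sha256(open(%s,'rb').read()).hexdigest())",
      deparse(src)))), stdout = TRUE)
  expect_identical(ref$checksum, oracle)

  ref2 <- attach_file(fx$store, e$id, src, "other")
  expect_false(ref2$file_id == ref$file_id)
  expect_identical(ref2$checksum, ref$checksum)    # content-address property
  expect_error(attach_file(fx$store, 999L, src, "other"), class = "prodis_not_found_error")
  expect_error(attach_file(fx$store, e$id, tempfile("missing"), "other"),
               class = "prodis_not_found_error")
  prodis_close(fx$store)
})

test_that("get_experiment round-trips records and reflects later writes", {
  fx <- seeded_store()
  smp <- create_sample(fx$store, "extract", organism = "S. mansoni")
  prt <- create_protocol(fx$store, "extraction SOP", "grind, precipitate")
  e <- create_experiment(fx$store, fx$project, "LC", "fractionation", "ana", "2020-03-01",
                         conditions = lc_conditions(instrument = "AKTA", column = "Mono Q",
                                                    solvent_a = "buffer A", flow_rate = 0.5),
                         samples = smp$sample_id, protocol = prt$protocol_id)
  got <- get_experiment(fx$store, e$id)
  expect_identical(got$title, "fractionation")
  expect_identical(got$conditions$fields$instrument, "AKTA")
  expect_equal(got$samples$sample_id, smp$sample_id)
  expect_identical(got$protocol$name, "extraction SOP")

  expect_error(get_experiment(fx$store, 0), class = "prodis_usage_error")
  expect_error(get_experiment(fx$store, 999), class = "prodis_not_found_error")

  src <- tempfile("trace", fileext = ".csv")
  writeLines("Peak,RetentionTime,Height,Area\n1,2.5,10,100", src)
  ref <- attach_file(fx$store, e$id, src, "chromatogram")
  got2 <- get_experiment(fx$store, e$id)
  expect_true(ref$file_id %in% got2$attachments$file_id)  # read-your-writes
  prodis_close(fx$store)
})

test_that("list_experiments orders by id and type filters partition the total", {
  fx <- seeded_store()
  types <- c("PREP", "LC", "GEL2D", "MS", "PREP", "MS", "GEL2D")
  conds <- list(NULL, lc_conditions(), gel_conditions(), ms_conditions(),
                NULL, ms_conditions(), gel_conditions())
  for (i in seq_along(types)) {
    create_experiment(fx$store, fx$project, types[i], sprintf("e%d", i), "ana",
                      "2021-01-01", conditions = conds[[i]])
  }
  all_exp <- list_experiments(fx$store, fx$project)
  expect_false(is.unsorted(all_exp$id, strictly = TRUE))
  counts <- vapply(c("PREP", "LC", "GEL2D", "MS"), function(ty) {
    nrow(list_experiments(fx$store, fx$project, type = ty))
  }, integer(1))
  expect_equal(sum(counts), nrow(all_exp))          # partition over types
  expect_equal(nrow(list_experiments(fx$store, fx$project, type = "LC")), 1L)
  expect_error(list_experiments(fx$store, 42L), class = "prodis_not_found_error")
  prodis_close(fx$store)
})

test_that("attachment checksums re-verify after a close/reopen cycle", {
  fx <- seeded_store()
  e <- create_experiment(fx$store, fx$project, "PREP", "exp", "ana", "2020-01-01")
  for (i in 1:3) {
    src <- tempfile(sprintf("att%d_", i))
    writeLines(sprintf("payload %d", i), src)
    attach_file(fx$store, e$id, src, "other")
  }
  path <- fx$store$path
  prodis_close(fx$store)
  st <- prodis_open(path)
  v <- verify_attachments(st)
  expect_equal(nrow(v), 3L)
  expect_true(all(v$ok))
  prodis_close(st)
})

test_that("id assignment stays unique and monotone under random interleavings of create/get", {
  set.seed(401)
  for (rep in 1:5) {
    fx <- seeded_store()
    ids <- integer()
    for (step in 1:40) {
      if (length(ids) == 0 || runif(1) < 0.6) {
        ids <- c(ids, create_experiment(fx$store, fx$project, "PREP",
                                        sprintf("s%d", step), "ana", "2020-01-01")$id)
      } else {
        probe <- sample(ids, 1)
        expect_equal(get_experiment(fx$store, probe)$id, probe)
      }
    }
    expect_equal(anyDuplicated(ids), 0L)
    expect_true(all(diff(ids) > 0))
    prodis_close(fx$store)
  }
})
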