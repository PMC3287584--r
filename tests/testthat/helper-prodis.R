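# Shared fixtures and independent oracles for the suite.

# Fresh store in a throwaway directory; callers close it themselves or let
# the temp dir vanish with the session.
tmp_store <- function() {
  d <- tempfile("prodis_test_")
  dir.create(d)
  prodis_create(file.path(d, "prodis.db"))
}

# Store with one user and one project, returning both handles.
seeded_store <- function(coordinator = "ana", project = "Proj") {
  st <- tmp_store()
  register_user(st, coordinator, "pw", coordinator)
  prj <- create_project(st, project, "", coordinator)
  list(store = st, project = prj$project_id, coordinator = coordinator)
}

# Store populated with n bare PREP experiments; returns store, project and ids.
store_with_experiments <- function(n) {
  fx <- seeded_store()
  ids <- vapply(seq_len(n), function(i) {
    create_experiment(fx$store, fx$project, "PREP", sprintf("exp %d", i),
                      fx$coordinator, "2020-01-01")$id
  }, integer(1))
  c(fx, list(ids = ids))
}

# Brute-force transitive closure by repeated edge relaxation: the oracle the
# tracking module's reachability queries are checked against.
brute_closure <- function(n, edges) {
  reach <- matrix(FALSE, n, n)
  if (nrow(edges)) reach[cbind(edges$parent, edges$child)] <- TRUE
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Brute-force cycle detector: would adding parent->child to `edges` close a
# cycle? True iff parent is reachable from child.
brute_would_cycle <- function(n, edges, parent, child) {
  if (parent == child) return(TRUE)
  reach <- brute_closure(n, edges)
  isTRUE(reach[child, parent])
}

# Round a double vector through IEEE-754 float32, the precision loss a
# 32-bit binary encoding is allowed to introduce.
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
          n = length(x), size = 4L)
}

# Normalized-spectra comparison with optional float32 slack on peak arrays.
expect_spectra_equal <- function(got, truth, float32 = FALSE) {
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$precursor_mz, truth$precursor_mz)
  expect_equal(got$precursor_charge, truth$precursor_charge)
  for (i in seq_len(nrow(truth))) {
    if (float32) {
      expect_equal(got$peaks[[i]]$mz, as_float32(truth$peaks[[i]]$mz))
      expect_equal(got$peaks[[i]]$intensity, as_float32(truth$peaks[[i]]$intensity))
    } else {
      expect_identical(got$peaks[[i]], truth$peaks[[i]])
    }
  }
}

# The one demo store most tracking/report tests share, built once per run.
demo_env <- new.env(parent = emptyenv())
demo_store <- function() {
  if (is.null(demo_env$store)) {
    d <- tempfile("prodis_demo_")
    dir.create(d)
    demo_env$store <- make_demo_store(d, seed = 1)
  }
  demo_env$store
}
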