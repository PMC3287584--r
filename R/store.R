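#' Create or open a prodis store
#'
#' A store is a single SQLite database file plus a sibling `files/`
#' directory holding attachments (gel images, chromatograms, peak lists)
#' outside the database, with links and checksums kept inside it. The
#' schema is versioned through a metadata row; `prodis_open()` refuses a
#' store written by an incompatible schema version.
#'
#' @param path Path of the database file; its parent directory is created
#'   if needed. The managed file store lives in `files/` next to it.
#' @return A `prodis_store` handle, usable as the first argument of every
#'   other function in the package.
#' @examples
#' st <- prodis_create(file.path(tempdir(), "demo-store", "prodis.db"))
#' register_user(st, "ana", "s3cret", "Ana")
#' prodis_close(st)
#' @export
prodis_create <- function(path) {
  if (file.exists(path)) stop_usage(sprintf("store already exists: %s", path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  store_pragmas(con)
  for (stmt in prodis_schema()) DBI::dbExecute(con, stmt)
  DBI::dbExecute(con, "INSERT INTO meta (key, value) VALUES ('schema_version', '1')")
  st <- new_store(con, path)
  st
}

#' @rdname prodis_create
#' @export
prodis_open <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("store not found: %s", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  store_pragmas(con)
  ver <- tryCatch(
    DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key = 'schema_version'")$value,
    error = function(e) character()
  )
  if (length(ver) != 1L || ver != "1") {
    DBI::dbDisconnect(con)
    stop_format(sprintf("not a prodis store (schema_version %s): %s",
                        if (length(ver)) ver else "missing", path))
  }
  new_store(con, path)
}

#' @rdname prodis_create
#' @param store A `prodis_store` handle.
#' @export
prodis_close <- function(store) {
  check_store(store)
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

# Single-writer desk-scale engine: referential integrity enforced, durability
# relaxed (the store is rebuildable from instrument files; speed matters more
# than crash-proof fsync at every insert).
store_pragmas <- function(con) {
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  DBI::dbExecute(con, "PRAGMA synchronous = OFF")
  DBI::dbGetQuery(con, "PRAGMA journal_mode = MEMORY")
}

new_store <- function(con, path, actor = NULL) {
  structure(
    list(con = con, path = normalizePath(path),
         files_dir = file.path(normalizePath(dirname(path)), "files"),
         actor = actor),
    class = "prodis_store"
  )
}

check_store <- function(store) {
  if (!inherits(store, "prodis_store")) stop_usage("expected a prodis_store handle")
  if (!DBI::dbIsValid(store$con)) stop_usage("store connection is closed")
  invisible(store)
}

#' @export
print.prodis_store <- function(x, ...) {
  n_exp <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM experiments")$n
  n_prj <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM projects")$n
  cat(sprintf("<prodis_store> %s\n  projects: %d  experiments: %d  actor: %s\n",
              x$path, n_prj, n_exp, x$actor %||% "<local mode>"))
  invisible(x)
}

prodis_schema <- function() {
  c(
    "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT NOT NULL)",
    "CREATE TABLE users (
       login TEXT PRIMARY KEY,
       display_name TEXT NOT NULL,
       salt TEXT NOT NULL,
       password_hash TEXT NOT NULL
     )",
    "CREATE TABLE projects (
       project_id INTEGER PRIMARY KEY,
       name TEXT NOT NULL UNIQUE,
       description TEXT NOT NULL DEFAULT '',
       coordinator TEXT NOT NULL REFERENCES users(login),
       guest_visible INTEGER NOT NULL DEFAULT 0
     )",
    "CREATE TABLE publications (
       project_id INTEGER NOT NULL REFERENCES projects(project_id),
       citation TEXT NOT NULL
     )",
    "CREATE TABLE memberships (
       user TEXT NOT NULL REFERENCES users(login),
       project_id INTEGER NOT NULL REFERENCES projects(project_id),
       role TEXT NOT NULL CHECK (role IN ('GUEST','RESEARCHER','COORDINATOR')),
       PRIMARY KEY (user, project_id)
     )",
    "CREATE TABLE samples (
       sample_id INTEGER PRIMARY KEY,
       name TEXT NOT NULL,
       organism TEXT NOT NULL DEFAULT '',
       description TEXT NOT NULL DEFAULT '',
       origin_experiment INTEGER REFERENCES experiments(id)
     )",
    "CREATE TABLE protocols (
       protocol_id INTEGER PRIMARY KEY,
       name TEXT NOT NULL,
       body TEXT NOT NULL DEFAULT '',
       applies_to TEXT NOT NULL DEFAULT ''
     )",
    "CREATE TABLE experiments (
       id INTEGER PRIMARY KEY,
       project_id INTEGER NOT NULL REFERENCES projects(project_id),
       type TEXT NOT NULL CHECK (type IN ('PREP','LC','GEL2D','MS')),
       title TEXT NOT NULL,
       performed_by TEXT NOT NULL REFERENCES users(login),
       date TEXT NOT NULL,
       protocol_id INTEGER REFERENCES protocols(protocol_id),
       conditions TEXT,
       notes TEXT NOT NULL DEFAULT ''
     )",
    "CREATE TABLE experiment_samples (
       experiment_id INTEGER NOT NULL REFERENCES experiments(id),
       sample_id INTEGER NOT NULL REFERENCES samples(sample_id),
       PRIMARY KEY (experiment_id, sample_id)
     )",
    "CREATE TABLE files (
       file_id INTEGER PRIMARY KEY,
       experiment_id INTEGER NOT NULL REFERENCES experiments(id),
       relative_path TEXT NOT NULL,
       original_name TEXT NOT NULL,
       byte_size INTEGER NOT NULL,
       checksum TEXT NOT NULL,
       kind TEXT NOT NULL CHECK (kind IN
         ('gel_image','chromatogram','peak_list','spot_table','ident_result','other')),
       external INTEGER NOT NULL DEFAULT 0
     )",
    "CREATE TABLE spots (
       experiment_id INTEGER NOT NULL REFERENCES experiments(id),
       spot_id TEXT NOT NULL,
       x REAL, y REAL, intensity REAL, volume REAL, area REAL,
       percent_volume REAL, pi REAL, mw REAL,
       PRIMARY KEY (experiment_id, spot_id)
     )",
    "CREATE TABLE edges (
       parent INTEGER NOT NULL REFERENCES experiments(id),
       child INTEGER NOT NULL REFERENCES experiments(id),
       created_order INTEGER NOT NULL,
       PRIMARY KEY (parent, child)
     )",
    "CREATE TABLE audit (
       seq INTEGER PRIMARY KEY,
       user TEXT NOT NULL,
       action TEXT NOT NULL CHECK (action IN
         ('create','update','link','attach','view-denied')),
       experiment INTEGER,
       timestamp TEXT NOT NULL
     )",
    "CREATE TABLE plates (
       plate_id INTEGER PRIMARY KEY,
       ms_experiment INTEGER NOT NULL REFERENCES experiments(id),
       rows INTEGER NOT NULL,
       cols INTEGER NOT NULL
     )",
    "CREATE TABLE wells (
       plate_id INTEGER NOT NULL REFERENCES plates(plate_id),
       well TEXT NOT NULL,
       source_type TEXT NOT NULL CHECK (source_type IN ('gel_spot','sample','calibrant')),
       source_experiment INTEGER,
       source_ref TEXT,
       PRIMARY KEY (plate_id, well)
     )",
    "CREATE TABLE identifications (
       experiment_id INTEGER NOT NULL REFERENCES experiments(id),
       engine TEXT NOT NULL CHECK (engine IN ('mascot','xtandem','omssa')),
       spectrum_ref TEXT NOT NULL,
       accession TEXT NOT NULL,
       description TEXT NOT NULL DEFAULT '',
       score REAL NOT NULL
     )",
    "CREATE TABLE manifests (
       manifest_id INTEGER PRIMARY KEY,
       ms_experiment INTEGER NOT NULL REFERENCES experiments(id),
       engine TEXT NOT NULL,
       params TEXT NOT NULL,
       input_file INTEGER NOT NULL REFERENCES files(file_id),
       created TEXT NOT NULL
     )"
  )
}

db_get <- function(store, sql, ...) {
  p <- list(...)
  if (length(p)) as_tibble(DBI::dbGetQuery(store$con, sql, params = p))
  else as_tibble(DBI::dbGetQuery(store$con, sql))
}

db_exec <- function(store, sql, ...) {
  p <- list(...)
  if (length(p)) DBI::dbExecute(store$con, sql, params = p)
  else DBI::dbExecute(store$con, sql)
}

next_id <- function(store, table, column) {
  v <- DBI::dbGetQuery(store$con,
    sprintf("SELECT COALESCE(MAX(%s), 0) + 1 AS n FROM %s", column, table))$n
  as.integer(v)
}
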