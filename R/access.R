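#' User accounts and authentication
#'
#' Users are identified by a login/password pair. Passwords are stored
#' only as salted, iterated SHA-256 hashes; `authenticate()` deliberately
#' reports one opaque failure for both a wrong login and a wrong
#' password, so an attacker cannot enumerate accounts.
#'
#' @param store A `prodis_store` handle.
#' @param login Unique login name.
#' @param password Clear-text password (hashed before storage).
#' @param display_name Human-readable name.
#' @return `register_user()` returns a one-row tibble describing the
#'   account; `authenticate()` returns an opaque session token string.
#' @export
register_user <- function(store, login, password, display_name = login) {
  check_store(store)
  check_scalar_chr(login, "login")
  check_scalar_chr(password, "password")
  if (nrow(db_get(store, "SELECT login FROM users WHERE login = ?", login)) > 0) {
    stop_usage(sprintf("login already registered: %s", login))
  }
  salt <- random_salt()
  db_exec(store,
    "INSERT INTO users (login, display_name, salt, password_hash) VALUES (?, ?, ?, ?)",
    login, display_name, salt, hash_password(password, salt))
  tibble(login = login, display_name = display_name)
}

#' @rdname register_user
#' @export
authenticate <- function(store, login, password) {
  check_store(store)
  row <- db_get(store, "SELECT salt, password_hash FROM users WHERE login = ?", login)
  ok <- nrow(row) == 1L && identical(hash_password(password, row$salt), row$password_hash)
  if (!ok) stop_auth("authentication failed")
  # Opaque session token; sessions are not persisted (single-process tool).
  sha256_string(paste(login, random_salt(), sep = "|"))
}

#' Act as a user for subsequent operations
#'
#' Returns a copy of the store handle bound to an authenticated user.
#' Operations through a bound handle consult the permission matrix and
#' write audit entries under that login. An unbound handle runs in
#' "local mode" (library embedding, no access control); the CLI always
#' binds an actor unless `--local` is passed.
#'
#' @inheritParams register_user
#' @export
prodis_login <- function(store, login, password) {
  authenticate(store, login, password)
  st <- store
  st$actor <- login
  st
}

role_rank <- function(role) {
  match(role, c("GUEST", "RESEARCHER", "COORDINATOR"))
}

user_exists <- function(store, login) {
  nrow(db_get(store, "SELECT login FROM users WHERE login = ?", login)) == 1L
}

membership_role <- function(store, login, project_id) {
  r <- db_get(store,
    "SELECT role FROM memberships WHERE user = ? AND project_id = ?",
    login, project_id)
  if (nrow(r)) r$role else NA_character_
}

#' Project membership
#'
#' At most one membership per user and project; re-adding a member
#' updates the role. Roles are totally ordered GUEST < RESEARCHER <
#' COORDINATOR and every permission rule is monotone in that order.
#'
#' @inheritParams register_user
#' @param project Project id.
#' @param role One of `"GUEST"`, `"RESEARCHER"`, `"COORDINATOR"`.
#' @export
add_member <- function(store, project, login, role = "RESEARCHER") {
  check_store(store)
  project <- check_id(project, "project")
  if (!user_exists(store, login)) stop_not_found(sprintf("unknown user: %s", login))
  if (!project_exists(store, project)) stop_not_found(sprintf("unknown project: %d", project))
  if (!role %in% c("GUEST", "RESEARCHER", "COORDINATOR")) {
    stop_usage(sprintf("unknown role: %s", role))
  }
  db_exec(store,
    "INSERT INTO memberships (user, project_id, role) VALUES (?, ?, ?)
     ON CONFLICT (user, project_id) DO UPDATE SET role = excluded.role",
    login, project, role)
  tibble(user = login, project = project, role = role)
}

#' Permission decisions
#'
#' The permission matrix, per project: a COORDINATOR member views and
#' edits every experiment of the project; a RESEARCHER member views all
#' of the project's experiments (including teammates') but edits only
#' experiments they performed themselves; a GUEST member — and any user
#' at all, member or not, on a project flagged `guest_visible` — sees
#' only a stub (id, type, title); users with no membership in a
#' non-guest-visible project see nothing. Rights never decrease as the
#' role increases.
#'
#' @inheritParams register_user
#' @param experiment Experiment internal id.
#' @return A one-row tibble with `allowed` (logical), `scope`
#'   (`"full"`, `"stub"` or `NA`) and a human-readable `reason`.
#' @export
can_view <- function(store, login, experiment) {
  check_store(store)
  experiment <- check_id(experiment, "experiment")
  if (!user_exists(store, login)) stop_not_found(sprintf("unknown user: %s", login))
  e <- db_get(store, "SELECT id, project_id FROM experiments WHERE id = ?", experiment)
  if (!nrow(e)) stop_not_found(sprintf("unknown experiment: %d", experiment))
  p <- db_get(store, "SELECT guest_visible FROM projects WHERE project_id = ?", e$project_id)
  role <- membership_role(store, login, e$project_id)
  if (!is.na(role) && role_rank(role) >= role_rank("RESEARCHER")) {
    return(tibble(allowed = TRUE, scope = "full",
                  reason = sprintf("%s member of project %d", role, e$project_id)))
  }
  if (p$guest_visible == 1L) {
    return(tibble(allowed = TRUE, scope = "stub",
                  reason = "guest-level access to a guest-visible project: id/type/title only"))
  }
  tibble(allowed = FALSE, scope = NA_character_,
         reason = "no membership in a non-guest-visible project")
}

#' @rdname can_view
#' @export
can_edit <- function(store, login, experiment) {
  check_store(store)
  experiment <- check_id(experiment, "experiment")
  if (!user_exists(store, login)) stop_not_found(sprintf("unknown user: %s", login))
  e <- db_get(store, "SELECT project_id, performed_by FROM experiments WHERE id = ?", experiment)
  if (!nrow(e)) stop_not_found(sprintf("unknown experiment: %d", experiment))
  role <- membership_role(store, login, e$project_id)
  if (identical(role, "COORDINATOR")) {
    return(tibble(allowed = TRUE, scope = "full",
                  reason = "coordinator updates all data of their project"))
  }
  if (identical(role, "RESEARCHER") && identical(e$performed_by, login)) {
    return(tibble(allowed = TRUE, scope = "full",
                  reason = "researcher updates their own experiment"))
  }
  if (identical(role, "RESEARCHER")) {
    return(tibble(allowed = FALSE, scope = NA_character_,
                  reason = "researchers do not edit teammates' experiments"))
  }
  tibble(allowed = FALSE, scope = NA_character_,
         reason = "no edit rights without researcher or coordinator membership")
}

# Enforcement points used by the store/tracking/report operations.
# actor == NULL means local mode: full rights, actions audited as 'local'.
enforce_view <- function(store, experiment) {
  if (is.null(store$actor)) return("full")
  d <- can_view(store, store$actor, experiment)
  if (!d$allowed) {
    record_action(store, store$actor, "view-denied", experiment)
    stop_permission(sprintf("view denied for %s on experiment %d: %s",
                            store$actor, experiment, d$reason))
  }
  d$scope
}

enforce_edit <- function(store, experiment) {
  if (is.null(store$actor)) return(invisible(TRUE))
  d <- can_edit(store, store$actor, experiment)
  if (!d$allowed) {
    stop_permission(sprintf("edit denied for %s on experiment %d: %s",
                            store$actor, experiment, d$reason))
  }
  invisible(TRUE)
}

actor_or_local <- function(store) store$actor %||% "local"

#' Audit trail
#'
#' Every mutating operation appends exactly one immutable entry recording
#' who did what to which experiment. `audit_log()` is readable by the
#' project's coordinator (or in local mode).
#'
#' @inheritParams register_user
#' @param user Acting login recorded with the entry.
#' @param action One of `create`, `update`, `link`, `attach`,
#'   `view-denied`.
#' @param experiment Optional experiment internal id.
#' @export
record_action <- function(store, user, action, experiment = NULL) {
  check_store(store)
  seq <- next_id(store, "audit", "seq")
  db_exec(store,
    "INSERT INTO audit (seq, user, action, experiment, timestamp) VALUES (?, ?, ?, ?, ?)",
    seq, user, action,
    if (is.null(experiment)) NA_integer_ else as.integer(experiment),
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  tibble(seq = seq, user = user, action = action,
         experiment = if (is.null(experiment)) NA_integer_ else as.integer(experiment))
}

#' @rdname record_action
#' @param project Project id whose trail to read.
#' @export
audit_log <- function(store, project) {
  check_store(store)
  project <- check_id(project, "project")
  if (!project_exists(store, project)) stop_not_found(sprintf("unknown project: %d", project))
  if (!is.null(store$actor)) {
    role <- membership_role(store, store$actor, project)
    if (!identical(role, "COORDINATOR")) {
      stop_permission("audit log is readable by the project coordinator only")
    }
  }
  db_get(store,
    "SELECT a.seq, a.user, a.action, a.experiment, a.timestamp
     FROM audit a LEFT JOIN experiments e ON a.experiment = e.id
     WHERE e.project_id = ? OR (a.experiment IS NULL)
     ORDER BY a.seq", project)
}
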