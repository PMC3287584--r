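# Fixture: two projects, each with a coordinator, two researchers and a
# guest member; one project guest-visible, the other private.
access_fixture <- function(guest_visible = FALSE) {
  st <- tmp_store()
  for (u in c("coord", "res1", "res2", "guestu", "outsider")) register_user(st, u, "pw", u)
  prj <- create_project(st, "Main", "", "coord", guest_visible = guest_visible)
  add_member(st, prj$project_id, "res1", "RESEARCHER")
  add_member(st, prj$project_id, "res2", "RESEARCHER")
  add_member(st, prj$project_id, "guestu", "GUEST")
  own <- create_experiment(st, prj$project_id, "PREP", "res1's own", "res1", "2020-01-01")
  teammate <- create_experiment(st, prj$project_id, "PREP", "res2's work", "res2", "2020-01-02")
  list(store = st, project = prj$project_id, own = own$id, teammate = teammate$id)
}

test_that("registration is unique and authentication fails opaquely on either wrong field", {
  st <- tmp_store()
  register_user(st, "ana", "secret", "Ana")
  expect_error(register_user(st, "ana", "other"), class = "prodis_usage_error")
  expect_type(authenticate(st, "ana", "secret"), "character")
  err_pw <- tryCatch(authenticate(st, "ana", "wrong"), error = conditionMessage)
  err_user <- tryCatch(authenticate(st, "nobody", "wrong"), error = conditionMessage)
  expect_identical(err_pw, err_user)  # does not reveal which field failed
  # passwords are never stored in the clear
  row <- DBI::dbGetQuery(st$con, "SELECT password_hash, salt FROM users WHERE login='ana'")
  expect_false(grepl("secret", row$password_hash, fixed = TRUE))
  expect_true(nchar(row$salt) >= 16)
  prodis_close(st)
})

test_that("the demo guest account authenticates with guest-level access", {
  st <- demo_store()
  expect_type(authenticate(st, "guest", "guest"), "character")
  d <- can_view(st, "guest", 1)
  expect_true(d$allowed)
  expect_equal(d$scope, "stub")
  expect_false(can_edit(st, "guest", 1)$allowed)
})

test_that("the role-by-ownership permission matrix matches the stated policy in all nine cells", {
  fx <- access_fixture(guest_visible = TRUE)
  st <- fx$store
  # Rows: guest member, researcher member, coordinator.
  # Columns: researcher's own experiment, a teammate's, and (below) another
  # project's experiment. Expected: guests see stubs only and edit nothing;
  # researchers see everything in their project but edit only what they
  # performed; coordinators see and edit everything in their project.
  matrix_cases <- list(
    list(user = "guestu", exp = fx$own, view = TRUE, scope = "stub", edit = FALSE),
    list(user = "guestu", exp = fx$teammate, view = TRUE, scope = "stub", edit = FALSE),
    list(user = "res1", exp = fx$own, view = TRUE, scope = "full", edit = TRUE),
    list(user = "res1", exp = fx$teammate, view = TRUE, scope = "full", edit = FALSE),
    list(user = "coord", exp = fx$own, view = TRUE, scope = "full", edit = TRUE),
    list(user = "coord", exp = fx$teammate, view = TRUE, scope = "full", edit = TRUE))
  for (cs in matrix_cases) {
    v <- can_view(st, cs$user, cs$exp)
    e <- can_edit(st, cs$user, cs$exp)
    expect_equal(v$allowed, cs$view, info = paste(cs$user, cs$exp))
    expect_equal(v$scope, cs$scope, info = paste(cs$user, cs$exp))
    expect_equal(e$allowed, cs$edit, info = paste(cs$user, cs$exp))
  }
  # other-project column: members of Main get nothing in a private project
  register_user(st, "coord2", "pw")
  p2 <- create_project(st, "Private", "", "coord2")
  foreign <- create_experiment(st, p2$project_id, "PREP", "private work", "coord2", "2020-02-01")
  for (u in c("guestu", "res1", "coord")) {
    expect_false(can_view(st, u, foreign$id)$allowed)
    expect_false(can_edit(st, u, foreign$id)$allowed)
  }
  prodis_close(st)
})

test_that("rights are monotone in role and non-members see nothing in private projects", {
  fx <- access_fixture(guest_visible = FALSE)
  st <- fx$store
  rank <- c(GUEST = 1, RESEARCHER = 2, COORDINATOR = 3)
  user_of <- c(GUEST = "guestu", RESEARCHER = "res1", COORDINATOR = "coord")
  for (exp in c(fx$own, fx$teammate)) {
    views <- vapply(user_of, function(u) can_view(st, u, exp)$allowed, logical(1))
    edits <- vapply(user_of, function(u) can_edit(st, u, exp)$allowed, logical(1))
    expect_false(is.unsorted(views[order(rank)]))  # allowed never drops as role rises
    expect_false(is.unsorted(edits[order(rank)]))
  }
  expect_false(can_view(st, "outsider", fx$own)$allowed)
  # guest-visible off: even the GUEST member sees nothing
  expect_false(can_view(st, "guestu", fx$own)$allowed)
  prodis_close(st)
})

test_that("visibility is exactly the union of memberships plus guest-visible stubs", {
  st <- tmp_store()
  for (u in c("c1", "c2", "c3", "alice")) register_user(st, u, "pw")
  p_open <- create_project(st, "Open", "", "c1", guest_visible = TRUE)
  p_mine <- create_project(st, "Mine", "", "c2")
  p_priv <- create_project(st, "Priv", "", "c3")
  add_member(st, p_mine$project_id, "alice", "RESEARCHER")
  exps <- list(
    open = create_experiment(st, p_open$project_id, "PREP", "e", "c1", "2020-01-01")$id,
    mine = create_experiment(st, p_mine$project_id, "PREP", "e", "c2", "2020-01-01")$id,
    priv = create_experiment(st, p_priv$project_id, "PREP", "e", "c3", "2020-01-01")$id)
  expect_equal(can_view(st, "alice", exps$mine)$scope, "full")   # membership
  expect_equal(can_view(st, "alice", exps$open)$scope, "stub")   # guest-visible stub
  expect_false(can_view(st, "alice", exps$priv)$allowed)         # everything else hidden
  prodis_close(st)
})

test_that("every mutating call leaves exactly one audit entry, ordered and coordinator-readable", {
  fx <- seeded_store()
  st <- fx$store
  st_auth <- prodis_login(st, "ana", "pw")
  e1 <- create_experiment(st_auth, fx$project, "PREP", "a", "ana", "2020-01-01")
  e2 <- create_experiment(st_auth, fx$project, "PREP", "b", "ana", "2020-01-02")
  link_experiments(st_auth, e1$id, e2$id)
  src <- tempfile(); writeLines("x", src)
  attach_file(st_auth, e1$id, src, "other")
  log <- audit_log(st_auth, fx$project)
  expect_equal(nrow(log), 4L)  # one entry per mutating call in this session
  expect_equal(log$action, c("create", "create", "link", "attach"))
  expect_false(is.unsorted(log$seq, strictly = TRUE))
  expect_true(all(log$user == "ana"))

  register_user(st, "res", "pw")
  add_member(st, fx$project, "res", "RESEARCHER")
  st_res <- prodis_login(st, "res", "pw")
  expect_error(audit_log(st_res, fx$project), class = "prodis_permission_error")
  prodis_close(st)
})

test_that("a bound actor is enforced on reads and writes; denials are audited", {
  fx <- access_fixture(guest_visible = TRUE)
  st <- fx$store
  as_res1 <- prodis_login(st, "res1", "pw")
  expect_error(attach_file(as_res1, fx$teammate, tempfile(), "other"),
               class = "prodis_permission_error")
  register_user(st, "stranger", "pw")
  register_user(st, "coordB", "pw")
  pB <- create_project(st, "B", "", "coordB")
  eB <- create_experiment(st, pB$project_id, "PREP", "hidden", "coordB", "2020-01-01")
  as_stranger <- prodis_login(st, "stranger", "pw")
  expect_error(get_experiment(as_stranger, eB$id), class = "prodis_permission_error")
  denied <- DBI::dbGetQuery(st$con,
    "SELECT COUNT(*) AS n FROM audit WHERE action = 'view-denied' AND user = 'stranger'")
  expect_equal(denied$n, 1L)
  # guest-scope read returns the stub only
  as_guest <- prodis_login(st, "guestu", "pw")
  stub <- get_experiment(as_guest, fx$own)
  expect_true(stub$stub)
  expect_null(stub$performed_by)
  prodis_close(st)
})
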