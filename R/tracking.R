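#' Link two experiments in the provenance graph
#'
#' Experiments are cross-linked parent to child when the products of one
#' are used in another (extraction feeding gels, gel spots feeding an MS
#' run). Links form a directed acyclic graph: an experiment may have
#' several parents (pooling) and several children (splitting), but any
#' link that would close a cycle is rejected at link time by a
#' reachability check. Both endpoints must belong to the same project. A
#' child dated before its parent is allowed but warns — instrument clocks
#' drift and the temporal hint is advisory.
#'
#' @param store A `prodis_store` handle.
#' @param parent,child Experiment internal ids.
#' @return One-row tibble with the stored edge.
#' @export
link_experiments <- function(store, parent, child) {
  check_store(store)
  parent <- check_id(parent, "parent")
  child <- check_id(child, "child")
  if (parent == child) stop_usage(sprintf("cannot link experiment %d to itself", parent))
  for (x in c(parent, child)) {
    if (!experiment_exists(store, x)) stop_not_found(sprintf("unknown experiment: %d", x))
  }
  pp <- db_get(store, "SELECT project_id, date FROM experiments WHERE id = ?", parent)
  cc <- db_get(store, "SELECT project_id, date FROM experiments WHERE id = ?", child)
  if (pp$project_id != cc$project_id) {
    stop_usage(sprintf("cross-project link forbidden: %d and %d are in different projects",
                       parent, child))
  }
  enforce_edit(store, child)
  if (nrow(db_get(store, "SELECT 1 FROM edges WHERE parent = ? AND child = ?", parent, child))) {
    stop_usage(sprintf("duplicate edge %d -> %d", parent, child))
  }
  if (parent %in% reachable_from(store, child)) {
    stop_usage(sprintf("edge %d -> %d would create a cycle", parent, child))
  }
  if (as.Date(cc$date) < as.Date(pp$date)) {
    warn(sprintf("child experiment %d (%s) is dated before parent %d (%s)",
                 child, cc$date, parent, pp$date))
  }
  ord <- next_id(store, "edges", "created_order")
  db_exec(store, "INSERT INTO edges (parent, child, created_order) VALUES (?, ?, ?)",
          parent, child, ord)
  record_action(store, actor_or_local(store), "link", child)
  tibble(parent = parent, child = child, created_order = ord)
}

check_known <- function(store, id) {
  id <- check_id(id, "experiment id")
  if (!experiment_exists(store, id)) stop_not_found(sprintf("unknown experiment: %d", id))
  id
}

#' Neighbours and transitive closure in the provenance graph
#'
#' `parents()`/`children()` return the direct in-/out-neighbours;
#' `ancestors()`/`descendants()` the transitive closure along the edges,
#' excluding the experiment itself. All return sorted integer vectors
#' (empty for isolated experiments).
#'
#' @inheritParams link_experiments
#' @param id Experiment internal id.
#' @export
parents <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  sort(as.integer(db_get(store, "SELECT parent FROM edges WHERE child = ?", id)$parent))
}

#' @rdname parents
#' @export
children <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  sort(as.integer(db_get(store, "SELECT child FROM edges WHERE parent = ?", id)$child))
}

# Breadth-first reachability following `direction` ("down" = child edges).
reachable_from <- function(store, id, direction = c("down", "up")) {
  direction <- match.arg(direction)
  edges <- db_get(store, "SELECT parent, child FROM edges")
  from <- if (direction == "down") edges$parent else edges$child
  to <- if (direction == "down") edges$child else edges$parent
  seen <- integer()
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(to[from %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(as.integer(seen))
}

#' @rdname parents
#' @export
descendants <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  setdiff(reachable_from(store, id, "down"), id)
}

#' @rdname parents
#' @export
ancestors <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  setdiff(reachable_from(store, id, "up"), id)
}

#' Build the experiment tree below a root
#'
#' Depth-first expansion following child edges, children ordered by
#' internal id. When the sub-graph is a DAG with shared nodes (an
#' experiment pooled from several parents), the shared node is repeated
#' under each of its parents — tree semantics, as rendered in reports.
#' Acyclicity bounds the depth, so the expansion always terminates.
#'
#' @inheritParams parents
#' @param root Internal id of the root experiment.
#' @return A nested `prodis_tree` list with fields `id`, `type`, `title`
#'   and `children`.
#' @export
build_tree <- function(store, root) {
  check_store(store)
  root <- check_known(store, root)
  edges <- db_get(store, "SELECT parent, child FROM edges")
  meta <- db_get(store, "SELECT id, type, title FROM experiments")
  expand <- function(id) {
    m <- meta[meta$id == id, ]
    kids <- sort(edges$child[edges$parent == id])
    structure(list(id = as.integer(id), type = m$type, title = m$title,
                   children = lapply(kids, expand)),
              class = "prodis_tree")
  }
  expand(root)
}

#' Serialize an experiment tree
#'
#' Text form is an indented listing, two spaces per depth level, one
#' `<id> [<type>] <title>` line per node; JSON form is the nested list.
#' Both are deterministic: identical stores yield identical bytes.
#'
#' @param tree A `prodis_tree` from [build_tree()].
#' @param format `"text"` or `"json"`.
#' @export
format_tree <- function(tree, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    to_list <- function(node) {
      list(id = node$id, type = node$type, title = node$title,
           children = lapply(node$children, to_list))
    }
    return(as.character(jsonlite::toJSON(to_list(tree), auto_unbox = TRUE, digits = NA)))
  }
  lines <- character()
  walk <- function(node, depth) {
    lines[[length(lines) + 1L]] <<- sprintf("%s%d [%s] %s",
      strrep("  ", depth), node$id, node$type, node$title)
    for (k in node$children) walk(k, depth + 1L)
  }
  walk(tree, 0L)
  paste(lines, collapse = "\n")
}

#' @export
print.prodis_tree <- function(x, ...) {
  cat(format_tree(x), "\n")
  invisible(x)
}

# Flat node listing of a tree with depths; used by reports and tests.
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node, depth) {
    out[[length(out) + 1L]] <<- tibble(id = node$id, depth = depth)
    for (k in node$children) walk(k, depth + 1L)
  }
  walk(tree, 0L)
  bind_rows(out)
}

#' Trace an experiment back to its originating sample(s)
#'
#' Walks the provenance graph upwards to every parentless ancestor — the
#' first experiments in the tree, which carry the sample information —
#' and returns them with their sample references. A parentless
#' experiment traces to itself.
#'
#' @inheritParams parents
#' @return Tibble with one row per (root, sample) pair: `root`,
#'   `root_title`, `sample_id`, `sample_name`, `organism`. Roots without
#'   samples contribute one row with NA sample fields.
#' @export
trace_origin <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  anc <- c(ancestors(store, id), id)
  roots <- sort(purrr::keep(anc, function(a) length(parents(store, a)) == 0L))
  rows <- purrr::map(roots, function(r) {
    e <- get_experiment_unchecked(store, r)
    if (nrow(e$samples)) {
      tibble(root = r, root_title = e$title,
             sample_id = e$samples$sample_id, sample_name = e$samples$name,
             organism = e$samples$organism)
    } else {
      tibble(root = r, root_title = e$title,
             sample_id = NA_integer_, sample_name = NA_character_,
             organism = NA_character_)
    }
  })
  bind_rows(rows)
}
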