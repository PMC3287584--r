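#' Render an experiment report
#'
#' A report collects the experiment's metadata, condition set,
#' attachments and identifications, followed by the experiment tree(s)
#' rooted at the experiment's parentless ancestors (one tree per root,
#' sorted by root id) whenever the experiment participates in any
#' provenance edge. Rendering is deterministic: an identical store
#' yields byte-identical output. Formats: plain text, print-ready HTML
#' (well-formed XHTML), and XML (the [export_record()] document plus a
#' structured tree block).
#'
#' @param store A `prodis_store` handle.
#' @param id Experiment internal id.
#' @param format `"text"`, `"html"` or `"xml"`.
#' @return Character scalar with the rendered document.
#' @export
render_report <- function(store, id, format = c("text", "html", "xml")) {
  check_store(store)
  id <- check_known(store, id)
  if (!format[1] %in% c("text", "html", "xml")) {
    stop_usage(sprintf("unknown report format: %s", format[1]))
  }
  format <- match.arg(format)
  scope <- enforce_view(store, id)
  exp <- get_experiment_unchecked(store, id)
  if (identical(scope, "stub")) {
    # Guest-level access: never render beyond the stub fields.
    txt <- sprintf("EXPERIMENT %d [%s] %s\n(restricted view: guest access)\n",
                   exp$id, exp$type, exp$title)
    return(switch(format, text = txt, html = html_wrap(txt, exp),
                  xml = stub_xml(exp)))
  }
  roots <- report_roots(store, id)
  trees <- purrr::map(roots, function(r) build_tree(store, r))
  if (format == "xml") return(report_xml(store, exp, trees))
  txt <- report_text(store, exp, trees)
  if (format == "text") txt else html_wrap(txt, exp)
}

# Parentless ancestors of id (id itself when parentless), sorted; empty
# when the experiment is isolated (no edges at all).
report_roots <- function(store, id) {
  if (!length(parents(store, id)) && !length(children(store, id))) return(integer())
  anc <- c(ancestors(store, id), id)
  sort(purrr::keep(anc, function(a) length(parents(store, a)) == 0L))
}

report_text <- function(store, exp, trees) {
  prj <- db_get(store, "SELECT name FROM projects WHERE project_id = ?", exp$project_id)
  lines <- c(
    sprintf("EXPERIMENT REPORT: %d", exp$id),
    "=====================",
    sprintf("Title: %s", exp$title),
    sprintf("Type: %s", exp$type),
    sprintf("Project: %s (id %d)", prj$name, exp$project_id),
    sprintf("Performed by: %s", exp$performed_by),
    sprintf("Date: %s", exp$date))
  if (nzchar(exp$notes)) lines <- c(lines, sprintf("Notes: %s", exp$notes))
  if (!is.null(exp$conditions)) {
    f <- exp$conditions$fields
    lines <- c(lines, "", "Conditions:",
               sprintf("  %s: %s", names(f), vapply(f, as.character, character(1))))
  }
  if (nrow(exp$samples)) {
    lines <- c(lines, "", "Samples:",
               sprintf("  [%d] %s (%s)", exp$samples$sample_id, exp$samples$name,
                       exp$samples$organism))
  }
  if (!is.null(exp$protocol)) {
    lines <- c(lines, "", sprintf("Protocol: %s", exp$protocol$name))
  }
  if (nrow(exp$attachments)) {
    a <- exp$attachments
    lines <- c(lines, "", "Attachments:",
               sprintf("  [%d] %s (%s, %d bytes, sha256 %s)",
                       a$file_id, a$original_name, a$kind, a$byte_size, a$checksum))
  }
  if (nrow(exp$identifications)) {
    i <- exp$identifications
    lines <- c(lines, "", "Identifications:",
               sprintf("  %s %s score=%s (%s)", i$engine, i$accession,
                       fmt_num(i$score, 3), i$spectrum_ref))
  }
  if (length(trees)) {
    lines <- c(lines, "", "Experiment tree:")
    for (tr in trees) lines <- c(lines, format_tree(tr))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_wrap <- function(txt, exp) {
  paste0(
    "<html><head><title>", html_escape(sprintf("Experiment %d", exp$id)),
    "</title></head><body><h1>",
    html_escape(sprintf("Experiment %d: %s", exp$id, exp$title)),
    "</h1><pre>", html_escape(txt), "</pre></body></html>\n")
}

tree_to_xml <- function(parent_node, tree) {
  node <- xml2::xml_add_child(parent_node, "node",
                              id = as.character(tree$id), type = tree$type)
  xml2::xml_add_child(node, "title", tree$title)
  for (k in tree$children) tree_to_xml(node, k)
}

report_xml <- function(store, exp, trees) {
  doc <- xml2::xml_new_root("experimentReport")
  rec <- xml2::read_xml(export_record(store, exp$id))
  xml2::xml_add_child(doc, rec)
  if (length(trees)) {
    tl <- xml2::xml_add_child(doc, "experimentTrees")
    for (tr in trees) tree_to_xml(tl, tr)
  }
  as.character(doc)
}

stub_xml <- function(exp) {
  doc <- xml2::xml_new_root("experimentReport", restricted = "true")
  e <- xml2::xml_add_child(doc, "prodisExperiment",
                           id = as.character(exp$id), type = exp$type)
  xml2::xml_add_child(e, "title", exp$title)
  as.character(doc)
}

#' Export an experiment as a transportable XML record
#'
#' One `prodisExperiment` root element; child elements follow the
#' requirement-field order (performer, date, samples, protocol, then
#' conditions), then notes, attachment references with their SHA-256
#' checksums, and identifications. The document is re-importable with
#' [import_record()], and export -> import -> export reproduces the
#' bytes exactly.
#'
#' @inheritParams render_report
#' @return Character scalar of UTF-8 XML.
#' @export
export_record <- function(store, id) {
  check_store(store)
  id <- check_known(store, id)
  exp <- get_experiment_unchecked(store, id)
  doc <- xml2::xml_new_root("prodisExperiment",
                            id = as.character(exp$id), type = exp$type)
  xml2::xml_add_child(doc, "title", exp$title)
  xml2::xml_add_child(doc, "performed_by", exp$performed_by)
  xml2::xml_add_child(doc, "date", exp$date)
  smp <- xml2::xml_add_child(doc, "samples")
  for (i in seq_len(nrow(exp$samples))) {
    xml2::xml_add_child(smp, "sample",
                        name = exp$samples$name[i],
                        organism = exp$samples$organism[i],
                        description = exp$samples$description[i])
  }
  if (!is.null(exp$protocol)) {
    xml2::xml_add_child(doc, "protocol", exp$protocol$body,
                        name = exp$protocol$name,
                        applies_to = exp$protocol$applies_to)
  }
  if (!is.null(exp$conditions)) {
    cnd <- xml2::xml_add_child(doc, "conditions")
    f <- exp$conditions$fields
    for (nm in names(f)) xml2::xml_add_child(cnd, nm, as.character(f[[nm]]))
  }
  if (nzchar(exp$notes)) xml2::xml_add_child(doc, "notes", exp$notes)
  if (nrow(exp$attachments)) {
    att <- xml2::xml_add_child(doc, "attachments")
    a <- exp$attachments
    for (i in seq_len(nrow(a))) {
      xml2::xml_add_child(att, "attachment",
                          name = a$original_name[i], kind = a$kind[i],
                          byte_size = as.character(a$byte_size[i]),
                          checksum = a$checksum[i])
    }
  }
  if (nrow(exp$identifications)) {
    idn <- xml2::xml_add_child(doc, "identifications")
    d <- exp$identifications
    for (i in seq_len(nrow(d))) {
      xml2::xml_add_child(idn, "identification", d$description[i],
                          engine = d$engine[i], spectrum_ref = d$spectrum_ref[i],
                          accession = d$accession[i],
                          score = as.character(d$score[i]))
    }
  }
  as.character(doc)
}

num_or_chr <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v) && grepl("^-?[0-9.eE+]+$", x)) v else x
}

#' Import an exported experiment record
#'
#' Recreates the experiment (with its exported internal id, which must
#' be free) in the target store: samples and protocol are created as
#' needed, conditions are rebuilt from the document, and attachment
#' references are imported as metadata-only (`external`) records — the
#' bytes themselves are not transported, only names, kinds, sizes and
#' checksums.
#'
#' @inheritParams render_report
#' @param xml XML text produced by [export_record()].
#' @param project Target project id; the record's performer must be a
#'   member.
#' @return The imported experiment record.
#' @export
import_record <- function(store, xml, project) {
  check_store(store)
  doc <- read_xml_doc(xml)
  if (xml2::xml_name(doc) != "prodisExperiment") {
    stop_format(sprintf("expected prodisExperiment root, found '%s'", xml2::xml_name(doc)))
  }
  id <- as.integer(xml2::xml_attr(doc, "id"))
  type <- xml2::xml_attr(doc, "type")
  get_text <- function(xp) {
    n <- xml2::xml_find_first(doc, xp)
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  sample_ids <- purrr::map_int(xml2::xml_find_all(doc, "./samples/sample"), function(s) {
    create_sample(store, xml2::xml_attr(s, "name"),
                  organism = xml2::xml_attr(s, "organism"),
                  description = xml2::xml_attr(s, "description"))$sample_id
  })
  prot_node <- xml2::xml_find_first(doc, "./protocol")
  protocol <- if (!inherits(prot_node, "xml_missing")) {
    create_protocol(store, xml2::xml_attr(prot_node, "name"),
                    body = xml2::xml_text(prot_node),
                    applies_to = xml2::xml_attr(prot_node, "applies_to"))$protocol_id
  } else NULL
  cond_node <- xml2::xml_find_first(doc, "./conditions")
  conditions <- if (!inherits(cond_node, "xml_missing")) {
    kids <- xml2::xml_children(cond_node)
    fields <- stats::setNames(lapply(kids, function(k) num_or_chr(xml2::xml_text(k))),
                              vapply(kids, xml2::xml_name, character(1)))
    new_conditions(type, fields)
  } else NULL
  exp <- create_experiment(store, project, type, get_text("./title"),
                           get_text("./performed_by"), get_text("./date"),
                           conditions = conditions, samples = sample_ids,
                           protocol = protocol, notes = get_text("./notes") %||% "",
                           .id = id)
  for (a in xml2::xml_find_all(doc, "./attachments/attachment")) {
    file_id <- next_id(store, "files", "file_id")
    db_exec(store,
      "INSERT INTO files (file_id, experiment_id, relative_path, original_name,
         byte_size, checksum, kind, external) VALUES (?, ?, '', ?, ?, ?, ?, 1)",
      file_id, id, xml2::xml_attr(a, "name"),
      as.numeric(xml2::xml_attr(a, "byte_size")),
      xml2::xml_attr(a, "checksum"), xml2::xml_attr(a, "kind"))
  }
  for (d in xml2::xml_find_all(doc, "./identifications/identification")) {
    db_exec(store,
      "INSERT INTO identifications (experiment_id, engine, spectrum_ref, accession,
         description, score) VALUES (?, ?, ?, ?, ?, ?)",
      id, xml2::xml_attr(d, "engine"), xml2::xml_attr(d, "spectrum_ref"),
      xml2::xml_attr(d, "accession"), xml2::xml_text(d),
      as.numeric(xml2::xml_attr(d, "score")))
  }
  get_experiment_unchecked(store, id)
}
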