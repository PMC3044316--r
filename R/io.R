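# Model serialization: the native JSON dialect and GraphML export.
#
# JSON dialect (documented in the methods vignette and README):
#   {
#     "model_id": "...",
#     "entities":   [ {"id", "class", "displayName", "cellComponent",
#                      "featureTypes": [], "xrefs": ["DB:ACC"], "components": []} ],
#     "processes":  [ {"id", "biologicalEvent", "displayName"} ],
#     "connectors": [ {"id", "role", "process", "entity", "stoichiometry"} ]
#   }
# cellComponent is omitted when absent; stoichiometry is always written.
# Strict mode rejects unknown keys; lax mode (default) preserves them in an
# annotations blob that round-trips.

ENTITY_KEYS <- c("id", "class", "displayName", "cellComponent", "featureTypes",
                 "xrefs", "components")
PROCESS_KEYS <- c("id", "biologicalEvent", "displayName")
CONNECTOR_KEYS <- c("id", "role", "process", "entity", "stoichiometry")

#' Read a pathway model from its JSON dialect
#'
#' @param x A file path or a JSON string.
#' @param strict If `TRUE`, unknown record keys are an error; by default they
#'   are preserved as opaque annotations (simulation attributes such as
#'   initial values and kinetics travel this way and are ignored by all
#'   rules).
#' @return A [pathway_model()]. Unknown vocabulary terms load with a notice,
#'   not an error; structural problems (dangling references, duplicate ids,
#'   a connector end naming the wrong node kind, a process without a
#'   biological event) raise one error listing every offense.
#' @export
read_pathway_model <- function(x, strict = FALSE) {
  txt <- if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      abort(c("Malformed model JSON:", x = conditionMessage(e)),
            class = "pathwaylint_parse_error")
    }
  )
  if (!is.list(doc)) abort("Model document must be a JSON object.",
                           class = "pathwaylint_parse_error")

  grab_annotations <- function(rec, known, kind, strict) {
    extra <- rec[setdiff(names(rec), known)]
    if (strict && length(extra) > 0) {
      abort(sprintf("Unknown key(s) in %s record '%s': %s", kind,
                    rec$id %||% "?", paste(names(extra), collapse = ", ")),
            class = "pathwaylint_parse_error")
    }
    extra
  }

  entities <- bind_rows(lapply(doc$entities, function(r) {
    tibble(
      id = as.character(r$id %||% NA_character_),
      class = as.character(r$class %||% "Entity"),
      display_name = as.character(r$displayName %||% r$id %||% NA_character_),
      cell_component = as.character(r$cellComponent %||% NA_character_),
      feature_types = list(as.character(unlist(r$featureTypes))),
      xrefs = list(as.character(unlist(r$xrefs))),
      components = list(as.character(unlist(r$components))),
      annotations = list(grab_annotations(r, ENTITY_KEYS, "entity", strict))
    )
  }))
  processes <- bind_rows(lapply(doc$processes, function(r) {
    tibble(
      id = as.character(r$id %||% NA_character_),
      biological_event = as.character(r$biologicalEvent %||% NA_character_),
      display_name = as.character(r$displayName %||% r$id %||% NA_character_),
      annotations = list(grab_annotations(r, PROCESS_KEYS, "process", strict))
    )
  }))
  connectors <- bind_rows(lapply(doc$connectors, function(r) {
    tibble(
      id = as.character(r$id %||% NA_character_),
      role = as.character(r$role %||% NA_character_),
      process = as.character(r$process %||% NA_character_),
      entity = as.character(r$entity %||% NA_character_),
      stoichiometry = as.integer(r$stoichiometry %||% 1L),
      annotations = list(grab_annotations(r, CONNECTOR_KEYS, "connector", strict))
    )
  }))

  pathway_model(entities, processes, connectors,
                model_id = doc$model_id %||% "model")
}

#' Write a pathway model to its JSON dialect
#'
#' Output is deterministic: records are sorted by id, keys appear in a fixed
#' order, and defaults (stoichiometry 1) are written explicitly, so two
#' saves of equal models are byte-identical and
#' `read_pathway_model(write_pathway_model(m))` reproduces `m`
#' field-for-field.
#'
#' @param model A [pathway_model()].
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return The JSON text (invisibly when `path` is given).
#' @export
write_pathway_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  ent_rec <- function(i) {
    e <- model$entities[i, ]
    rec <- list(id = e$id, class = e$class, displayName = e$display_name)
    if (!is.na(e$cell_component)) rec$cellComponent <- e$cell_component
    rec$featureTypes <- I(e$feature_types[[1]])
    rec$xrefs <- I(e$xrefs[[1]])
    rec$components <- I(e$components[[1]])
    c(rec, e$annotations[[1]])
  }
  proc_rec <- function(i) {
    p <- model$processes[i, ]
    c(list(id = p$id, biologicalEvent = p$biological_event,
           displayName = p$display_name), p$annotations[[1]])
  }
  conn_rec <- function(i) {
    k <- model$connectors[i, ]
    c(list(id = k$id, role = k$role, process = k$process, entity = k$entity,
           stoichiometry = k$stoichiometry), k$annotations[[1]])
  }
  doc <- list(
    model_id = model$model_id,
    entities = lapply(seq_len(nrow(model$entities)), ent_rec),
    processes = lapply(seq_len(nrow(model$processes)), proc_rec),
    connectors = lapply(seq_len(nrow(model$connectors)), conn_rec)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                          null = "null")
  txt <- paste0(as.character(txt), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Export a pathway model as GraphML
#'
#' Writes standard GraphML for visual inspection in graph viewers: one node
#' per entity (attributes `kind`, `label`, `class`, `cellComponent`) and per
#' process (attributes `kind`, `label`, `event`), one directed edge per
#' connector (attribute `role`; input roles point entity to process, the
#' product role points process to entity).
#'
#' @param model A [pathway_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(model, path) {
  stopifnot(inherits(model, "pathway_model"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keys <- list(
    c("kind", "node"), c("label", "node"), c("class", "node"),
    c("event", "node"), c("cellComponent", "node"), c("role", "edge")
  )
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[1], attr.type = "string")
  }
  g <- xml2::xml_add_child(doc, "graph", id = model$model_id,
                           edgedefault = "directed")
  add_data <- function(node, key, value) {
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- value
  }
  for (i in seq_len(nrow(model$entities))) {
    e <- model$entities[i, ]
    nd <- xml2::xml_add_child(g, "node", id = e$id)
    add_data(nd, "kind", "entity")
    add_data(nd, "label", e$display_name)
    add_data(nd, "class", e$class)
    if (!is.na(e$cell_component)) add_data(nd, "cellComponent", e$cell_component)
  }
  for (i in seq_len(nrow(model$processes))) {
    p <- model$processes[i, ]
    nd <- xml2::xml_add_child(g, "node", id = p$id)
    add_data(nd, "kind", "process")
    add_data(nd, "label", p$display_name)
    add_data(nd, "event", p$biological_event)
  }
  for (i in seq_len(nrow(model$connectors))) {
    k <- model$connectors[i, ]
    ends <- if (k$role == OUTPUT_ROLE) c(k$process, k$entity) else c(k$entity, k$process)
    ed <- xml2::xml_add_child(g, "edge", id = k$id, source = ends[1],
                              target = ends[2])
    add_data(ed, "role", k$role)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
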