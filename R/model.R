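# The pathway model container: a bipartite graph stored as three tibbles.

#' Construct a pathway model
#'
#' A pathway model is a bipartite graph in the place/transition style:
#' entities (molecules) and processes (biological events) form the two node
#' sets, joined by role-typed connectors. `pathway_model()` validates all
#' structural invariants (unique ids, resolving references, bipartiteness by
#' construction, acyclic complex composition, an event term on every
#' process) and returns a canonicalized object with records sorted by id.
#'
#' @param entities A data frame with columns `id`, `class` (one of
#'   [entity_classes()]), `display_name`, `cell_component` (CC term or `NA`),
#'   and list-columns `feature_types`, `xrefs` (strings `"DB:ACCESSION"`),
#'   `components` (entity ids; only `Complex` entities may have components).
#'   Missing optional columns are filled with empty defaults.
#' @param processes A data frame with columns `id`, `biological_event`
#'   (an ME term; required) and `display_name`.
#' @param connectors A data frame with columns `id`, `role` (one of
#'   [connector_roles()]), `process`, `entity`, `stoichiometry` (positive
#'   integer, default 1).
#' @param model_id Character scalar naming the model.
#' @return An object of class `pathway_model`: a list with fields
#'   `model_id`, `entities`, `processes`, `connectors` (tibbles) and
#'   `notices` (character vector of open-vocabulary notices).
#' @export
#' @examples
#' m <- pathway_model(
#'   entities = tibble::tibble(id = c("A", "B"), class = "Protein"),
#'   processes = tibble::tibble(id = "p1", biological_event = "ME_UnknownActivation"),
#'   connectors = tibble::tibble(id = c("c1", "c2"),
#'     role = c("InputProcessBiological", "OutputProcessBiological"),
#'     process = "p1", entity = c("A", "B"))
#' )
#' m
pathway_model <- function(entities = NULL, processes = NULL, connectors = NULL,
                          model_id = "model") {
  entities <- canonical_entities(entities)
  processes <- canonical_processes(processes)
  connectors <- canonical_connectors(connectors)

  offenses <- model_offenses(entities, processes, connectors)
  if (length(offenses) > 0) {
    abort(c("Invalid pathway model:", setNames(offenses, rep("x", length(offenses)))),
          class = "pathwaylint_model_error")
  }

  m <- structure(
    list(
      model_id = as.character(model_id),
      entities = arrange(entities, .data$id),
      processes = arrange(processes, .data$id),
      connectors = arrange(connectors, .data$id),
      notices = vocab_notices(entities, processes)
    ),
    class = "pathway_model"
  )
  m
}

empty_entities <- function() {
  tibble(
    id = character(), class = character(), display_name = character(),
    cell_component = character(), feature_types = list(), xrefs = list(),
    components = list(), annotations = list()
  )
}

empty_processes <- function() {
  tibble(id = character(), biological_event = character(),
         display_name = character(), annotations = list())
}

empty_connectors <- function() {
  tibble(id = character(), role = character(), process = character(),
         entity = character(), stoichiometry = integer(), annotations = list())
}

col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

# empty annotation blobs compare equal regardless of how they were built
norm_ann <- function(ann) {
  lapply(ann, function(a) if (length(a) == 0) list() else a)
}

as_chr_list_col <- function(x, n) {
  if (is.null(x)) return(rep(list(character()), n))
  lapply(x, function(v) if (is.null(v) || length(v) == 0) character() else as.character(v))
}

canonical_entities <- function(entities) {
  if (is.null(entities) || nrow(as_tibble(entities)) == 0) return(empty_entities())
  e <- as_tibble(entities)
  n <- nrow(e)
  ann <- col_or(e, "annotations", NULL)
  tibble(
    id = as.character(e$id),
    class = as.character(col_or(e, "class", rep("Entity", n))),
    display_name = as.character(col_or(e, "display_name", e$id)),
    cell_component = as.character(col_or(e, "cell_component", rep(NA_character_, n))),
    # feature_types and xrefs are sets: stored sorted for determinism
    feature_types = lapply(as_chr_list_col(col_or(e, "feature_types", NULL), n),
                           function(v) sort(unique(v))),
    xrefs = lapply(as_chr_list_col(col_or(e, "xrefs", NULL), n),
                   function(v) sort(unique(v))),
    components = as_chr_list_col(col_or(e, "components", NULL), n),
    annotations = if (is.null(ann)) rep(list(list()), n) else norm_ann(ann)
  )
}

canonical_processes <- function(processes) {
  if (is.null(processes) || nrow(as_tibble(processes)) == 0) return(empty_processes())
  p <- as_tibble(processes)
  n <- nrow(p)
  ann <- col_or(p, "annotations", NULL)
  tibble(
    id = as.character(p$id),
    biological_event = as.character(col_or(p, "biological_event", rep(NA_character_, n))),
    display_name = as.character(col_or(p, "display_name", p$id)),
    annotations = if (is.null(ann)) rep(list(list()), n) else norm_ann(ann)
  )
}

canonical_connectors <- function(connectors) {
  if (is.null(connectors) || nrow(as_tibble(connectors)) == 0) return(empty_connectors())
  k <- as_tibble(connectors)
  n <- nrow(k)
  ann <- col_or(k, "annotations", NULL)
  tibble(
    id = as.character(k$id),
    role = as.character(k$role),
    process = as.character(k$process),
    entity = as.character(k$entity),
    stoichiometry = as.integer(col_or(k, "stoichiometry", rep(1L, n))),
    annotations = if (is.null(ann)) rep(list(list()), n) else norm_ann(ann)
  )
}

# Every structural offense in one pass, so load errors list all problems.
model_offenses <- function(entities, processes, connectors) {
  off <- character()
  dup <- function(ids, kind) {
    d <- unique(ids[duplicated(ids)])
    if (length(d) > 0) sprintf("duplicate %s id: %s", kind, paste(d, collapse = ", "))
  }
  off <- c(off, dup(entities$id, "entity"), dup(processes$id, "process"),
           dup(connectors$id, "connector"))

  both <- intersect(entities$id, processes$id)
  if (length(both) > 0) {
    off <- c(off, sprintf("id used for both an entity and a process: %s",
                          paste(both, collapse = ", ")))
  }

  bad_class <- setdiff(unique(entities$class), ENTITY_CLASSES)
  if (length(bad_class) > 0) {
    off <- c(off, sprintf("unknown entity class: %s", paste(bad_class, collapse = ", ")))
  }

  no_event <- processes$id[is.na(processes$biological_event) |
                             processes$biological_event == ""]
  if (length(no_event) > 0) {
    off <- c(off, sprintf("process without biological_event: %s",
                          paste(no_event, collapse = ", ")))
  }

  bad_role <- connectors$id[!connectors$role %in% CONNECTOR_ROLES]
  if (length(bad_role) > 0) {
    off <- c(off, sprintf("connector with unknown role: %s",
                          paste(bad_role, collapse = ", ")))
  }

  # Bipartiteness / referential integrity: the process end must name a
  # process and the entity end an entity.
  for (i in seq_len(nrow(connectors))) {
    cid <- connectors$id[i]
    p <- connectors$process[i]
    e <- connectors$entity[i]
    if (!p %in% processes$id) {
      off <- c(off, sprintf(
        "connector %s: process end '%s' %s", cid, p,
        if (p %in% entities$id) "names an entity (connectors join one process and one entity)"
        else "does not resolve"))
    }
    if (!e %in% entities$id) {
      off <- c(off, sprintf(
        "connector %s: entity end '%s' %s", cid, e,
        if (e %in% processes$id) "names a process (connectors join one process and one entity)"
        else "does not resolve"))
    }
  }

  bad_st <- connectors$id[is.na(connectors$stoichiometry) | connectors$stoichiometry < 1L]
  if (length(bad_st) > 0) {
    off <- c(off, sprintf("connector with stoichiometry < 1: %s",
                          paste(bad_st, collapse = ", ")))
  }

  # Complex composition: only complexes have components, components resolve,
  # no entity is its own transitive component.
  comp_map <- setNames(entities$components, entities$id)
  for (i in seq_len(nrow(entities))) {
    comps <- entities$components[[i]]
    if (length(comps) == 0) next
    if (entities$class[i] != "Complex") {
      off <- c(off, sprintf("entity %s has components but class %s (only Complex may)",
                            entities$id[i], entities$class[i]))
    }
    missing <- setdiff(comps, entities$id)
    if (length(missing) > 0) {
      off <- c(off, sprintf("entity %s: component id does not resolve: %s",
                            entities$id[i], paste(missing, collapse = ", ")))
    }
  }
  cyc <- composition_cycles(comp_map)
  if (length(cyc) > 0) {
    off <- c(off, sprintf("entity is its own transitive component: %s",
                          paste(cyc, collapse = ", ")))
  }
  off
}

composition_cycles <- function(comp_map) {
  bad <- character()
  for (root in names(comp_map)) {
    seen <- character()
    frontier <- comp_map[[root]]
    while (length(frontier) > 0) {
      if (root %in% frontier) { bad <- c(bad, root); break }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(comp_map[intersect(frontier, names(comp_map))],
                                        use.names = FALSE)), seen)
    }
  }
  bad
}

vocab_notices <- function(entities, processes) {
  notices <- character()
  ev <- setdiff(unique(processes$biological_event), me_vocabulary())
  ev <- ev[!is.na(ev)]
  if (length(ev) > 0) {
    notices <- c(notices, sprintf("unknown biological event term (kept verbatim): %s",
                                  paste(sort(ev), collapse = ", ")))
  }
  ft <- setdiff(unique(unlist(entities$feature_types, use.names = FALSE)),
                ft_vocabulary())
  if (length(ft) > 0) {
    notices <- c(notices, sprintf("unknown feature type term (kept verbatim): %s",
                                  paste(sort(ft), collapse = ", ")))
  }
  cc <- setdiff(unique(entities$cell_component[!is.na(entities$cell_component)]),
                cc_vocabulary())
  if (length(cc) > 0) {
    notices <- c(notices, sprintf("unknown cell component term (kept verbatim): %s",
                                  paste(sort(cc), collapse = ", ")))
  }
  notices
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %s\n", x$model_id))
  cat(sprintf("  entities:   %d\n", nrow(x$entities)))
  cat(sprintf("  processes:  %d\n", nrow(x$processes)))
  cat(sprintf("  connectors: %d\n", nrow(x$connectors)))
  if (length(x$notices) > 0) {
    cat("  notices:\n")
    for (n in x$notices) cat("   -", n, "\n")
  }
  invisible(x)
}

assert_process <- function(model, process_id) {
  if (!process_id %in% model$processes$id) {
    abort(sprintf("Unknown process id: %s", process_id))
  }
}

assert_entity <- function(model, entity_id) {
  if (!entity_id %in% model$entities$id) {
    abort(sprintf("Unknown entity id: %s", entity_id))
  }
}

#' Connectors joining one process/entity pair
#'
#' Returns every connector between the given process and entity, any role,
#' ordered by connector id. A structurally correct model has at most one
#' connector per pair; see [check_valid_connections()].
#'
#' @param model A [pathway_model()].
#' @param process_id,entity_id Node ids; both must resolve.
#' @return A tibble of connector records (possibly zero rows).
#' @export
connectors_between <- function(model, process_id, entity_id) {
  assert_process(model, process_id)
  assert_entity(model, entity_id)
  model$connectors |>
    filter(.data$process == process_id, .data$entity == entity_id) |>
    arrange(.data$id)
}

role_participants <- function(model, process_id, roles) {
  k <- model$connectors |>
    filter(.data$process == process_id, .data$role %in% roles) |>
    arrange(.data$id)
  ents <- model$entities[match(k$entity, model$entities$id), ]
  tibble(
    entity_id = k$entity,
    class = ents$class,
    display_name = ents$display_name,
    cell_component = ents$cell_component,
    feature_types = ents$feature_types,
    xrefs = ents$xrefs,
    components = ents$components,
    connector_id = k$id,
    role = k$role,
    stoichiometry = k$stoichiometry
  )
}

#' Participants of a process, by connector role
#'
#' `has_input()` returns the entities joined to a process through any of the
#' three input roles (substrate, inhibitor, activator); `has_inputprocess()`
#' restricts to substrates (`InputProcessBiological`); `has_output()` to
#' products (`OutputProcessBiological`). An entity appears once per
#' connector, with the connector id, role and stoichiometric coefficient
#' alongside the entity annotation columns.
#'
#' @param model A [pathway_model()].
#' @param process_id A process id; must resolve.
#' @return A tibble with one row per matching connector.
#' @export
has_input <- function(model, process_id) {
  assert_process(model, process_id)
  role_participants(model, process_id, INPUT_ROLES)
}

#' @rdname has_input
#' @export
has_inputprocess <- function(model, process_id) {
  assert_process(model, process_id)
  role_participants(model, process_id, "InputProcessBiological")
}

#' @rdname has_input
#' @export
has_output <- function(model, process_id) {
  assert_process(model, process_id)
  role_participants(model, process_id, OUTPUT_ROLE)
}
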