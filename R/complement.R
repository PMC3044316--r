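# Criterion 3: model complementation for simulation readiness.
#
# Detection always runs on the input model before any mutation
# (simultaneous semantics): adding a binding process for one starting
# complex must not change the starting status of its components mid-pass.

DEGRADABLE_CLASSES <- c("Protein", "Complex", "mRNA", "SmallMolecule")

#' Species that need a synthesized source or sink
#'
#' `find_starting_entities()` returns the non-Complex entities connected to
#' processes only through input-role connectors (isolated entities included:
#' the condition holds vacuously, and an isolated species needs a source
#' before simulation just the same). `find_starting_complexes()` is the same
#' condition restricted to `Complex` entities. `find_degrading_entities()`
#' returns the entities of class Protein/Complex/mRNA/SmallMolecule that are
#' not yet the substrate of an `ME_UnknownDegradation` process (set
#' `include_proteasome = TRUE` to also accept `ME_ProteasomeDegradation` as
#' an existing sink).
#'
#' @param model A [pathway_model()].
#' @param include_proteasome Whether proteasome degradation counts as an
#'   existing degradation process. The printed condition checks only the
#'   unknown-degradation event; the widening is offered as a documented
#'   option.
#' @return A sorted character vector of entity ids.
#' @export
find_starting_entities <- function(model) {
  starting_ids(model, complex = FALSE)
}

#' @rdname find_starting_entities
#' @export
find_starting_complexes <- function(model) {
  starting_ids(model, complex = TRUE)
}

starting_ids <- function(model, complex) {
  e <- model$entities
  keep <- if (complex) e$class == "Complex" else e$class != "Complex"
  produced <- unique(model$connectors$entity[model$connectors$role == OUTPUT_ROLE])
  sort(e$id[keep & !e$id %in% produced])
}

#' @rdname find_starting_entities
#' @export
find_degrading_entities <- function(model, include_proteasome = FALSE) {
  e <- model$entities
  candidates <- e$id[e$class %in% DEGRADABLE_CLASSES]
  sink_events <- "ME_UnknownDegradation"
  if (include_proteasome) sink_events <- c(sink_events, "ME_ProteasomeDegradation")
  sink_procs <- model$processes$id[model$processes$biological_event %in% sink_events]
  degraded <- unique(model$connectors$entity[
    model$connectors$role == "InputProcessBiological" &
      model$connectors$process %in% sink_procs
  ])
  sort(setdiff(candidates, degraded))
}

#' Complement a model with production, binding, and degradation processes
#'
#' Rewrites the model so that every species has a source and every
#' degradable species a sink, the precondition for token-based simulation:
#' each starting entity gains an `ME_UnknownProduction` process with one
#' product connector; each starting complex with recorded components gains
#' an `ME_Binding` process producing it, with one substrate connector per
#' component (a starting complex with no recorded components falls back to
#' unknown production, with a provenance note); each degrading entity gains
#' an `ME_UnknownDegradation` process consuming it. Original nodes are never
#' removed or re-typed, new ids are deterministic functions of the target
#' entity id, and a second pass adds nothing.
#'
#' @param model A [pathway_model()].
#' @param include_proteasome Passed to [find_degrading_entities()].
#' @return A list with `model` (the complemented [pathway_model()]) and
#'   `delta` (a `model_delta`: tibbles `processes` and `connectors` of
#'   added records plus per-addition provenance `notes`).
#' @export
complement_model <- function(model, include_proteasome = FALSE) {
  stopifnot(inherits(model, "pathway_model"))
  starting <- find_starting_entities(model)
  starting_cx <- find_starting_complexes(model)
  degrading <- find_degrading_entities(model, include_proteasome)

  used_ids <- c(model$entities$id, model$processes$id, model$connectors$id)
  fresh <- function(id) {
    while (id %in% used_ids) id <- paste0(id, "_")
    used_ids <<- c(used_ids, id)
    id
  }

  procs <- list(); conns <- list(); notes <- list()
  add_note <- function(target, rule, note) {
    notes[[length(notes) + 1L]] <<- tibble(target_id = target, rule = rule, note = note)
  }
  add_production <- function(eid, rule, note) {
    pid <- fresh(paste0(eid, "__unknown_production"))
    procs[[length(procs) + 1L]] <<- tibble(
      id = pid, biological_event = "ME_UnknownProduction",
      display_name = paste0("production of ", eid))
    conns[[length(conns) + 1L]] <<- tibble(
      id = fresh(paste0(pid, "__out")), role = OUTPUT_ROLE,
      process = pid, entity = eid, stoichiometry = 1L)
    add_note(eid, rule, note)
  }

  for (eid in starting) {
    add_production(eid, "starting_entity",
                   "starting entity: unknown production process added")
  }
  comp_of <- setNames(model$entities$components, model$entities$id)
  for (cid in starting_cx) {
    comps <- comp_of[[cid]]
    if (length(comps) == 0) {
      add_production(cid, "starting_complex",
                     "starting complex without recorded components: fell back to unknown production")
      next
    }
    pid <- fresh(paste0(cid, "__binding"))
    procs[[length(procs) + 1L]] <- tibble(
      id = pid, biological_event = "ME_Binding",
      display_name = paste0("binding forming ", cid))
    conns[[length(conns) + 1L]] <- tibble(
      id = fresh(paste0(pid, "__out")), role = OUTPUT_ROLE,
      process = pid, entity = cid, stoichiometry = 1L)
    for (comp in comps) {
      conns[[length(conns) + 1L]] <- tibble(
        id = fresh(paste0(pid, "__in__", comp)), role = "InputProcessBiological",
        process = pid, entity = comp, stoichiometry = 1L)
    }
    add_note(cid, "starting_complex",
             "starting complex: binding process over its components added")
  }
  for (eid in degrading) {
    pid <- fresh(paste0(eid, "__unknown_degradation"))
    procs[[length(procs) + 1L]] <- tibble(
      id = pid, biological_event = "ME_UnknownDegradation",
      display_name = paste0("degradation of ", eid))
    conns[[length(conns) + 1L]] <- tibble(
      id = fresh(paste0(pid, "__in")), role = "InputProcessBiological",
      process = pid, entity = eid, stoichiometry = 1L)
    add_note(eid, "degrading_entity",
             "degrading entity: unknown degradation process added")
  }

  delta <- structure(
    list(
      processes = if (length(procs)) bind_rows(procs) else
        tibble(id = character(), biological_event = character(),
               display_name = character()),
      connectors = if (length(conns)) bind_rows(conns) else
        tibble(id = character(), role = character(), process = character(),
               entity = character(), stoichiometry = integer()),
      notes = if (length(notes)) bind_rows(notes) else
        tibble(target_id = character(), rule = character(), note = character())
    ),
    class = "model_delta"
  )
  list(model = apply_delta(model, delta), delta = delta)
}

#' Apply a complementation delta to a model
#'
#' Deltas are replayable: applying the delta returned by
#' [complement_model()] to its source model reproduces the complemented
#' model exactly.
#'
#' @param model The source [pathway_model()].
#' @param delta A `model_delta`.
#' @return A [pathway_model()] with the added processes and connectors.
#' @export
apply_delta <- function(model, delta) {
  stopifnot(inherits(model, "pathway_model"), inherits(delta, "model_delta"))
  pathway_model(
    entities = model$entities,
    processes = bind_rows(model$processes,
                          canonical_processes(delta$processes)),
    connectors = bind_rows(model$connectors,
                           canonical_connectors(delta$connectors)),
    model_id = model$model_id
  )
}

#' Serialize or read a complementation delta
#'
#' @param delta A `model_delta`.
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`), or a `model_delta`
#'   for `read_model_delta()`.
#' @export
write_model_delta <- function(delta, path = NULL) {
  stopifnot(inherits(delta, "model_delta"))
  doc <- list(
    added_processes = lapply(seq_len(nrow(delta$processes)), function(i) {
      as.list(delta$processes[i, ])
    }),
    added_connectors = lapply(seq_len(nrow(delta$connectors)), function(i) {
      as.list(delta$connectors[i, ])
    }),
    notes = lapply(seq_len(nrow(delta$notes)), function(i) {
      as.list(delta$notes[i, ])
    })
  )
  txt <- paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' @rdname write_model_delta
#' @param x A file path or JSON string, as written by [write_model_delta()].
#' @export
read_model_delta <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  row_bind <- function(recs, template) {
    if (length(recs) == 0) return(template)
    bind_rows(lapply(recs, as_tibble))
  }
  structure(
    list(
      processes = row_bind(doc$added_processes,
                           tibble(id = character(), biological_event = character(),
                                  display_name = character())),
      connectors = row_bind(doc$added_connectors,
                            tibble(id = character(), role = character(),
                                   process = character(), entity = character(),
                                   stoichiometry = integer())) |>
        mutate(stoichiometry = as.integer(.data$stoichiometry)),
      notes = row_bind(doc$notes, tibble(target_id = character(),
                                         rule = character(), note = character()))
    ),
    class = "model_delta"
  )
}

#' @export
print.model_delta <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<model_delta> +%d processes, +%d connectors\n",
              nrow(x$processes), nrow(x$connectors)))
  cat(sprintf("  unknown production: %d\n  binding:            %d\n  unknown degradation: %d\n",
              s$n_production, s$n_binding, s$n_degradation))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_delta <- function(x, ...) {
  bind_rows(
    mutate(x$processes, kind = "process", .before = 1),
    mutate(select(x$connectors, "id", "role", "process", "entity"),
           kind = "connector", .before = 1)
  ) |> as_tibble()
}

#' @exportS3Method generics::glance
glance.model_delta <- function(x, ...) {
  tibble(
    n_processes = nrow(x$processes),
    n_connectors = nrow(x$connectors),
    n_production = sum(x$processes$biological_event == "ME_UnknownProduction"),
    n_binding = sum(x$processes$biological_event == "ME_Binding"),
    n_degradation = sum(x$processes$biological_event == "ME_UnknownDegradation")
  )
}
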