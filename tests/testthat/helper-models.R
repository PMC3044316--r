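# Small model builders used across the suite. Fixtures are constructed in
# code, never stored on disk.

library(tibble)

# A linear chain A -[substrate]-> P -[product]-> B, both Proteins.
chain_model <- function() {
  pathway_model(
    entities = tibble(id = c("A", "B"), class = "Protein"),
    processes = tibble(id = "p1", biological_event = "ME_UnknownActivation"),
    connectors = tibble(
      id = c("c_in", "c_out"),
      role = c("InputProcessBiological", "OutputProcessBiological"),
      process = "p1", entity = c("A", "B"), stoichiometry = 1L
    ),
    model_id = "chain"
  )
}

# One process of the given event built clean from the shipped constraints.
one_proc <- function(event, ...) make_clean_model(events = event, ...)

# Rebuild a model after tweaking an entity field. For list-valued fields
# pass value wrapped in list().
set_entity_field <- function(model, entity_id, field, value) {
  e <- model$entities
  i <- which(e$id == entity_id)
  stopifnot(length(i) == 1)
  if (field %in% c("feature_types", "xrefs", "components")) {
    e[[field]][[i]] <- value
  } else {
    e[[field]][i] <- value
  }
  pathway_model(e, model$processes, model$connectors, model$model_id)
}

set_connector_field <- function(model, connector_id, field, value) {
  k <- model$connectors
  i <- which(k$id == connector_id)
  stopifnot(length(i) == 1)
  k[[field]][i] <- value
  pathway_model(model$entities, model$processes, k, model$model_id)
}

add_connector <- function(model, id, role, process, entity, stoichiometry = 1L) {
  k <- dplyr::bind_rows(model$connectors,
                        tibble(id = id, role = role, process = process,
                               entity = entity,
                               stoichiometry = as.integer(stoichiometry)))
  pathway_model(model$entities, model$processes, k, model$model_id)
}

add_entity <- function(model, id, class = "Protein", ...) {
  e <- dplyr::bind_rows(model$entities, tibble(id = id, class = class, ...))
  pathway_model(e, model$processes, model$connectors, model$model_id)
}

drop_connectors <- function(model, ids) {
  k <- model$connectors[!model$connectors$id %in% ids, ]
  pathway_model(model$entities, model$processes, k, model$model_id)
}

# Single-process model of a group-3 event with a given coefficient.
stoich_model <- function(event, coefficient) {
  pathway_model(
    entities = tibble(
      id = c("sub", "cplx"), class = c("Protein", "Complex"),
      components = list(character(), "sub")
    ),
    processes = tibble(id = "p1", biological_event = event),
    connectors = tibble(
      id = c("c_in", "c_out"),
      role = c("InputProcessBiological", "OutputProcessBiological"),
      process = "p1", entity = c("sub", "cplx"),
      stoichiometry = c(as.integer(coefficient), 1L)
    ),
    model_id = sprintf("%s_k%d", event, coefficient)
  )
}

# A mixed-event random fixture guaranteed to contain every covered event at
# least once (so every violation category has a host process).
mixed_fixture <- function(seed, extra = 29) {
  evs <- c(covered_events(),
           pathwaylint:::with_rng(seed, function()
             sample(covered_events(), extra, replace = TRUE)))
  make_clean_model(events = evs, seed = seed)
}

category_counts <- function(report) {
  setNames(report$counts_by_category$n, report$counts_by_category$category)
}
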