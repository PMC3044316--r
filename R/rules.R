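# The event-condition-action rule registry.

#' The rule registry
#'
#' Builds the full registry of 40 event-condition-action rules from a
#' constraint table: one structural (criterion 1) condition-action rule, 36
#' reactive criterion-2 rules (each triggered by its biological event), and
#' three criterion-3 condition-action rules whose action mutates the model
#' (see [complement_model()]). Criterion-1 and criterion-2 rules only
#' report.
#'
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @return A tibble with columns `rule_id`, `criterion`, `group`,
#'   `trigger_event`, `action_kind`, `provenance`, `description`, ordered by
#'   criterion, group, and rule id.
#' @export
rule_registry <- function(constraints = default_constraints()) {
  stopifnot(inherits(constraints, "constraint_table"))
  c1 <- tibble(
    rule_id = "C1_VALID_CONNECTION", criterion = 1L, group = NA_integer_,
    trigger_event = NA_character_, action_kind = "report",
    provenance = "paper",
    description = "At most one connector may join a process/entity pair (one role per entity)."
  )
  c2 <- bind_rows(lapply(constraints$constraints, function(cs) {
    tibble(
      rule_id = event_rule_id(cs$event), criterion = 2L, group = cs$group,
      trigger_event = cs$event, action_kind = "report",
      provenance = cs$provenance,
      description = sprintf("Event-specific constraints for %s (group %d).",
                            cs$event, cs$group)
    )
  }))
  c3 <- tibble(
    rule_id = c("C3_STARTING_ENTITY", "C3_STARTING_COMPLEX",
                "C3_DEGRADING_ENTITY"),
    criterion = 3L, group = NA_integer_, trigger_event = NA_character_,
    action_kind = "mutate", provenance = "paper",
    description = c(
      "A non-complex entity never produced gains an unknown production process.",
      "A complex never produced gains a binding process over its components.",
      "A Protein/Complex/mRNA/SmallMolecule without a degradation process gains an unknown degradation process."
    )
  )
  bind_rows(c1, c2, c3) |>
    arrange(.data$criterion, .data$group, .data$rule_id)
}

#' List rules, optionally filtered
#'
#' @param registry A rule registry tibble from [rule_registry()].
#' @param criterion Optional criterion filter (1, 2 or 3).
#' @param group Optional group filter (1-5; only criterion-2 rules carry a
#'   group).
#' @return The filtered registry tibble, in stable order.
#' @export
list_rules <- function(registry = rule_registry(), criterion = NULL,
                       group = NULL) {
  if (!is.null(criterion)) {
    if (!criterion %in% 1:3) abort("`criterion` must be 1, 2 or 3.")
    registry <- filter(registry, .data$criterion == !!as.integer(criterion))
  }
  if (!is.null(group)) {
    if (!group %in% 1:5) abort("`group` must be an integer in 1..5.")
    registry <- filter(registry, !is.na(.data$group),
                       .data$group == !!as.integer(group))
  }
  registry
}

#' Event terms used in a model but covered by no rule
#'
#' Event-specific rules exist only for events with characteristics that
#' distinguish them from other events; processes annotated with any other
#' term (e.g. `ME_Cleavage`, `ME_UnknownInteraction`) are simply not checked
#' by criterion 2 -- they are accounted here, not warned about.
#'
#' @param model A [pathway_model()].
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @return A sorted character vector of uncovered ME terms appearing on the
#'   model's processes.
#' @export
uncovered_events <- function(model, constraints = default_constraints()) {
  stopifnot(inherits(model, "pathway_model"))
  used <- unique(model$processes$biological_event)
  sort(setdiff(used, names(constraints$constraints)))
}
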