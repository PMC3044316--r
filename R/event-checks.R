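# Criterion 2: evaluation of one event constraint against one process.
#
# Clauses are evaluated in a fixed order -- cardinality, type, property,
# relationship -- and a role whose required participants are entirely
# missing suppresses the dependent type/property/relationship clauses on
# that role, so one curation mistake is reported once, not echoed by every
# clause that would have inspected the absent entity.

warning_row <- function(category, rule_id, criterion, process_id, entity_ids,
                        event, message) {
  tibble(
    category = category, rule_id = rule_id, criterion = as.integer(criterion),
    process_id = process_id %||% NA_character_,
    entity_ids = list(as.character(entity_ids)),
    event = event %||% NA_character_, message = message
  )
}

no_warnings <- function() {
  tibble(category = character(), rule_id = character(), criterion = integer(),
         process_id = character(), entity_ids = list(), event = character(),
         message = character())
}

event_rule_id <- function(event) paste0("C2_", sub("^ME_", "", event))

role_of <- function(parts, role) {
  if (role == "input") parts[parts$role %in% INPUT_ROLES, , drop = FALSE]
  else if (role == "inputprocess") parts[parts$role == "InputProcessBiological", , drop = FALSE]
  else parts[parts$role == OUTPUT_ROLE, , drop = FALSE]
}

uniq_ent <- function(p) p[!duplicated(p$entity_id), , drop = FALSE]

ids_sorted <- function(p) sort(unique(p$entity_id))

normalize_xrefs <- function(x) tolower(x)

# Core evaluator over a precomputed participants table (one row per
# connector of the process, entity annotations alongside).
eval_constraint <- function(parts, process_id, event, constraint, feature_map) {
  rid <- event_rule_id(event)
  w <- list()
  emit <- function(category, entity_ids, message) {
    w[[length(w) + 1L]] <<- warning_row(category, rid, 2L, process_id,
                                        entity_ids, event, message)
  }
  by_role <- list(input = role_of(parts, "input"),
                  inputprocess = role_of(parts, "inputprocess"),
                  output = role_of(parts, "output"))
  suppressed <- character()

  # -- cardinality ---------------------------------------------------------
  card <- constraint$cardinalities
  for (i in seq_len(nrow(card))) {
    role <- card$role[i]; mn <- card$min[i]; mx <- card$max[i]
    n <- nrow(by_role[[role]])
    ok <- n >= mn && (is.na(mx) || n <= mx)
    if (ok) next
    if (n == 0L && mn >= 1L) {
      suppressed <- c(suppressed, role)
      cat_code <- switch(role, inputprocess = "MISSING_INPUTPROCESS",
                         output = "MISSING_OUTPUT",
                         input = "WRONG_CARDINALITY_INPUT")
      msg <- sprintf("%s requires at least %d %s entit%s but none is defined.",
                     event, mn, role, if (mn == 1) "y" else "ies")
    } else {
      cat_code <- paste0("WRONG_CARDINALITY_", toupper(role))
      msg <- sprintf("%s requires %s %s entit%s but %d %s connected.",
                     event,
                     if (!is.na(mx) && mx == mn) sprintf("exactly %d", mn)
                     else if (is.na(mx)) sprintf("at least %d", mn)
                     else sprintf("between %d and %d", mn, mx),
                     role, if (identical(mx, 1L) && mn <= 1L) "y" else "ies",
                     n, if (n == 1) "is" else "are")
    }
    emit(cat_code, ids_sorted(by_role[[role]]), msg)
  }
  # A role with zero participants has nothing to inspect downstream even
  # when no cardinality clause fired for it.
  for (role in names(by_role)) {
    if (nrow(by_role[[role]]) == 0L) suppressed <- union(suppressed, role)
  }
  # "input" missing implies its subfamily member "inputprocess" missing too,
  # but not the other way around.
  role_live <- function(role) !(role %in% suppressed)

  # -- type ----------------------------------------------------------------
  types <- constraint$types
  for (i in seq_len(nrow(types))) {
    role <- types$role[i]
    if (!role_live(role)) next
    p <- uniq_ent(by_role[[role]])
    match_cls <- is_a(p$class, types$class[i])
    if (types$quantifier[i] == "all") {
      offenders <- p[!match_cls, ]
    } else {
      offenders <- if (any(match_cls)) p[0, ] else p
    }
    if (nrow(offenders) == 0) next
    cat_code <- if (all(offenders$class == "Entity")) "MISSING_TYPE" else "WRONG_TYPE"
    emit(cat_code, ids_sorted(offenders),
         sprintf("%s requires %s %s entit%s of type %s; offending: %s.",
                 event,
                 if (types$quantifier[i] == "all") "every" else "at least one",
                 role, if (types$quantifier[i] == "all") "y" else "y",
                 types$class[i], paste(ids_sorted(offenders), collapse = ", ")))
  }

  # -- property ------------------------------------------------------------
  for (ps in constraint$properties) {
    role <- ps$role
    if (!role_live(role)) next
    p <- uniq_ent(by_role[[role]])
    if (ps$property == "feature_type") {
      # The modification rules require at least one entity on the role to
      # carry the event's feature term; group 2 terms come from the map.
      term <- if (constraint$group == 2L && event %in% names(feature_map)) {
        unname(feature_map[[event]])
      } else ps$value
      has_term <- map_lgl(p$feature_types, function(ft) term %in% ft)
      if (!any(has_term)) {
        emit("MISSING_FEATURETYPE", ids_sorted(p),
             sprintf("%s requires an %s entity with feature type %s.",
                     event, role, term))
      }
    } else if (ps$property == "cell_component") {
      if (ps$requirement == "must_be_present") {
        missing <- p[is.na(p$cell_component), ]
        if (nrow(missing) > 0) {
          emit("MISSING_CELLCOMPONENT", ids_sorted(missing),
               sprintf("%s requires a cell component on %s entit%s %s.",
                       event, role, "y(ies)",
                       paste(ids_sorted(missing), collapse = ", ")))
        }
      } else {
        allowed <- ps$value
        missing <- p[is.na(p$cell_component), ]
        wrong <- p[!is.na(p$cell_component) & !p$cell_component %in% allowed, ]
        if (nrow(missing) > 0) {
          emit("MISSING_CELLCOMPONENT", ids_sorted(missing),
               sprintf("%s requires cell component %s on the %s entity but none is given (%s).",
                       event, paste(allowed, collapse = " or "), role,
                       paste(ids_sorted(missing), collapse = ", ")))
        }
        if (nrow(wrong) > 0) {
          emit("WRONG_CELLCOMPONENT", ids_sorted(wrong),
               sprintf("%s requires cell component %s on the %s entity; found %s.",
                       event, paste(allowed, collapse = " or "), role,
                       paste(sort(unique(wrong$cell_component)), collapse = ", ")))
        }
      }
    } else if (ps$property == "stoichiometry") {
      conns <- by_role[[role]]
      in_set <- if (ps$requirement == "equals_integer") {
        conns$stoichiometry == ps$value
      } else {
        conns$stoichiometry >= ps$min &
          (is.na(ps$max) | conns$stoichiometry <= ps$max)
      }
      bad <- conns[!in_set, ]
      if (nrow(bad) > 0) {
        expected <- if (ps$requirement == "equals_integer") {
          sprintf("= %d", ps$value)
        } else if (is.na(ps$max)) sprintf(">= %d", ps$min)
        else sprintf("in %d..%d", ps$min, ps$max)
        emit("WRONG_STOICHIOMETRY", ids_sorted(bad),
             sprintf("%s requires stoichiometric coefficient %s on the %s entity; found %s.",
                     event, expected, role,
                     paste(sort(bad$stoichiometry), collapse = ", ")))
      }
    } else if (ps$property == "unification_xref") {
      missing <- p[map_int(p$xrefs, length) == 0L, ]
      if (nrow(missing) > 0) {
        emit("MISSING_UNIFICATIONXREF", ids_sorted(missing),
             sprintf("%s requires a unification xref on %s entit%s %s.",
                     event, role, "y(ies)",
                     paste(ids_sorted(missing), collapse = ", ")))
      }
    }
  }

  # -- relationship --------------------------------------------------------
  for (rs in constraint$relationships) {
    if (!role_live(rs$role_a) || !role_live(rs$role_b)) next
    a <- uniq_ent(by_role[[rs$role_a]])
    b <- uniq_ent(by_role[[rs$role_b]])
    if (rs$property == "unification_xref") {
      pool <- uniq_ent(rbind(a, b))
      missing <- pool[map_int(pool$xrefs, length) == 0L, , drop = FALSE]
      if (nrow(missing) > 0) {
        # No identity comparison is attempted when a side is unidentified.
        emit("MISSING_UNIFICATIONXREF", ids_sorted(missing),
             sprintf("%s compares unification xrefs of %s and %s entities, but %s %s none.",
                     event, rs$role_a, rs$role_b,
                     paste(ids_sorted(missing), collapse = ", "),
                     if (nrow(missing) == 1) "has" else "have"))
        next
      }
      xa <- normalize_xrefs(unlist(a$xrefs, use.names = FALSE))
      xb <- normalize_xrefs(unlist(b$xrefs, use.names = FALSE))
      if (length(intersect(xa, xb)) == 0L) {
        emit("WRONG_UNIFICATIONXREF", sort(unique(c(a$entity_id, b$entity_id))),
             sprintf("%s requires the %s and %s entities to reference the same molecule, but their xrefs are disjoint.",
                     event, rs$role_a, rs$role_b))
      }
    } else { # cell_component, relation 'different'
      pool <- uniq_ent(rbind(a, b))
      missing <- pool[is.na(pool$cell_component), , drop = FALSE]
      if (nrow(missing) > 0) {
        emit("MISSING_CELLCOMPONENT", ids_sorted(missing),
             sprintf("%s compares cell components of %s and %s entities, but %s %s none defined.",
                     event, rs$role_a, rs$role_b,
                     paste(ids_sorted(missing), collapse = ", "),
                     if (nrow(missing) == 1) "has" else "have"))
        next
      }
      same_pairs <- unique(unlist(lapply(seq_len(nrow(a)), function(i) {
        hits <- b$entity_id[b$cell_component == a$cell_component[i]]
        if (length(hits) > 0) c(a$entity_id[i], hits)
      })))
      if (length(same_pairs) > 0 && rs$relation == "different") {
        emit("SAME_CELLCOMPONENT_SHOULD_DIFFER", sort(same_pairs),
             sprintf("%s moves the entity between compartments, but %s and %s entities share the same cell component.",
                     event, rs$role_a, rs$role_b))
      }
    }
  }

  if (length(w) == 0) no_warnings() else bind_rows(w)
}

#' Check one process against an event constraint
#'
#' Evaluates the declarative constraint (cardinality, then type, then
#' property, then relationship clauses) for a single process and returns the
#' violations as warning records. A required participant that is entirely
#' missing is reported once via its cardinality clause; the dependent
#' clauses on that participant are suppressed.
#'
#' @param model A [pathway_model()].
#' @param process_id A process id whose `biological_event` equals
#'   `constraint$event`.
#' @param constraint An `event_constraint` (see [constraint_for_event()]).
#' @param feature_map Event-to-feature-type map used by the group-2
#'   (modification) rules; defaults to [default_feature_map()].
#' @return A tibble of warnings (columns `category`, `rule_id`, `criterion`,
#'   `process_id`, `entity_ids`, `event`, `message`), zero rows when the
#'   process satisfies the constraint.
#' @export
check_event_process <- function(model, process_id, constraint,
                                feature_map = default_feature_map()) {
  assert_process(model, process_id)
  stopifnot(inherits(constraint, "event_constraint"))
  event <- model$processes$biological_event[model$processes$id == process_id]
  if (!identical(event, constraint$event)) {
    abort(sprintf("Process %s has event %s, not %s.", process_id, event,
                  constraint$event))
  }
  parts <- role_participants(model, process_id, CONNECTOR_ROLES)
  eval_constraint(parts, process_id, event, constraint, feature_map)
}

#' Group-specific entry points of the event rules
#'
#' Convenience wrappers over [check_event_process()] that look up the
#' shipped constraint for the process and assert the expected event family:
#' `check_group2()` for the modification rules (exactly one substrate, an
#' output carrying the mapped feature term, matching xrefs; the
#' self-modification event autophosphorylation additionally forbids any
#' further input entity), `check_stoichiometry_event()` for
#' dimerization/oligomerization/polymerization (admissible coefficient sets
#' \{2\}, \{3..20\}, \{21..\}), and `check_internalization()` for the
#' plasma-membrane-to-cytosol movement rule.
#'
#' @inheritParams check_event_process
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @return A tibble of warnings, as [check_event_process()].
#' @export
check_group2 <- function(model, process_id, constraints = default_constraints(),
                         feature_map = default_feature_map()) {
  cs <- process_constraint(model, process_id, constraints, group = 2L)
  event <- cs$event
  if (!event %in% names(feature_map)) {
    config_error(sprintf("no feature-type mapping for %s", event))
  }
  check_event_process(model, process_id, cs, feature_map)
}

#' @rdname check_group2
#' @export
check_stoichiometry_event <- function(model, process_id,
                                      constraints = default_constraints()) {
  cs <- process_constraint(model, process_id, constraints, group = 3L)
  check_event_process(model, process_id, cs)
}

#' @rdname check_group2
#' @export
check_internalization <- function(model, process_id,
                                  constraints = default_constraints()) {
  assert_process(model, process_id)
  event <- model$processes$biological_event[model$processes$id == process_id]
  if (!identical(event, "ME_Internalization")) {
    abort(sprintf("Process %s has event %s; expected ME_Internalization.",
                  process_id, event))
  }
  check_event_process(model, process_id,
                      constraint_for_event("ME_Internalization", constraints))
}

process_constraint <- function(model, process_id, constraints, group = NULL) {
  assert_process(model, process_id)
  event <- model$processes$biological_event[model$processes$id == process_id]
  cs <- constraint_for_event(event, constraints)
  if (is.null(cs)) abort(sprintf("No event constraint defined for %s.", event))
  if (!is.null(group) && cs$group != group) {
    abort(sprintf("%s is a group-%d event, not group %d.", event, cs$group, group))
  }
  cs
}
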