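# Loading and validating the declarative event-constraint table.
#
# A constraint table is a list with two parts: `constraints`, one record per
# biological event (cardinality, type, property, and property-relationship
# clauses), and `feature_map`, the event -> feature-type mapping used by the
# modification (group 2) rules.

VALID_ROLES <- c("input", "inputprocess", "output")
VALID_QUANTIFIERS <- c("all", "at_least_one")
VALID_PROPERTIES <- c("feature_type", "cell_component", "stoichiometry",
                      "unification_xref")
VALID_REQUIREMENTS <- c("equals_term", "in_term_set", "equals_integer",
                        "in_integer_range", "must_be_present")
EXPECTED_GROUP_SIZES <- c(`1` = 11L, `2` = 15L, `3` = 3L, `4` = 3L, `5` = 4L)

config_error <- function(msg, context = NULL) {
  if (!is.null(context)) msg <- sprintf("%s (in constraint for %s)", msg, context)
  abort(msg, class = "pathwaylint_config_error")
}

parse_constraint <- function(rec, default_provenance) {
  ev <- rec$event %||% config_error("constraint record without an event term")
  if (!is.numeric(rec$group %||% NA) || !(rec$group %in% 1:5)) {
    config_error("group must be an integer in 1..5", ev)
  }
  card <- bind_rows(lapply(rec$cardinalities %||% list(), function(cs) {
    if (!(cs$role %||% "") %in% VALID_ROLES) config_error("unknown cardinality role", ev)
    mn <- as.integer(cs$min %||% 0L)
    mx <- if (is.null(cs$max)) NA_integer_ else as.integer(cs$max)
    if (mn < 0 || (!is.na(mx) && mx < mn)) config_error("cardinality must satisfy 0 <= min <= max", ev)
    tibble(role = cs$role, min = mn, max = mx)
  }))
  if (nrow(card) == 0) card <- tibble(role = character(), min = integer(), max = integer())
  types <- bind_rows(lapply(rec$types %||% list(), function(ts) {
    if (!(ts$role %||% "") %in% VALID_ROLES) config_error("unknown type-spec role", ev)
    if (!(ts$class %||% "") %in% ENTITY_CLASSES) config_error("unknown type-spec class", ev)
    if (!(ts$quantifier %||% "") %in% VALID_QUANTIFIERS) config_error("unknown type-spec quantifier", ev)
    tibble(role = ts$role, class = ts$class, quantifier = ts$quantifier)
  }))
  if (nrow(types) == 0) types <- tibble(role = character(), class = character(),
                                        quantifier = character())
  props <- lapply(rec$properties %||% list(), function(ps) {
    if (!(ps$role %||% "") %in% VALID_ROLES) config_error("unknown property-spec role", ev)
    if (!(ps$property %||% "") %in% VALID_PROPERTIES) config_error("unknown property", ev)
    if (!(ps$requirement %||% "") %in% VALID_REQUIREMENTS) config_error("unknown requirement", ev)
    ok <- switch(ps$requirement,
      equals_term = ps$property %in% c("feature_type", "cell_component") &&
        is.character(unlist(ps$value)) && length(unlist(ps$value)) == 1,
      in_term_set = ps$property == "cell_component" &&
        is.character(unlist(ps$value)) && length(unlist(ps$value)) >= 1,
      equals_integer = ps$property == "stoichiometry" && is.numeric(ps$value %||% NA),
      in_integer_range = ps$property == "stoichiometry" && is.numeric(ps$min %||% NA),
      must_be_present = ps$property %in% c("cell_component", "unification_xref")
    )
    if (!isTRUE(ok)) config_error(sprintf("requirement '%s' does not fit property '%s'",
                                          ps$requirement, ps$property), ev)
    list(role = ps$role, property = ps$property, requirement = ps$requirement,
         value = unlist(ps$value) %||% NULL,
         min = if (is.null(ps$min)) NA_integer_ else as.integer(ps$min),
         max = if (is.null(ps$max)) NA_integer_ else as.integer(ps$max))
  })
  rels <- lapply(rec$relationships %||% list(), function(rs) {
    if (!(rs$role_a %||% "") %in% VALID_ROLES || !(rs$role_b %||% "") %in% VALID_ROLES) {
      config_error("unknown relationship role", ev)
    }
    if (!(rs$property %||% "") %in% c("cell_component", "unification_xref")) {
      config_error("relationship property must be cell_component or unification_xref", ev)
    }
    if (!(rs$relation %||% "") %in% c("same", "different")) {
      config_error("relation must be 'same' or 'different'", ev)
    }
    list(role_a = rs$role_a, role_b = rs$role_b, property = rs$property,
         relation = rs$relation)
  })
  structure(
    list(event = ev, group = as.integer(rec$group),
         provenance = rec$provenance %||% default_provenance,
         cardinalities = card, types = types, properties = props,
         relationships = rels),
    class = "event_constraint"
  )
}

#' Load an event-constraint table
#'
#' Reads a JSON constraint table (the format of the shipped
#' `event_constraints.json`; see the methods vignette) into the declarative
#' form the rule engine evaluates. Constraints loaded from a user file
#' without an explicit provenance are tagged `"user"`.
#'
#' @param path Path to a JSON constraint file.
#' @param strict If `TRUE` (default) the table must contain exactly 36
#'   constraints with group sizes 11/15/3/3/4 and a feature map covering
#'   every group-2 event; `strict = FALSE` permits partial tables for
#'   experimentation.
#' @return A `constraint_table`: list with `constraints` (named list of
#'   `event_constraint` records), `feature_map` (named character vector) and
#'   `version`.
#' @export
load_constraint_table <- function(path, strict = TRUE) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) config_error(conditionMessage(e)))
  default_prov <- if (identical(path, shipped_constraint_path())) "synthesized" else "user"
  cons <- lapply(doc$constraints %||% list(), parse_constraint,
                 default_provenance = default_prov)
  events <- map_chr(cons, "event")
  dups <- unique(events[duplicated(events)])
  if (length(dups) > 0) config_error(sprintf("duplicate event: %s", paste(dups, collapse = ", ")))
  names(cons) <- events

  fm <- unlist(doc$feature_map %||% list())
  if (strict) {
    if (length(cons) != 36) {
      config_error(sprintf("strict mode requires exactly 36 event constraints, found %d",
                           length(cons)))
    }
    sizes <- table(factor(map_int(cons, "group"), levels = 1:5))
    if (!all(as.integer(sizes) == EXPECTED_GROUP_SIZES)) {
      config_error(sprintf("strict mode requires group sizes 11/15/3/3/4, found %s",
                           paste(as.integer(sizes), collapse = "/")))
    }
    g2 <- events[map_int(cons, "group") == 2L]
    missing_fm <- setdiff(g2, names(fm))
    if (length(missing_fm) > 0) {
      config_error(sprintf("feature map must cover every group-2 event; missing: %s",
                           paste(missing_fm, collapse = ", ")))
    }
  }
  structure(list(constraints = cons, feature_map = fm,
                 version = doc$version %||% "unversioned"),
            class = "constraint_table")
}

shipped_constraint_path <- function() {
  system.file("extdata", "event_constraints.json", package = "pathwaylint",
              mustWork = TRUE)
}

.constraint_cache <- new.env(parent = emptyenv())

#' The shipped constraint table and feature map
#'
#' `default_constraints()` loads (and caches) the constraint table shipped
#' with the package: 36 event constraints in five groups, each tagged with
#' provenance `"paper"` (printed rules) or `"synthesized"` (defaults
#' reconstructed from the group templates). `default_feature_map()` returns
#' the event-to-feature-type mapping of the modification rules; it is total
#' on group-2 events and not injective (phosphorylation and
#' autophosphorylation both map to `FT_Phosphorylated`).
#'
#' @return A `constraint_table`, or a named character vector for the map.
#' @export
default_constraints <- function() {
  if (is.null(.constraint_cache$table)) {
    .constraint_cache$table <- load_constraint_table(shipped_constraint_path())
  }
  .constraint_cache$table
}

#' @rdname default_constraints
#' @export
default_feature_map <- function() default_constraints()$feature_map

#' Look up the constraint for one biological event
#'
#' @param event An ME term.
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @return An `event_constraint`, or `NULL` when the event has no rule
#'   (an uncovered event, e.g. `ME_Cleavage`).
#' @export
constraint_for_event <- function(event, constraints = default_constraints()) {
  stopifnot(inherits(constraints, "constraint_table"))
  constraints$constraints[[event]]
}

#' @export
print.constraint_table <- function(x, ...) {
  groups <- table(factor(map_int(x$constraints, "group"), levels = 1:5))
  cat(sprintf("<constraint_table> version %s: %d event constraints (groups %s)\n",
              x$version, length(x$constraints),
              paste(as.integer(groups), collapse = "/")))
  invisible(x)
}

#' @export
print.event_constraint <- function(x, ...) {
  cat(sprintf("<event_constraint> %s (group %d, provenance %s)\n",
              x$event, x$group, x$provenance))
  if (nrow(x$cardinalities) > 0) {
    for (i in seq_len(nrow(x$cardinalities))) {
      cc <- x$cardinalities[i, ]
      cat(sprintf("  cardinality %s: %d..%s\n", cc$role, cc$min,
                  ifelse(is.na(cc$max), "*", cc$max)))
    }
  }
  if (nrow(x$types) > 0) {
    for (i in seq_len(nrow(x$types))) {
      tt <- x$types[i, ]
      cat(sprintf("  type %s: %s (%s)\n", tt$role, tt$class, tt$quantifier))
    }
  }
  for (p in x$properties) {
    cat(sprintf("  property %s.%s: %s %s\n", p$role, p$property, p$requirement,
                if (p$requirement == "in_integer_range") {
                  sprintf("[%d, %s]", p$min, ifelse(is.na(p$max), "Inf", p$max))
                } else paste(p$value, collapse = "|")))
  }
  for (r in x$relationships) {
    cat(sprintf("  relationship %s/%s on %s: %s\n", r$role_a, r$role_b,
                r$property, r$relation))
  }
  invisible(x)
}
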