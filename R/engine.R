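# The validation engine: evaluates the rule registry over a model and
# assembles the report.

#' Validate a pathway model against the rule registry
#'
#' Runs the requested criteria over the model and returns a validation
#' report. Criterion 1 applies the structural one-role-per-pair rule to
#' every (process, entity) pair; criterion 2 evaluates, for each process,
#' the event constraint whose trigger event matches the process's
#' biological event (processes whose event has no rule are accounted in the
#' report's `uncovered_events`, not warned about); criterion 3, when
#' requested, reports how many starting entities, starting complexes and
#' degrading entities a complementation pass would touch -- validation never
#' mutates the model, mutation is [complement_model()]'s job.
#'
#' Warnings are ordered by process id, then rule id, then first named
#' entity, and the output is a deterministic function of the model and
#' configuration.
#'
#' @param model A [pathway_model()].
#' @param criteria Subset of `c(1, 2, 3)`.
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @param feature_map Event-to-feature-type map for the group-2 rules.
#' @return A `validation_report`: list with `model_id`, `criteria`,
#'   `warnings` (tibble), `uncovered_events`, `counts_by_category`,
#'   `counts_by_event` (the per-event frequency/warnings/reasons table) and
#'   `criterion3` (addition counts, `NULL` unless criterion 3 was
#'   requested). Use [tidy()] for the warnings, [glance()] for a one-row
#'   summary, [autoplot()] for a category bar chart.
#' @export
validate_pathway <- function(model, criteria = c(1, 2),
                             constraints = default_constraints(),
                             feature_map = default_feature_map()) {
  stopifnot(inherits(model, "pathway_model"))
  criteria <- sort(unique(as.integer(criteria)))
  if (length(criteria) == 0 || !all(criteria %in% 1:3)) {
    abort("`criteria` must be a non-empty subset of {1, 2, 3}.")
  }

  warnings <- list()
  if (1L %in% criteria) warnings$c1 <- check_valid_connections(model)

  uncovered <- character()
  if (2L %in% criteria) {
    uncovered <- uncovered_events(model, constraints)
    parts_all <- participants_by_process(model)
    pids <- sort(model$processes$id)
    events <- model$processes$biological_event[match(pids, model$processes$id)]
    warnings$c2 <- bind_rows(lapply(seq_along(pids), function(i) {
      cs <- constraints$constraints[[events[i]]]
      if (is.null(cs)) return(NULL)
      parts <- parts_all[[pids[i]]] %||% empty_participants()
      eval_constraint(parts, pids[i], events[i], cs, feature_map)
    }))
  }

  w <- bind_rows(warnings)
  if (nrow(w) == 0) w <- no_warnings()
  w <- w |>
    mutate(.first_entity = map_chr(.data$entity_ids,
                                   function(e) if (length(e)) e[1] else "")) |>
    arrange(.data$process_id, .data$rule_id, .data$.first_entity) |>
    select(-".first_entity")

  counts_by_category <- tibble(category = WARNING_CATEGORIES) |>
    left_join(count(w, .data$category), by = "category") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))

  counts_by_event <- event_counts(model, w)

  criterion3 <- NULL
  if (3L %in% criteria) {
    criterion3 <- tibble(
      rule_id = c("C3_STARTING_ENTITY", "C3_STARTING_COMPLEX",
                  "C3_DEGRADING_ENTITY"),
      description = c("starting entities needing an unknown production process",
                      "starting complexes needing a binding process",
                      "degrading entities needing an unknown degradation process"),
      n = c(length(find_starting_entities(model)),
            length(find_starting_complexes(model)),
            length(find_degrading_entities(model)))
    )
  }

  structure(
    list(
      model_id = model$model_id,
      criteria = criteria,
      n_processes = nrow(model$processes),
      n_entities = nrow(model$entities),
      warnings = w,
      uncovered_events = uncovered,
      counts_by_category = counts_by_category,
      counts_by_event = counts_by_event,
      criterion3 = criterion3
    ),
    class = "validation_report"
  )
}

empty_participants <- function() {
  tibble(entity_id = character(), class = character(),
         display_name = character(), cell_component = character(),
         feature_types = list(), xrefs = list(), components = list(),
         connector_id = character(), role = character(),
         stoichiometry = integer())
}

# One join over the whole model, split per process: the per-process
# evaluator then works on small in-memory slices.
participants_by_process <- function(model) {
  k <- arrange(model$connectors, .data$id)
  if (nrow(k) == 0) return(list())
  ents <- model$entities[match(k$entity, model$entities$id), ]
  parts <- data.frame(
    entity_id = k$entity, class = ents$class,
    display_name = ents$display_name, cell_component = ents$cell_component,
    connector_id = k$id, role = k$role, stoichiometry = k$stoichiometry,
    stringsAsFactors = FALSE
  )
  parts$feature_types <- ents$feature_types
  parts$xrefs <- ents$xrefs
  parts$components <- ents$components
  split(parts, k$process)
}

# The per-event marginal table: frequency of the event in the model, number
# of criterion-2 warnings attributed to its processes, and the reasons
# (category counts) collapsed to a stable string.
event_counts <- function(model, w) {
  freq <- count(model$processes, event = .data$biological_event, name = "frequency")
  w2 <- filter(w, .data$criterion == 2L)
  if (nrow(w2) > 0) {
    reasons <- w2 |>
      count(.data$event, .data$category) |>
      arrange(.data$event, .data$category) |>
      group_by(.data$event) |>
      summarise(warnings = sum(.data$n),
                reasons = paste(sprintf("%s (%d)", .data$category, .data$n),
                                collapse = "; "),
                .groups = "drop")
  } else {
    reasons <- tibble(event = character(), warnings = integer(),
                      reasons = character())
  }
  freq |>
    left_join(reasons, by = "event") |>
    mutate(warnings = ifelse(is.na(.data$warnings), 0L, .data$warnings),
           reasons = ifelse(is.na(.data$reasons), "", .data$reasons)) |>
    arrange(.data$event)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (criteria %s)\n", x$model_id,
              paste(x$criteria, collapse = ",")))
  cat(sprintf("  processes: %d, entities: %d\n", x$n_processes, x$n_entities))
  cat(sprintf("  warnings: %d\n", nrow(x$warnings)))
  nz <- filter(x$counts_by_category, .data$n > 0)
  for (i in seq_len(nrow(nz))) {
    cat(sprintf("   - %s: %d\n", nz$category[i], nz$n[i]))
  }
  if (length(x$uncovered_events) > 0) {
    cat(sprintf("  uncovered events (no rule defined): %s\n",
                paste(x$uncovered_events, collapse = ", ")))
  }
  if (!is.null(x$criterion3)) {
    cat("  complementation (criterion 3) would add:\n")
    for (i in seq_len(nrow(x$criterion3))) {
      cat(sprintf("   - %s: %d\n", x$criterion3$rule_id[i], x$criterion3$n[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$warnings

#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble(
    model_id = x$model_id,
    criteria = paste(x$criteria, collapse = ","),
    n_processes = x$n_processes,
    n_entities = x$n_entities,
    n_warnings = nrow(x$warnings),
    n_warned_processes = length(unique(
      x$warnings$process_id[!is.na(x$warnings$process_id)])),
    n_uncovered_events = length(x$uncovered_events)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  dat <- filter(object$counts_by_category, .data$n > 0)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$category, .data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "warnings",
      title = sprintf("Validation warnings for %s", object$model_id)
    ) +
    ggplot2::theme_minimal()
}

#' Write a validation report
#'
#' `write_report_json()` serializes the full report (warnings with entity
#' lists, category and per-event marginals). `write_report_tsv()` writes the
#' per-event table -- columns `event`, `frequency`, `warnings`, `reasons` --
#' the shape in which curated-model validation results are conventionally
#' summarised.
#'
#' @param report A `validation_report`.
#' @param path Output file path; `NULL` returns the text.
#' @return The serialized text, invisibly when written to a file.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  doc <- list(
    model_id = report$model_id,
    criteria = report$criteria,
    n_processes = report$n_processes,
    n_entities = report$n_entities,
    warnings = lapply(seq_len(nrow(report$warnings)), function(i) {
      r <- report$warnings[i, ]
      list(category = r$category, rule_id = r$rule_id, criterion = r$criterion,
           process_id = r$process_id, entity_ids = I(r$entity_ids[[1]]),
           event = r$event, message = r$message)
    }),
    uncovered_events = I(report$uncovered_events),
    counts_by_category = setNames(as.list(report$counts_by_category$n),
                                  report$counts_by_category$category)
  )
  if (!is.null(report$criterion3)) {
    doc$criterion3 <- setNames(as.list(report$criterion3$n),
                               report$criterion3$rule_id)
  }
  txt <- paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                 null = "null"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  tab <- report$counts_by_event
  lines <- c(
    paste(c("event", "frequency", "warnings", "reasons"), collapse = "\t"),
    vapply(seq_len(nrow(tab)), function(i) {
      paste(c(tab$event[i], tab$frequency[i], tab$warnings[i], tab$reasons[i]),
            collapse = "\t")
    }, character(1))
  )
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
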