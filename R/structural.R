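# Criterion 1: the valid-connection rule.

#' Check the one-role-per-pair structural rule
#'
#' An entity may participate in a process with only one role, so a
#' structurally correct model joins each (process, entity) pair by at most
#' one connector; the five valid configurations are listed by
#' [connection_configurations()]. Every pair joined by two or more
#' connectors (any role combination) yields one `INVALID_CONNECTION`
#' warning naming all connectors of the pair as fix candidates. Choosing the
#' correct connector requires understanding of the modeled interaction, so
#' the rule only reports; it never repairs.
#'
#' @param model A [pathway_model()].
#' @return A tibble of warnings, one per violating pair, ordered by process
#'   id then entity id.
#' @export
check_valid_connections <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  k <- model$connectors
  if (nrow(k) == 0) return(no_warnings())
  pairs <- k |>
    group_by(.data$process, .data$entity) |>
    summarise(
      n = n(),
      connector_ids = list(sort(.data$id)),
      roles = list(.data$role[order(.data$id)]),
      .groups = "drop"
    ) |>
    filter(.data$n >= 2L) |>
    arrange(.data$process, .data$entity)
  if (nrow(pairs) == 0) return(no_warnings())
  bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    fix <- paste(sprintf("%s (%s)", p$connector_ids[[1]], p$roles[[1]]),
                 collapse = ", ")
    warning_row(
      "INVALID_CONNECTION", "C1_VALID_CONNECTION", 1L, p$process, p$entity,
      NA_character_,
      sprintf("Entity %s is joined to process %s by %d connectors; keep exactly one of: %s.",
              p$entity, p$process, p$n, fix)
    )
  }))
}
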