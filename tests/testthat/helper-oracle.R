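# Independent brute-force checker used as the oracle for engine equality
# tests: plain nested loops over the model tables and the declarative
# constraint records, sharing no evaluation code with the package engine.
# Returns one row per expected warning (criteria 1 and 2).

oracle_warnings <- function(model, constraints = default_constraints(),
                            feature_map = default_feature_map()) {
  rows <- list()
  add <- function(pid, category) {
    rows[[length(rows) + 1L]] <<- data.frame(process_id = pid,
                                             category = category,
                                             stringsAsFactors = FALSE)
  }
  conns <- model$connectors
  ents <- model$entities
  ent_i <- function(eid) which(ents$id == eid)

  # criterion 1: exhaustive pair count
  for (pid in model$processes$id) {
    for (eid in unique(conns$entity[conns$process == pid])) {
      cnt <- 0L
      for (i in seq_len(nrow(conns))) {
        if (conns$process[i] == pid && conns$entity[i] == eid) cnt <- cnt + 1L
      }
      if (cnt >= 2L) add(pid, "INVALID_CONNECTION")
    }
  }

  input_role_names <- c("InputProcessBiological", "InputInhibitorBiological",
                        "InputAssociationBiological")
  for (j in seq_len(nrow(model$processes))) {
    pid <- model$processes$id[j]
    ev <- model$processes$biological_event[j]
    cs <- constraints$constraints[[ev]]
    if (is.null(cs)) next
    idx <- which(conns$process == pid)
    role_conn <- function(role) {
      keep <- integer()
      for (i in idx) {
        r <- conns$role[i]
        hit <- switch(role,
                      input = r %in% input_role_names,
                      inputprocess = r == "InputProcessBiological",
                      output = r == "OutputProcessBiological")
        if (hit) keep <- c(keep, i)
      }
      keep
    }
    counts <- c(input = length(role_conn("input")),
                inputprocess = length(role_conn("inputprocess")),
                output = length(role_conn("output")))
    suppressed <- names(counts)[counts == 0]
    role_ents <- function(role) unique(conns$entity[role_conn(role)])

    for (ci in seq_len(nrow(cs$cardinalities))) {
      role <- cs$cardinalities$role[ci]
      mn <- cs$cardinalities$min[ci]; mx <- cs$cardinalities$max[ci]
      n <- counts[[role]]
      if (n >= mn && (is.na(mx) || n <= mx)) next
      if (n == 0L && mn >= 1L) {
        add(pid, switch(role, inputprocess = "MISSING_INPUTPROCESS",
                        output = "MISSING_OUTPUT",
                        input = "WRONG_CARDINALITY_INPUT"))
      } else {
        add(pid, paste0("WRONG_CARDINALITY_", toupper(role)))
      }
    }

    for (ti in seq_len(nrow(cs$types))) {
      role <- cs$types$role[ti]
      if (role %in% suppressed) next
      classes <- ents$class[match(role_ents(role), ents$id)]
      fits <- if (cs$types$class[ti] == "Entity") rep(TRUE, length(classes))
              else classes == cs$types$class[ti]
      offenders <- if (cs$types$quantifier[ti] == "all") classes[!fits]
                   else if (any(fits)) character() else classes
      if (length(offenders) == 0) next
      add(pid, if (all(offenders == "Entity")) "MISSING_TYPE" else "WRONG_TYPE")
    }

    for (ps in cs$properties) {
      role <- ps$role
      if (role %in% suppressed) next
      eids <- role_ents(role)
      if (ps$property == "feature_type") {
        term <- if (cs$group == 2 && ev %in% names(feature_map)) {
          unname(feature_map[[ev]])
        } else ps$value
        ok <- FALSE
        for (eid in eids) if (term %in% ents$feature_types[[ent_i(eid)]]) ok <- TRUE
        if (!ok) add(pid, "MISSING_FEATURETYPE")
      } else if (ps$property == "cell_component") {
        ccs <- ents$cell_component[match(eids, ents$id)]
        if (any(is.na(ccs))) add(pid, "MISSING_CELLCOMPONENT")
        if (ps$requirement != "must_be_present" &&
            any(!is.na(ccs) & !ccs %in% ps$value)) {
          add(pid, "WRONG_CELLCOMPONENT")
        }
      } else if (ps$property == "stoichiometry") {
        ks <- conns$stoichiometry[role_conn(role)]
        bad <- if (ps$requirement == "equals_integer") ks != ps$value
               else ks < ps$min | (!is.na(ps$max) & ks > ps$max)
        if (any(bad)) add(pid, "WRONG_STOICHIOMETRY")
      } else if (ps$property == "unification_xref") {
        nx <- vapply(eids, function(eid) length(ents$xrefs[[ent_i(eid)]]), 1L)
        if (any(nx == 0)) add(pid, "MISSING_UNIFICATIONXREF")
      }
    }

    for (rs in cs$relationships) {
      if (rs$role_a %in% suppressed || rs$role_b %in% suppressed) next
      ea <- role_ents(rs$role_a); eb <- role_ents(rs$role_b)
      if (rs$property == "unification_xref") {
        pool <- unique(c(ea, eb))
        nx <- vapply(pool, function(eid) length(ents$xrefs[[ent_i(eid)]]), 1L)
        if (any(nx == 0)) { add(pid, "MISSING_UNIFICATIONXREF"); next }
        xa <- tolower(unlist(ents$xrefs[match(ea, ents$id)]))
        xb <- tolower(unlist(ents$xrefs[match(eb, ents$id)]))
        if (!any(xa %in% xb)) add(pid, "WRONG_UNIFICATIONXREF")
      } else {
        pool <- unique(c(ea, eb))
        if (any(is.na(ents$cell_component[match(pool, ents$id)]))) {
          add(pid, "MISSING_CELLCOMPONENT"); next
        }
        cca <- ents$cell_component[match(ea, ents$id)]
        ccb <- ents$cell_component[match(eb, ents$id)]
        if (rs$relation == "different" && any(outer(cca, ccb, `==`))) {
          add(pid, "SAME_CELLCOMPONENT_SHOULD_DIFFER")
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(process_id = character(), category = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$process_id, out$category), , drop = FALSE]
}

# Engine warnings reduced to the oracle's (process, category) shape.
engine_pairs <- function(report) {
  w <- report$warnings
  out <- data.frame(process_id = w$process_id, category = w$category,
                    stringsAsFactors = FALSE)
  out[order(out$process_id, out$category), , drop = FALSE]
}

expect_matches_oracle <- function(model, ...) {
  report <- validate_pathway(model, criteria = c(1, 2), ...)
  got <- engine_pairs(report)
  want <- oracle_warnings(model, ...)
  rownames(got) <- NULL; rownames(want) <- NULL
  expect_equal(got, want)
}
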