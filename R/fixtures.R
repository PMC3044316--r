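# Synthetic model generation: clean models built constructively from the
# constraint table, targeted single-violation mutants, and the two worked
# correction examples (connector-role misassignment; event-term
# misassignment).
#
# Generation is a pure function of (palette, n, seed): the RNG state is
# saved and restored around every draw, and only integer sampling is used,
# so the same seed yields an identical model everywhere.

# Relative frequencies with which each event occurs in realistic curated
# signal-transduction models; used as sampling weights so random fixtures
# resemble a curation workload (binding, phosphorylation, activation and
# expression dominate). Proportions are approximate by design.
EVENT_WEIGHTS <- c(
  ME_Autocleavage = 2, ME_Binding = 1898, ME_DNABinding = 29,
  ME_DNAReplication = 6, ME_Dissociation = 37, `ME_GDP-GTPExchange` = 4,
  ME_Isomerization = 1, ME_MetabolicReaction = 40,
  ME_ProteasomeDegradation = 34, ME_ProteinCleavage = 5,
  ME_UnknownDegradation = 45, ME_Acetylation = 3, ME_ADPRibosylation = 2,
  ME_Amidation = 1, ME_Glycosylation = 1, ME_Nitrosylation = 2,
  ME_Oxidation = 12, ME_Phosphorylation = 448, ME_Reduction = 1,
  ME_Sumoylation = 2, ME_Ubiquitination = 67, ME_UnknownActivation = 793,
  ME_UnknownInactivation = 6, ME_Autophosphorylation = 12,
  ME_Dephosphorylation = 9, ME_Deubiquitination = 4, ME_Dimerization = 49,
  ME_Oligomerization = 7, ME_Polymerization = 5, ME_Internalization = 9,
  ME_NuclearExport = 4, ME_Translocation = 136, ME_GeneExpression = 721,
  ME_IonTransportThroughIonChannel = 2, ME_Transcription = 13,
  ME_Translation = 364
)

with_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  fn()
}

card_row <- function(cs, role) {
  r <- cs$cardinalities[cs$cardinalities$role == role, ]
  if (nrow(r) > 0) r[1, ] else NULL
}

# Build one satisfying process: entities, connectors, and annotations chosen
# so every clause of the event's constraint holds.
build_clean_process <- function(i, event, cs) {
  pid <- sprintf("p%04d", i)
  mk_id <- function(tag, j) sprintf("e%04d_%s%d", i, tag, j)

  if (is.null(cs)) {
    # Uncovered event: a generic substrate/product pair; no rule inspects it.
    n_ip <- 1L; n_act <- 0L; n_out <- 1L
  } else {
    ip <- card_row(cs, "inputprocess")
    n_ip <- if (!is.null(ip)) max(ip$min, 1L) else 1L
    inp <- card_row(cs, "input")
    n_act <- if (!is.null(inp)) max(0L, inp$min - n_ip) else 0L
    out <- card_row(cs, "output")
    n_out <- if (!is.null(out)) out$min else 1L
  }

  ent <- function(tag, j) {
    tibble(id = mk_id(tag, j), class = "Protein",
           cell_component = NA_character_, feature_types = list(character()),
           xrefs = list(sprintf("TRANSPATH:MO%04d_%s%d", i, tag, j)),
           components = list(character()))
  }
  subs <- if (n_ip > 0) bind_rows(lapply(seq_len(n_ip), function(j) ent("s", j))) else NULL
  acts <- if (n_act > 0) bind_rows(lapply(seq_len(n_act), function(j) ent("a", j))) else NULL
  outs <- if (n_out > 0) bind_rows(lapply(seq_len(n_out), function(j) ent("o", j))) else NULL
  ents <- bind_rows(subs, acts, outs)
  tags <- c(rep("inputprocess", n_ip), rep("activator", n_act), rep("output", n_out))
  of_role <- function(role) {
    which(switch(role,
                 input = tags %in% c("inputprocess", "activator"),
                 inputprocess = tags == "inputprocess",
                 output = tags == "output"))
  }
  stoich <- rep(1L, n_ip)

  if (!is.null(cs)) {
    for (k in seq_len(nrow(cs$types))) {
      ts <- cs$types[k, ]
      idx <- of_role(ts$role)
      if (length(idx) == 0) next
      if (ts$quantifier == "all") ents$class[idx] <- ts$class
      else ents$class[idx[1]] <- ts$class
    }
    for (ps in cs$properties) {
      idx <- of_role(ps$role)
      if (length(idx) == 0 && ps$property != "stoichiometry") next
      if (ps$property == "feature_type") {
        ents$feature_types[[idx[1]]] <- ps$value
      } else if (ps$property == "cell_component") {
        val <- switch(ps$requirement,
                      equals_term = ps$value,
                      in_term_set = ps$value[1],
                      must_be_present = "CC_Cytosol")
        ents$cell_component[idx] <- val
      } else if (ps$property == "stoichiometry") {
        stoich[] <- if (ps$requirement == "equals_integer") as.integer(ps$value)
                    else ps$min
      } else if (ps$property == "unification_xref") {
        # default unique xrefs already satisfy presence
      }
    }
    for (rs in cs$relationships) {
      ia <- of_role(rs$role_a); ib <- of_role(rs$role_b)
      if (length(ia) == 0 || length(ib) == 0) next
      if (rs$property == "unification_xref") {
        shared <- sprintf("TRANSPATH:MO%04d", i)
        for (j in c(ia, ib)) ents$xrefs[[j]] <- shared
      } else if (rs$relation == "different") {
        if (any(is.na(ents$cell_component[ia]))) {
          ents$cell_component[ia][is.na(ents$cell_component[ia])] <- "CC_Cytosol"
        }
        taken <- unique(ents$cell_component[ia])
        alt <- setdiff(CC_TERMS, taken)[1]
        fix <- is.na(ents$cell_component[ib]) | ents$cell_component[ib] %in% taken
        ents$cell_component[ib][fix] <- alt
      }
    }
    # A produced Complex is composed of the substrates that form it.
    for (j in of_role("output")) {
      if (ents$class[j] == "Complex") {
        ents$components[[j]] <- ents$id[of_role("inputprocess")]
      }
    }
  }

  conns <- bind_rows(
    if (n_ip > 0) tibble(
      id = sprintf("%s_cs%d", pid, seq_len(n_ip)),
      role = "InputProcessBiological", process = pid,
      entity = ents$id[tags == "inputprocess"], stoichiometry = stoich),
    if (n_act > 0) tibble(
      id = sprintf("%s_ca%d", pid, seq_len(n_act)),
      role = "InputAssociationBiological", process = pid,
      entity = ents$id[tags == "activator"], stoichiometry = 1L),
    if (n_out > 0) tibble(
      id = sprintf("%s_co%d", pid, seq_len(n_out)),
      role = OUTPUT_ROLE, process = pid,
      entity = ents$id[tags == "output"], stoichiometry = 1L)
  )
  list(
    entities = ents,
    process = tibble(id = pid, biological_event = event, display_name = pid),
    connectors = conns
  )
}

#' Generate a clean synthetic pathway model
#'
#' Builds a model in which every process satisfies its event's shipped
#' constraint, so validation under criteria 1 and 2 yields zero warnings.
#' With `n_processes = NULL` one process per palette event is built in
#' palette order; otherwise events are drawn from the palette with
#' frequencies weighted to resemble a realistic curation workload. Each
#' process gets its own participant entities, so fixtures compose without
#' cross-talk.
#'
#' @param n_processes Number of processes, or `NULL` for one per palette
#'   event.
#' @param events Event palette (default: the 36 rule-covered events).
#' @param seed Integer seed; the same spec always yields the identical
#'   model.
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @param allow_uncovered If `FALSE` (default), a palette event without a
#'   constraint is a generation error; if `TRUE`, such processes are built
#'   as generic substrate/product pairs (useful for exercising
#'   [uncovered_events()]).
#' @return A [pathway_model()].
#' @export
make_clean_model <- function(n_processes = NULL, events = covered_events(),
                             seed = 1L, constraints = default_constraints(),
                             allow_uncovered = FALSE) {
  stopifnot(length(events) > 0)
  unknown <- setdiff(events, names(constraints$constraints))
  if (length(unknown) > 0 && !allow_uncovered) {
    abort(sprintf("No constraint defined for palette event(s): %s (set allow_uncovered = TRUE to build them unchecked)",
                  paste(unknown, collapse = ", ")),
          class = "pathwaylint_generation_error")
  }
  evs <- if (is.null(n_processes)) {
    events
  } else if (n_processes == 0) {
    character()
  } else {
    wts <- EVENT_WEIGHTS[events]
    wts[is.na(wts)] <- 17  # uncovered terms: modest background frequency
    with_rng(seed, function() sample(events, n_processes, replace = TRUE,
                                     prob = wts))
  }
  parts <- lapply(seq_along(evs), function(i) {
    build_clean_process(i, evs[i], constraints$constraints[[evs[i]]])
  })
  pathway_model(
    entities = bind_rows(lapply(parts, `[[`, "entities")),
    processes = bind_rows(lapply(parts, `[[`, "process")),
    connectors = bind_rows(lapply(parts, `[[`, "connectors")),
    model_id = sprintf("fixture_seed%d", seed)
  )
}

wrong_class_for <- function(cls) {
  switch(cls, Protein = "Dna", Dna = "Protein", mRNA = "Protein",
         SmallMolecule = "Protein", Complex = "Protein", Entity = "Protein")
}

#' Inject planned rule violations into a clean model
#'
#' Mutates a clean fixture (one of [make_clean_model()]'s outputs) so that
#' validation detects exactly the planned number of warnings of each
#' category, each on a distinct process, with no masking between
#' injections. The result is verified post hoc by running
#' [validate_pathway()]; a plan the model cannot host (e.g. a stoichiometry
#' violation without any dimerization-family process) is a generation
#' error.
#'
#' @param model A clean [pathway_model()].
#' @param plan Named integer vector or list: `category -> count` over
#'   [warning_categories()].
#' @param seed Integer seed controlling which candidate processes receive
#'   each injection.
#' @param constraints A `constraint_table`; the shipped default if omitted.
#' @return The mutated [pathway_model()].
#' @export
inject_violations <- function(model, plan, seed = 1L,
                              constraints = default_constraints()) {
  stopifnot(inherits(model, "pathway_model"))
  plan <- unlist(plan)
  if (length(plan) == 0) return(model)
  bad <- setdiff(names(plan), WARNING_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown warning category in plan: %s", paste(bad, collapse = ", ")))
  }
  plan <- plan[plan > 0]
  if (length(plan) == 0) return(model)

  ents <- model$entities; procs <- model$processes; conns <- model$connectors
  tab <- constraints$constraints
  used <- character()

  evs_where <- function(pred) names(keep(tab, pred))
  has_card <- function(cs, role) any(cs$cardinalities$role == role)
  card_max <- function(cs, role) {
    r <- cs$cardinalities[cs$cardinalities$role == role, ]
    if (nrow(r) == 0) NA_integer_ else r$max[1]
  }
  card_min <- function(cs, role) {
    r <- cs$cardinalities[cs$cardinalities$role == role, ]
    if (nrow(r) == 0) NA_integer_ else r$min[1]
  }

  candidate_events <- list(
    WRONG_STOICHIOMETRY = evs_where(function(cs)
      any(map_chr(cs$properties, "property") == "stoichiometry")),
    WRONG_CARDINALITY_INPUTPROCESS = evs_where(function(cs)
      !is.na(card_max(cs, "inputprocess")) && !has_card(cs, "input")),
    WRONG_CARDINALITY_OUTPUT = evs_where(function(cs) {
      mx <- card_max(cs, "output")
      !is.na(mx) && isTRUE(card_min(cs, "output") >= 1L)
    }),
    WRONG_CARDINALITY_INPUT = evs_where(function(cs) !is.na(card_max(cs, "input"))),
    MISSING_INPUTPROCESS = evs_where(function(cs)
      isTRUE(card_min(cs, "inputprocess") >= 1L) && !has_card(cs, "input")),
    MISSING_OUTPUT = evs_where(function(cs) isTRUE(card_min(cs, "output") >= 1L)),
    WRONG_TYPE = evs_where(function(cs) nrow(cs$types) > 0),
    MISSING_TYPE = evs_where(function(cs) any(cs$types$quantifier == "all")),
    WRONG_CELLCOMPONENT = evs_where(function(cs)
      any(map_lgl(cs$properties, function(p) p$property == "cell_component" &&
                    p$requirement %in% c("equals_term", "in_term_set")))),
    MISSING_CELLCOMPONENT = evs_where(function(cs)
      any(map_lgl(cs$properties, function(p) p$property == "cell_component"))),
    MISSING_FEATURETYPE = evs_where(function(cs)
      any(map_lgl(cs$properties, function(p) p$property == "feature_type"))),
    MISSING_UNIFICATIONXREF = evs_where(function(cs)
      any(map_lgl(cs$relationships, function(r) r$property == "unification_xref"))),
    WRONG_UNIFICATIONXREF = evs_where(function(cs)
      any(map_lgl(cs$relationships, function(r) r$property == "unification_xref"))),
    SAME_CELLCOMPONENT_SHOULD_DIFFER = evs_where(function(cs)
      any(map_lgl(cs$relationships, function(r)
        r$property == "cell_component" && r$relation == "different"))),
    INVALID_CONNECTION = evs_where(function(cs)
      is.na(card_max(cs, "input")) && isTRUE(card_min(cs, "inputprocess") >= 1L))
  )

  first_conn <- function(pid, role_set) {
    k <- conns[conns$process == pid & conns$role %in% role_set, ]
    k[order(k$id), ][1, ]
  }
  set_entity <- function(eid, field, value) {
    i <- which(ents$id == eid)
    if (field %in% c("feature_types", "xrefs", "components")) {
      ents[[field]][[i]] <<- value
    } else {
      ents[[field]][i] <<- value
    }
  }
  get_entity <- function(eid) ents[ents$id == eid, ]
  clone_entity <- function(eid, tag) {
    e <- get_entity(eid)
    e$id <- paste0(eid, "_", tag)
    ents <<- bind_rows(ents, e)
    e$id
  }

  inject_one <- function(category, pid, k) {
    ev <- procs$biological_event[procs$id == pid]
    cs <- tab[[ev]]
    if (category == "WRONG_STOICHIOMETRY") {
      ps <- cs$properties[[which(map_chr(cs$properties, "property") == "stoichiometry")[1]]]
      bad_val <- if (ps$requirement == "equals_integer") as.integer(ps$value) + 1L
                 else max(1L, ps$min - 1L)
      kc <- first_conn(pid, "InputProcessBiological")
      conns$stoichiometry[conns$id == kc$id] <<- bad_val
    } else if (category == "WRONG_CARDINALITY_INPUTPROCESS") {
      kc <- first_conn(pid, "InputProcessBiological")
      nid <- clone_entity(kc$entity, paste0("dupip", k))
      conns <<- bind_rows(conns, tibble(
        id = paste0(pid, "_inj_ip", k), role = "InputProcessBiological",
        process = pid, entity = nid, stoichiometry = kc$stoichiometry,
        annotations = list(list())))
    } else if (category == "WRONG_CARDINALITY_OUTPUT") {
      kc <- first_conn(pid, OUTPUT_ROLE)
      nid <- clone_entity(kc$entity, paste0("dupout", k))
      conns <<- bind_rows(conns, tibble(
        id = paste0(pid, "_inj_out", k), role = OUTPUT_ROLE,
        process = pid, entity = nid, stoichiometry = 1L,
        annotations = list(list())))
    } else if (category == "WRONG_CARDINALITY_INPUT") {
      kc <- first_conn(pid, "InputProcessBiological")
      nid <- clone_entity(kc$entity, paste0("dupact", k))
      conns <<- bind_rows(conns, tibble(
        id = paste0(pid, "_inj_act", k), role = "InputAssociationBiological",
        process = pid, entity = nid, stoichiometry = 1L,
        annotations = list(list())))
    } else if (category == "MISSING_INPUTPROCESS") {
      conns <<- conns[!(conns$process == pid &
                          conns$role == "InputProcessBiological"), ]
    } else if (category == "MISSING_OUTPUT") {
      conns <<- conns[!(conns$process == pid & conns$role == OUTPUT_ROLE), ]
    } else if (category %in% c("WRONG_TYPE", "MISSING_TYPE")) {
      ts <- if (category == "MISSING_TYPE") {
        cs$types[cs$types$quantifier == "all", ][1, ]
      } else cs$types[1, ]
      role_set <- switch(ts$role, input = INPUT_ROLES,
                         inputprocess = "InputProcessBiological",
                         output = OUTPUT_ROLE)
      # the builder made the first entity of the role conform
      kc <- first_conn(pid, role_set)
      new_cls <- if (category == "MISSING_TYPE") "Entity" else wrong_class_for(ts$class)
      set_entity(kc$entity, "class", new_cls)
      set_entity(kc$entity, "components", character())
    } else if (category == "WRONG_CELLCOMPONENT") {
      ps <- cs$properties[[which(map_lgl(cs$properties, function(p)
        p$property == "cell_component" &&
          p$requirement %in% c("equals_term", "in_term_set")))[1]]]
      role_set <- switch(ps$role, input = INPUT_ROLES,
                         inputprocess = "InputProcessBiological",
                         output = OUTPUT_ROLE)
      kc <- first_conn(pid, role_set)
      set_entity(kc$entity, "cell_component", setdiff(CC_TERMS, ps$value)[1])
    } else if (category == "MISSING_CELLCOMPONENT") {
      ps <- cs$properties[[which(map_lgl(cs$properties, function(p)
        p$property == "cell_component"))[1]]]
      role_set <- switch(ps$role, input = INPUT_ROLES,
                         inputprocess = "InputProcessBiological",
                         output = OUTPUT_ROLE)
      kc <- first_conn(pid, role_set)
      set_entity(kc$entity, "cell_component", NA_character_)
    } else if (category == "MISSING_FEATURETYPE") {
      kc <- first_conn(pid, OUTPUT_ROLE)
      set_entity(kc$entity, "feature_types", character())
    } else if (category == "MISSING_UNIFICATIONXREF") {
      kc <- first_conn(pid, "InputProcessBiological")
      set_entity(kc$entity, "xrefs", character())
    } else if (category == "WRONG_UNIFICATIONXREF") {
      out_conns <- conns[conns$process == pid & conns$role == OUTPUT_ROLE, ]
      for (eid in out_conns$entity) {
        set_entity(eid, "xrefs", sprintf("TRANSPATH:ALT_%s_%d", pid, k))
      }
    } else if (category == "SAME_CELLCOMPONENT_SHOULD_DIFFER") {
      kin <- first_conn(pid, "InputProcessBiological")
      kout <- first_conn(pid, OUTPUT_ROLE)
      cc_in <- get_entity(kin$entity)$cell_component
      set_entity(kout$entity, "cell_component", cc_in)
    } else if (category == "INVALID_CONNECTION") {
      kc <- first_conn(pid, "InputProcessBiological")
      conns <<- bind_rows(conns, tibble(
        id = paste0(pid, "_inj_dup", k), role = "InputAssociationBiological",
        process = pid, entity = kc$entity, stoichiometry = 1L,
        annotations = list(list())))
    }
  }

  with_rng(seed, function() {
    for (category in sort(names(plan))) {
      cand_evs <- candidate_events[[category]]
      for (k in seq_len(plan[[category]])) {
        cands <- setdiff(
          procs$id[procs$biological_event %in% cand_evs], used)
        if (length(cands) == 0) {
          abort(sprintf("Plan not achievable: no remaining process can host a %s violation.",
                        category),
                class = "pathwaylint_generation_error")
        }
        pid <- if (length(cands) == 1) cands else sample(cands, 1)
        used <<- c(used, pid)
        inject_one(category, pid, k)
      }
    }
  })

  out <- pathway_model(ents, procs, conns, model_id = model$model_id)
  report <- validate_pathway(out, criteria = c(1, 2), constraints = constraints)
  got <- setNames(report$counts_by_category$n, report$counts_by_category$category)
  ok <- all(got[names(plan)] == unname(plan)) && sum(got) == sum(plan)
  if (!ok) {
    abort("Injection verification failed: detected warnings do not match the plan.",
          class = "pathwaylint_generation_error")
  }
  out
}

#' The two worked correction examples
#'
#' Reconstructs two archetypal curation mistakes as paired fixtures.
#' Case 1 (connector-role misassignment): an unknown-activation process in
#' which activated Ras was drawn as a second substrate of Raf1 activation;
#' the cardinality rule flags the extra substrate, and the fix re-wires Ras
#' through an activator connector. Case 2 (event-term misassignment): a
#' "dimerization" joining two different molecules (an M-CSF:receptor
#' complex and a further receptor); dimerization admits a single substrate,
#' and the fix relabels the process as a binding event. Non-focal
#' annotations (xrefs, features, stoichiometry) are chosen to satisfy all
#' other clauses so each uncorrected model yields exactly the focal
#' warning.
#'
#' @return A named list of four [pathway_model()]s: `case1`, `case1_fixed`,
#'   `case2`, `case2_fixed`.
#' @export
make_case_models <- function() {
  case1_entities <- tibble(
    id = c("ras_active", "raf1", "raf1_active"),
    class = "Protein",
    display_name = c("Ras{active}", "Raf1", "Raf1{active}"),
    feature_types = list(c("FT_Active"), character(), c("FT_Active")),
    xrefs = list("TRANSPATH:MO_RAS", "TRANSPATH:MO_RAF1", "TRANSPATH:MO_RAF1")
  )
  case1_process <- tibble(id = "p_activation",
                          biological_event = "ME_UnknownActivation",
                          display_name = "Raf1 activation")
  mk_case1 <- function(ras_role, model_id) {
    pathway_model(
      entities = case1_entities,
      processes = case1_process,
      connectors = tibble(
        id = c("c_raf1_in", "c_ras_in", "c_raf1_out"),
        role = c("InputProcessBiological", ras_role, OUTPUT_ROLE),
        process = "p_activation",
        entity = c("raf1", "ras_active", "raf1_active"),
        stoichiometry = 1L
      ),
      model_id = model_id
    )
  }

  case2_entities <- tibble(
    id = c("mcsf2_mcsfr", "mcsfr", "mcsf2_mcsfr2"),
    class = c("Complex", "Protein", "Complex"),
    display_name = c("M-CSF(2):M-CSF-1-R", "M-CSF-1-R", "M-CSF(2):M-CSF-1-R(2)"),
    xrefs = list("TRANSPATH:MO_MCSF_CPLX", "TRANSPATH:MO_MCSFR",
                 "TRANSPATH:MO_MCSF_CPLX2"),
    components = list(character(), character(), c("mcsf2_mcsfr", "mcsfr"))
  )
  mk_case2 <- function(event, model_id) {
    pathway_model(
      entities = case2_entities,
      processes = tibble(id = "p_complexation", biological_event = event,
                         display_name = "receptor complex formation"),
      connectors = tibble(
        id = c("c_cplx_in", "c_recep_in", "c_cplx_out"),
        role = c("InputProcessBiological", "InputProcessBiological", OUTPUT_ROLE),
        process = "p_complexation",
        entity = c("mcsf2_mcsfr", "mcsfr", "mcsf2_mcsfr2"),
        stoichiometry = c(2L, 2L, 1L)
      ),
      model_id = model_id
    )
  }

  list(
    case1 = mk_case1("InputProcessBiological", "case1_original"),
    case1_fixed = mk_case1("InputAssociationBiological", "case1_corrected"),
    case2 = mk_case2("ME_Dimerization", "case2_original"),
    case2_fixed = mk_case2("ME_Binding", "case2_corrected")
  )
}
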