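# Controlled vocabularies and fixed enumerations of the data model.
#
# Terms are namespace-prefixed strings: ME_* biological events, FT_* feature
# (modification) types, CC_* cell components. Comparison is exact string
# equality; there is no term hierarchy.

ENTITY_CLASSES <- c("Entity", "Protein", "Dna", "mRNA", "SmallMolecule", "Complex")

INPUT_ROLES <- c(
  "InputProcessBiological",     # substrate: consumed by the process
  "InputInhibitorBiological",   # inhibitor
  "InputAssociationBiological"  # activator
)
OUTPUT_ROLE <- "OutputProcessBiological"
CONNECTOR_ROLES <- c(INPUT_ROLES, OUTPUT_ROLE)

# The 36 rule-covered biological events, in their five groups.
COVERED_EVENTS <- list(
  `1` = c(
    "ME_Autocleavage", "ME_Binding", "ME_DNABinding", "ME_DNAReplication",
    "ME_Dissociation", "ME_GDP-GTPExchange", "ME_Isomerization",
    "ME_MetabolicReaction", "ME_ProteasomeDegradation", "ME_ProteinCleavage",
    "ME_UnknownDegradation"
  ),
  `2` = c(
    "ME_Acetylation", "ME_ADPRibosylation", "ME_Amidation", "ME_Glycosylation",
    "ME_Nitrosylation", "ME_Oxidation", "ME_Phosphorylation", "ME_Reduction",
    "ME_Sumoylation", "ME_Ubiquitination", "ME_UnknownActivation",
    "ME_UnknownInactivation", "ME_Autophosphorylation", "ME_Dephosphorylation",
    "ME_Deubiquitination"
  ),
  `3` = c("ME_Dimerization", "ME_Oligomerization", "ME_Polymerization"),
  `4` = c("ME_Internalization", "ME_NuclearExport", "ME_Translocation"),
  `5` = c(
    "ME_GeneExpression", "ME_IonTransportThroughIonChannel",
    "ME_Transcription", "ME_Translation"
  )
)

# Event terms that occur in curated models but have no event-specific rule
# (they have no characteristics that distinguish them from other events).
# Cleavage and unknown interaction are attested; the rest round out a
# realistic 44-term curation vocabulary.
UNCOVERED_EVENTS <- c(
  "ME_Cleavage", "ME_UnknownInteraction", "ME_UnknownProduction",
  "ME_Transport", "ME_Secretion", "ME_Phagocytosis", "ME_Apoptosis",
  "ME_Recycling"
)

FT_TERMS <- c(
  "FT_Acetylated", "FT_ADPRibosylated", "FT_Amidated", "FT_Glycosylated",
  "FT_Nitrosylated", "FT_Oxidized", "FT_Phosphorylated", "FT_Reduced",
  "FT_Sumoylated", "FT_Ubiquitinated", "FT_Active", "FT_Inactive",
  "FT_Dephosphorylated", "FT_Deubiquitinated"
)

CC_TERMS <- c(
  "CC_Extracellular", "CC_PlasmaMembrane", "CC_Cytosol", "CC_Cytoplasm",
  "CC_Nucleoplasm", "CC_Nucleus", "CC_Mitochondrion",
  "CC_EndoplasmicReticulum", "CC_GolgiApparatus", "CC_Lysosome", "CC_Endosome"
)

WARNING_CATEGORIES <- c(
  "WRONG_CARDINALITY_INPUT", "WRONG_CARDINALITY_INPUTPROCESS",
  "WRONG_CARDINALITY_OUTPUT", "MISSING_INPUTPROCESS", "MISSING_OUTPUT",
  "WRONG_TYPE", "MISSING_TYPE", "WRONG_CELLCOMPONENT",
  "MISSING_CELLCOMPONENT", "MISSING_FEATURETYPE", "WRONG_STOICHIOMETRY",
  "MISSING_UNIFICATIONXREF", "WRONG_UNIFICATIONXREF",
  "SAME_CELLCOMPONENT_SHOULD_DIFFER", "INVALID_CONNECTION"
)

#' Entity classes of the pathway data model
#'
#' The six entity classes. `Protein`, `Dna`, `mRNA`, `SmallMolecule` and
#' `Complex` are subclasses of the root class `Entity`; [is_a()] tests class
#' membership with this hierarchy.
#'
#' @return A character vector of class names.
#' @export
#' @examples
#' entity_classes()
#' is_a("Complex", "Entity")
entity_classes <- function() ENTITY_CLASSES

#' Test entity class membership under the class hierarchy
#'
#' @param class Character vector of entity class names.
#' @param target A single class name to test against.
#' @return Logical vector: `TRUE` where `class` is `target` or a subclass of
#'   it. Every class is an `Entity`; the five subclasses are pairwise
#'   disjoint.
#' @export
is_a <- function(class, target) {
  stopifnot(is.character(class), length(target) == 1L)
  bad <- setdiff(unique(class), ENTITY_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown entity class: ", paste(bad, collapse = ", ")))
  }
  if (!target %in% ENTITY_CLASSES) {
    abort(paste0("Unknown entity class: ", target))
  }
  if (target == "Entity") rep(TRUE, length(class)) else class == target
}

#' Connector roles
#'
#' The four connector roles through which an entity participates in a
#' process: substrate (`InputProcessBiological`), inhibitor
#' (`InputInhibitorBiological`), activator (`InputAssociationBiological`) and
#' product (`OutputProcessBiological`). The first three form the input role
#' family returned by [input_roles()].
#'
#' @return Character vector of role names.
#' @export
connector_roles <- function() CONNECTOR_ROLES

#' @rdname connector_roles
#' @export
input_roles <- function() INPUT_ROLES

#' Valid process/entity connection configurations
#'
#' A process and an entity may be unconnected or joined by exactly one
#' connector of one of the four roles: five valid configurations in total.
#' Two or more connectors on the same pair are structurally invalid and are
#' reported by [check_valid_connections()].
#'
#' @return A tibble with columns `configuration` and `role` (`NA` for the
#'   unconnected configuration).
#' @export
connection_configurations <- function() {
  tibble(
    configuration = c("no_connection", "substrate", "inhibitor", "activator",
                      "product"),
    role = c(NA_character_, INPUT_ROLES, OUTPUT_ROLE)
  )
}

#' Shipped controlled vocabularies
#'
#' `me_vocabulary()` returns the 44 biological-event terms the package knows
#' about (the 36 rule-covered events of the constraint table plus 8 terms
#' with no event-specific rule, among them `ME_Cleavage` and
#' `ME_UnknownInteraction`). `ft_vocabulary()` and `cc_vocabulary()` return
#' the feature-type and cell-component terms used by the shipped constraints.
#' Vocabularies are open-world: models may use terms outside these lists,
#' which are preserved verbatim and flagged as load notices.
#'
#' @return A character vector of terms.
#' @export
me_vocabulary <- function() c(unlist(COVERED_EVENTS, use.names = FALSE),
                              UNCOVERED_EVENTS)

#' @rdname me_vocabulary
#' @export
ft_vocabulary <- function() FT_TERMS

#' @rdname me_vocabulary
#' @export
cc_vocabulary <- function() CC_TERMS

#' Biological events covered by the shipped event rules
#'
#' @param group Optional group number (1-5) to restrict to.
#' @return Character vector of ME terms.
#' @export
covered_events <- function(group = NULL) {
  if (is.null(group)) return(unlist(COVERED_EVENTS, use.names = FALSE))
  if (!as.character(group) %in% names(COVERED_EVENTS)) {
    abort("`group` must be an integer in 1..5.")
  }
  COVERED_EVENTS[[as.character(group)]]
}

#' Warning categories of the validation report
#'
#' The taxonomy under which rule violations are reported: cardinality
#' (wrong count / missing participant), type (wrong / not defined), cell
#' component (wrong / not given), feature type (not defined), stoichiometry
#' (not correct), unification xref (not defined / mismatching), same-location
#' violations of location-change events, and the structural invalid-connection
#' check.
#'
#' @return Character vector of category codes.
#' @export
warning_categories <- function() WARNING_CATEGORIES

vocab_namespace <- function(term) {
  ifelse(grepl("^ME_", term), "ME",
         ifelse(grepl("^FT_", term), "FT",
                ifelse(grepl("^CC_", term), "CC", NA_character_)))
}

known_term <- function(term, namespace) {
  vocab <- switch(namespace, ME = me_vocabulary(), FT = ft_vocabulary(),
                  CC = cc_vocabulary())
  term %in% vocab
}
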