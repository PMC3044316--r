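# Criterion 2: event-specific rules in five groups.

c2_warnings <- function(model) {
  w <- tidy(validate_pathway(model, criteria = 2))
  w[w$criterion == 2L, ]
}

test_that("a fixture built to satisfy each constraint yields zero warnings (all 36)", {
  for (ev in covered_events()) {
    w <- c2_warnings(one_proc(ev))
    expect_equal(nrow(w), 0, info = ev)
  }
})

test_that("each single injected defect yields exactly the expected category", {
  base <- make_clean_model()   # one process per covered event
  for (category in warning_categories()) {
    m <- inject_violations(base, setNames(1L, category), seed = 13)
    r <- validate_pathway(m, criteria = c(1, 2))
    counts <- category_counts(r)
    expect_equal(unname(counts[category]), 1L, info = category)
    expect_equal(sum(counts), 1L, info = category)
  }
})

test_that("group-3 admissible coefficient sets have exact boundaries", {
  admissible <- list(
    ME_Dimerization = function(k) k == 2,
    ME_Oligomerization = function(k) k >= 3 && k <= 20,
    ME_Polymerization = function(k) k >= 21
  )
  for (ev in names(admissible)) {
    for (k in 1:40) {
      w <- check_stoichiometry_event(stoich_model(ev, k), "p1")
      flagged <- sum(w$category == "WRONG_STOICHIOMETRY") > 0
      expect_equal(flagged, !admissible[[ev]](k),
                   info = sprintf("%s k=%d", ev, k))
    }
  }
})

test_that("dimerization demands one substrate with coefficient 2 and a Complex product", {
  m <- stoich_model("ME_Dimerization", 2)
  expect_equal(nrow(c2_warnings(m)), 0)
  w <- c2_warnings(stoich_model("ME_Dimerization", 1))
  expect_equal(w$category, "WRONG_STOICHIOMETRY")
  # a second substrate is a cardinality violation (the event-term
  # misassignment signature)
  m2 <- add_entity(m, "sub2", "Protein")
  m2 <- add_connector(m2, "c_in2", "InputProcessBiological", "p1", "sub2",
                      stoichiometry = 2L)
  w2 <- c2_warnings(m2)
  expect_equal(w2$category, "WRONG_CARDINALITY_INPUTPROCESS")
})

test_that("modification rules tie substrate, product feature, and shared xref", {
  m <- one_proc("ME_Acetylation")
  expect_equal(nrow(check_group2(m, "p0001")), 0)
  # product missing the mapped feature term
  m_noft <- set_entity_field(m, "e0001_o1", "feature_types", character())
  expect_equal(check_group2(m_noft, "p0001")$category, "MISSING_FEATURETYPE")
  # unidentified substrate: no identity comparison is attempted
  m_noxr <- set_entity_field(m, "e0001_s1", "xrefs", character())
  w <- check_group2(m_noxr, "p0001")
  expect_equal(w$category, "MISSING_UNIFICATIONXREF")
  # both identified but disjoint: the product is not a form of the substrate
  m_badxr <- set_entity_field(m, "e0001_o1", "xrefs", "TRANSPATH:OTHER")
  expect_equal(check_group2(m_badxr, "p0001")$category, "WRONG_UNIFICATIONXREF")
  # xref comparison is case-normalized
  m_case <- set_entity_field(m, "e0001_o1", "xrefs",
                             toupper(m$entities$xrefs[[
                               which(m$entities$id == "e0001_s1")]]))
  expect_equal(nrow(check_group2(m_case, "p0001")), 0)
})

test_that("autophosphorylation admits no enzyme: one total input entity", {
  m <- one_proc("ME_Autophosphorylation")
  expect_equal(nrow(c2_warnings(m)), 0)
  m2 <- add_entity(m, "enzyme", "Protein")
  m2 <- add_connector(m2, "c_act", "InputAssociationBiological", "p0001",
                      "enzyme")
  w <- c2_warnings(m2)
  expect_equal(w$category, "WRONG_CARDINALITY_INPUT")
  # plain phosphorylation permits the extra activator
  m3 <- one_proc("ME_Phosphorylation")
  m3 <- add_entity(m3, "kinase", "Protein")
  m3 <- add_connector(m3, "c_act", "InputAssociationBiological", "p0001",
                      "kinase")
  expect_equal(nrow(c2_warnings(m3)), 0)
})

test_that("internalization constrains source and target compartments and identity", {
  m <- one_proc("ME_Internalization")  # extracellular -> cytosol, shared xref
  expect_equal(nrow(check_internalization(m, "p0001")), 0)
  m_pm <- set_entity_field(m, "e0001_s1", "cell_component", "CC_PlasmaMembrane")
  expect_equal(nrow(check_internalization(m_pm, "p0001")), 0)
  m_bad <- set_entity_field(m, "e0001_s1", "cell_component", "CC_Cytosol")
  expect_equal(check_internalization(m_bad, "p0001")$category,
               "WRONG_CELLCOMPONENT")
  m_noxr <- set_entity_field(
    set_entity_field(m, "e0001_s1", "xrefs", character()),
    "e0001_o1", "xrefs", character())
  w <- check_internalization(m_noxr, "p0001")
  expect_equal(w$category, "MISSING_UNIFICATIONXREF")
  expect_equal(nrow(w), 1)  # dependency suppression: no sameAs attempted
})

test_that("translocation fires the same-compartment warning iff both present and equal", {
  base <- one_proc("ME_Translocation")
  cc_in <- base$entities$cell_component[base$entities$id == "e0001_s1"]
  cases <- list(
    list(out = cc_in, expect = "SAME_CELLCOMPONENT_SHOULD_DIFFER"),
    list(out = NA_character_, expect = "MISSING_CELLCOMPONENT"),
    list(out = "CC_Endosome", expect = NULL)
  )
  for (cs in cases) {
    m <- set_entity_field(base, "e0001_o1", "cell_component", cs$out)
    w <- c2_warnings(m)
    if (is.null(cs$expect)) expect_equal(nrow(w), 0)
    else expect_equal(w$category, cs$expect)
  }
  # a missing source compartment is also reported as missing, once
  m <- set_entity_field(base, "e0001_s1", "cell_component", NA_character_)
  expect_equal(c2_warnings(m)$category, "MISSING_CELLCOMPONENT")
})

test_that("transcription requires a single nucleoplasmic mRNA product", {
  m <- one_proc("ME_Transcription")
  expect_equal(nrow(c2_warnings(m)), 0)
  m_type <- set_entity_field(m, "e0001_o1", "class", "Protein")
  expect_equal(c2_warnings(m_type)$category, "WRONG_TYPE")
  m_loc <- set_entity_field(m, "e0001_o1", "cell_component", "CC_Cytosol")
  expect_equal(c2_warnings(m_loc)$category, "WRONG_CELLCOMPONENT")
  m_base <- set_entity_field(m, "e0001_o1", "class", "Entity")
  expect_equal(c2_warnings(m_base)$category, "MISSING_TYPE")
})

test_that("DNA binding needs two substrates, one a Dna, and a Complex product", {
  m <- one_proc("ME_DNABinding")
  expect_equal(nrow(c2_warnings(m)), 0)
  # hierarchy: Dna and Complex are Entities, so the generic class test passes
  classes <- m$entities$class
  expect_true("Dna" %in% classes && "Complex" %in% classes)
  m_nodna <- set_entity_field(m, "e0001_s1", "class", "Protein")
  expect_equal(c2_warnings(m_nodna)$category, "WRONG_TYPE")
  # dropping one substrate violates the at-least-two cardinality
  m_one <- drop_connectors(m, "p0001_cs2")
  expect_equal(c2_warnings(m_one)$category, "WRONG_CARDINALITY_INPUTPROCESS")
})

test_that("a missing required participant suppresses its dependent clauses", {
  m <- one_proc("ME_Acetylation")
  m_noout <- drop_connectors(m, "p0001_co1")
  w <- c2_warnings(m_noout)
  # one warning only: no feature/xref complaints about the absent product
  expect_equal(w$category, "MISSING_OUTPUT")
  m_noin <- drop_connectors(m, "p0001_cs1")
  expect_equal(c2_warnings(m_noin)$category, "MISSING_INPUTPROCESS")
})

test_that("group wrappers reject processes of the wrong event family", {
  m <- one_proc("ME_Dimerization")
  expect_error(check_group2(m, "p0001"), "group-3")
  expect_error(check_internalization(m, "p0001"), "expected ME_Internalization")
  expect_error(check_stoichiometry_event(one_proc("ME_Acetylation"), "p0001"),
               "group-2")
  expect_error(
    check_event_process(m, "p0001", constraint_for_event("ME_Binding")),
    "has event")
})
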