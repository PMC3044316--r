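# Data model, serialization, and graph-access predicates.

minimal_json <- '{
  "model_id": "tiny",
  "entities": [{"id": "A", "class": "Protein"}],
  "processes": [{"id": "p1", "biologicalEvent": "ME_UnknownProduction"}],
  "connectors": [{"id": "c1", "role": "OutputProcessBiological",
                  "process": "p1", "entity": "A"}]
}'

test_that("the smallest valid model loads with one node of each kind", {
  m <- read_pathway_model(minimal_json)
  expect_s3_class(m, "pathway_model")
  expect_equal(nrow(m$entities), 1)
  expect_equal(nrow(m$processes), 1)
  expect_equal(nrow(m$connectors), 1)
  expect_equal(m$connectors$stoichiometry, 1L)
})

test_that("structural load errors name every offense at once", {
  bad <- '{
    "model_id": "bad",
    "entities": [{"id": "A"}, {"id": "A"}],
    "processes": [{"id": "p1"}],
    "connectors": [
      {"id": "c1", "role": "OutputProcessBiological", "process": "p1", "entity": "GHOST"},
      {"id": "c2", "role": "NotARole", "process": "A", "entity": "A"}
    ]
  }'
  err <- expect_error(read_pathway_model(bad), class = "pathwaylint_model_error")
  msg <- conditionMessage(err)
  expect_match(msg, "duplicate entity id: A")
  expect_match(msg, "c1")            # dangling reference names the connector
  expect_match(msg, "GHOST")
  expect_match(msg, "without biological_event")
  expect_match(msg, "unknown role")
  expect_match(msg, "names an entity")  # bipartiteness: c2 points at entity A
})

test_that("malformed JSON raises a parse error", {
  expect_error(read_pathway_model("{ not json"),
               class = "pathwaylint_parse_error")
})

test_that("load after save is the identity and saves are byte-identical", {
  m <- make_clean_model(events = covered_events()[1:15], seed = 4)
  expect_gt(nrow(m$entities) + nrow(m$processes), 40)
  txt <- write_pathway_model(m)
  m2 <- read_pathway_model(txt)
  for (field in c("model_id", "entities", "processes", "connectors")) {
    expect_equal(m2[[field]], m[[field]], info = field)
  }
  expect_identical(write_pathway_model(m2), txt)
  # defaults are explicit: no elision ambiguity for coefficient 1
  expect_match(txt, '"stoichiometry": 1')
  # an empty model serializes to empty record lists
  empty_txt <- write_pathway_model(pathway_model(model_id = "empty"))
  expect_match(empty_txt, '"entities": \\[\\]')
  expect_equal(nrow(read_pathway_model(empty_txt)$connectors), 0)
})

test_that("unknown record keys are preserved in lax mode and rejected in strict", {
  doc <- '{
    "model_id": "m", "entities": [{"id": "A", "class": "Protein"}],
    "processes": [{"id": "p1", "biologicalEvent": "ME_UnknownProduction"}],
    "connectors": [{"id": "c1", "role": "OutputProcessBiological",
                    "process": "p1", "entity": "A",
                    "initialValue": 0.5, "kinetics": "mass-action"}]
  }'
  m <- read_pathway_model(doc)
  expect_equal(m$connectors$annotations[[1]]$kinetics, "mass-action")
  expect_match(write_pathway_model(m), '"kinetics": "mass-action"')
  expect_error(read_pathway_model(doc, strict = TRUE),
               class = "pathwaylint_parse_error")
})

test_that("unknown vocabulary terms load with a notice, not an error", {
  doc <- '{
    "model_id": "m",
    "entities": [{"id": "A", "class": "Protein", "cellComponent": "CC_Imaginarium"}],
    "processes": [{"id": "p1", "biologicalEvent": "ME_NotAThing"}],
    "connectors": [{"id": "c1", "role": "OutputProcessBiological",
                    "process": "p1", "entity": "A"}]
  }'
  m <- read_pathway_model(doc)
  expect_length(m$notices, 2)
  expect_match(paste(m$notices, collapse = " "), "ME_NotAThing")
  expect_match(paste(m$notices, collapse = " "), "CC_Imaginarium")
})

test_that("entity class membership respects the hierarchy", {
  expect_true(all(is_a(entity_classes(), "Entity")))
  expect_equal(is_a(c("Complex", "Protein"), "Complex"), c(TRUE, FALSE))
  expect_false(is_a("Dna", "mRNA"))
  expect_error(is_a("Gene", "Entity"), "Unknown entity class")
})

test_that("complex composition must be acyclic and class-consistent", {
  expect_error(
    pathway_model(entities = tibble(id = "X", class = "Protein",
                                    components = list("X"))),
    "components but class"
  )
  expect_error(
    pathway_model(entities = tibble(
      id = c("X", "Y"), class = "Complex",
      components = list("Y", "X")
    )),
    "transitive component"
  )
})

double_role_model <- function() {
  m <- chain_model()
  add_connector(m, "c_dup", "InputAssociationBiological", "p1", "A")
}

test_that("connectors_between returns all connectors of a pair in id order", {
  m <- double_role_model()
  both <- connectors_between(m, "p1", "A")
  expect_equal(both$id, c("c_dup", "c_in"))
  expect_equal(nrow(connectors_between(chain_model(), "p1", "A")), 1)
  # an unconnected pair: entity B is never an input of p1
  iso <- add_entity(chain_model(), "Z")
  expect_equal(nrow(connectors_between(iso, "p1", "Z")), 0)
  expect_error(connectors_between(m, "p1", "nope"), "Unknown entity")
  expect_error(connectors_between(m, "nope", "A"), "Unknown process")
})

test_that("role-specific participant scans follow the input role family", {
  m <- pathway_model(
    entities = tibble(id = c("A", "B"), class = "Protein"),
    processes = tibble(id = "p1", biological_event = "ME_UnknownActivation"),
    connectors = tibble(
      id = c("c1", "c2"),
      role = c("InputProcessBiological", "InputAssociationBiological"),
      process = "p1", entity = c("A", "B"), stoichiometry = 1L
    )
  )
  expect_setequal(has_input(m, "p1")$entity_id, c("A", "B"))
  expect_equal(has_inputprocess(m, "p1")$entity_id, "A")
  expect_equal(nrow(has_output(m, "p1")), 0)

  iso <- pathway_model(
    processes = tibble(id = "p_lonely", biological_event = "ME_Binding"))
  expect_equal(nrow(has_input(iso, "p_lonely")), 0)
  expect_equal(nrow(has_inputprocess(iso, "p_lonely")), 0)
  expect_equal(nrow(has_output(iso, "p_lonely")), 0)
})

test_that("role scans agree with a brute-force edge scan on random fixtures", {
  m <- mixed_fixture(seed = 21, extra = 10)
  for (pid in m$processes$id) {
    all_conns <- m$connectors[m$connectors$process == pid, ]
    scans <- dplyr::bind_rows(has_input(m, pid), has_output(m, pid))
    expect_setequal(scans$connector_id, all_conns$id)
    # the input family contains the substrate-only scan
    expect_true(all(has_inputprocess(m, pid)$connector_id %in%
                      has_input(m, pid)$connector_id))
  }
})

test_that("GraphML export is well-formed with one node per record", {
  m <- make_clean_model(events = c("ME_Binding", "ME_Transcription"))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(m, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(nodes, nrow(m$entities) + nrow(m$processes))
  expect_length(edges, nrow(m$connectors))
})
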