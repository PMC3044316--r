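# Criterion 3: starting/degrading species detection and model rewriting.

test_that("a linear chain gains one production and two degradations", {
  m <- chain_model()   # A -> p1 -> B, both Proteins
  expect_equal(find_starting_entities(m), "A")   # B is produced
  expect_equal(find_starting_complexes(m), character())
  expect_equal(find_degrading_entities(m), c("A", "B"))
  res <- complement_model(m)
  s <- glance(res$delta)
  expect_equal(s$n_production, 1)
  expect_equal(s$n_binding, 0)
  expect_equal(s$n_degradation, 2)
  expect_true("A__unknown_production" %in% res$model$processes$id)
  expect_true(all(c("A__unknown_degradation", "B__unknown_degradation") %in%
                    res$model$processes$id))
})

test_that("a consumed-only complex gains a binding process over its components", {
  m <- pathway_model(
    entities = tibble(
      id = c("X", "Y", "C"), class = c("Protein", "Protein", "Complex"),
      components = list(character(), character(), c("X", "Y"))
    ),
    processes = tibble(id = "p1", biological_event = "ME_Dissociation"),
    connectors = tibble(
      id = c("c_in", "c_x", "c_y"),
      role = c("InputProcessBiological", "OutputProcessBiological",
               "OutputProcessBiological"),
      process = "p1", entity = c("C", "X", "Y"))
  )
  expect_equal(find_starting_complexes(m), "C")
  expect_equal(find_starting_entities(m), character())  # X, Y are produced
  res <- complement_model(m)
  binding <- res$model$processes[res$model$processes$biological_event == "ME_Binding", ]
  expect_equal(nrow(binding), 1)
  kb <- res$model$connectors[res$model$connectors$process == binding$id, ]
  expect_setequal(kb$entity[kb$role == "InputProcessBiological"], c("X", "Y"))
  expect_equal(kb$entity[kb$role == "OutputProcessBiological"], "C")
  # the complex is now produced: a second pass has nothing to add there
  expect_equal(find_starting_complexes(res$model), character())
})

test_that("a produced complex is not a starting complex", {
  m <- one_proc("ME_Dimerization")   # complex product
  expect_equal(find_starting_complexes(m), character())
  # and the two starting sets are disjoint by construction
  mf <- mixed_fixture(seed = 9, extra = 5)
  expect_length(intersect(find_starting_entities(mf),
                          find_starting_complexes(mf)), 0)
})

test_that("isolated entities are starting entities (vacuous condition)", {
  m <- add_entity(chain_model(), "lonely", "SmallMolecule")
  expect_true("lonely" %in% find_starting_entities(m))
})

test_that("a starting complex without components falls back to production, with a note", {
  m <- pathway_model(
    entities = tibble(id = "C0", class = "Complex"),
    model_id = "bare_complex"
  )
  res <- complement_model(m)
  expect_equal(glance(res$delta)$n_binding, 0)
  expect_equal(glance(res$delta)$n_production, 1)
  note <- res$delta$notes$note[res$delta$notes$target_id == "C0"][1]
  expect_match(note, "without recorded components")
})

test_that("degradation detection follows class and existing sinks", {
  m <- chain_model()
  # an untyped species is not scheduled for degradation
  m2 <- add_entity(m, "raw", "Entity")
  expect_false("raw" %in% find_degrading_entities(m2))
  # an entity already consumed by an unknown degradation process is exempt
  res <- complement_model(m)
  expect_length(find_degrading_entities(res$model), 0)
  # proteasome degradation exempts only under the widened option
  mp <- pathway_model(
    entities = tibble(id = "P", class = "Protein"),
    processes = tibble(id = "deg", biological_event = "ME_ProteasomeDegradation"),
    connectors = tibble(id = "c1", role = "InputProcessBiological",
                        process = "deg", entity = "P")
  )
  expect_equal(find_degrading_entities(mp), "P")
  expect_length(find_degrading_entities(mp, include_proteasome = TRUE), 0)
})

test_that("complementation is idempotent, total, conservative, and validity-preserving", {
  for (seed in 1:5) {
    m <- make_clean_model(n_processes = 20, seed = seed)
    res <- complement_model(m)
    out <- res$model
    # totality: no starting or undegraded species remain
    expect_length(find_starting_entities(out), 0)
    expect_length(find_starting_complexes(out), 0)
    expect_length(find_degrading_entities(out), 0)
    # idempotence: the second pass is empty
    res2 <- complement_model(out)
    expect_equal(nrow(res2$delta$processes), 0)
    expect_equal(nrow(res2$delta$connectors), 0)
    # conservation: original records survive untouched
    expect_true(all(m$entities$id %in% out$entities$id))
    expect_equal(out$entities[out$entities$id %in% m$entities$id, ],
                 m$entities)
    expect_true(all(m$connectors$id %in% out$connectors$id))
    # validity: the output passes construction invariants (by construction)
    # and the structural rule gains no new violations
    expect_equal(nrow(check_valid_connections(out)),
                 nrow(check_valid_connections(m)))
  }
})

test_that("deltas are replayable and serializable", {
  m <- chain_model()
  res <- complement_model(m)
  expect_identical(write_pathway_model(apply_delta(m, res$delta)),
                   write_pathway_model(res$model))
  d2 <- read_model_delta(write_model_delta(res$delta))
  expect_identical(write_pathway_model(apply_delta(m, d2)),
                   write_pathway_model(res$model))
  expect_equal(nrow(tidy(res$delta)), nrow(res$delta$processes) +
                 nrow(res$delta$connectors))
})
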