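# Registry, evaluation semantics, and report invariants.

test_that("the registry holds one structural, 36 reactive, and 3 rewrite rules", {
  reg <- rule_registry()
  expect_equal(nrow(reg), 40)
  expect_equal(nrow(list_rules(reg, criterion = 1)), 1)
  expect_equal(nrow(list_rules(reg, criterion = 2)), 36)
  expect_equal(nrow(list_rules(reg, criterion = 3)), 3)
  # criterion-2 rules always bind to an event; criterion-3 never do
  c2 <- list_rules(reg, criterion = 2)
  expect_true(all(!is.na(c2$trigger_event)))
  expect_true(all(is.na(list_rules(reg, criterion = 3)$trigger_event)))
  expect_true(all(list_rules(reg, criterion = 3)$action_kind == "mutate"))
  expect_true(all(c2$action_kind == "report"))
  for (g in 1:5) {
    expect_equal(nrow(list_rules(reg, criterion = 2, group = g)),
                 c(11, 15, 3, 3, 4)[g], info = paste("group", g))
  }
  expect_error(list_rules(reg, criterion = 7), "must be 1, 2 or 3")
  expect_error(list_rules(reg, group = 9), "1..5")
})

test_that("an empty model validates with zero warnings and zero counts", {
  r <- validate_pathway(pathway_model(model_id = "void"), criteria = c(1, 2, 3))
  expect_equal(nrow(tidy(r)), 0)
  expect_true(all(r$counts_by_category$n == 0))
  expect_equal(nrow(r$counts_by_event), 0)
  expect_true(all(r$criterion3$n == 0))
})

test_that("uncovered events are accounted, not warned about", {
  m <- one_proc("ME_Dimerization")
  expect_length(uncovered_events(m), 0)

  cleavage <- pathway_model(
    entities = tibble(id = c("A", "B"), class = "Protein"),
    processes = tibble(id = "p1", biological_event = "ME_Cleavage"),
    connectors = tibble(
      id = c("c1", "c2"),
      role = c("InputProcessBiological", "OutputProcessBiological"),
      process = "p1", entity = c("A", "B"))
  )
  expect_equal(uncovered_events(cleavage), "ME_Cleavage")
  r <- validate_pathway(cleavage)
  expect_equal(nrow(tidy(r)), 0)
  expect_equal(r$uncovered_events, "ME_Cleavage")

  # set-difference oracle over the full 44-term vocabulary
  m44 <- make_clean_model(events = me_vocabulary(), allow_uncovered = TRUE)
  expect_equal(uncovered_events(m44),
               sort(setdiff(me_vocabulary(), covered_events())))
  expect_length(uncovered_events(m44), 8)
})

test_that("evaluation is deterministic and never mutates the model", {
  m <- inject_violations(mixed_fixture(seed = 5),
                         c(WRONG_TYPE = 2, MISSING_OUTPUT = 1,
                           INVALID_CONNECTION = 1), seed = 5)
  before <- write_pathway_model(m)
  r1 <- validate_pathway(m, criteria = c(1, 2))
  r2 <- validate_pathway(m, criteria = c(1, 2))
  expect_identical(write_report_json(r1), write_report_json(r2))
  expect_identical(write_pathway_model(m), before)
})

test_that("warnings grow monotonically with the criteria set", {
  m <- inject_violations(mixed_fixture(seed = 6),
                         c(INVALID_CONNECTION = 2, WRONG_STOICHIOMETRY = 1),
                         seed = 6)
  w1 <- tidy(validate_pathway(m, criteria = 1))
  w12 <- tidy(validate_pathway(m, criteria = c(1, 2)))
  expect_equal(nrow(w1), 2)
  expect_equal(nrow(w12), 3)
  # multiset inclusion: every criterion-1 warning reappears verbatim
  key <- function(w) paste(w$category, w$rule_id, w$process_id, w$message)
  expect_true(all(key(w1) %in% key(w12)))
})

test_that("report counts are exact marginals of the warning list", {
  m <- inject_violations(mixed_fixture(seed = 7),
                         c(MISSING_FEATURETYPE = 2, WRONG_CELLCOMPONENT = 1,
                           MISSING_INPUTPROCESS = 1), seed = 7)
  r <- validate_pathway(m, criteria = c(1, 2))
  expect_equal(sum(r$counts_by_category$n), nrow(tidy(r)))
  expect_equal(sum(r$counts_by_event$warnings),
               sum(tidy(r)$criterion == 2L))
  # ordering is stable: process id, then rule id
  w <- tidy(r)
  expect_false(is.unsorted(w$process_id))
})

test_that("criterion 3 is reported as addition counts, never as mutation", {
  m <- chain_model()
  r <- validate_pathway(m, criteria = c(1, 2, 3))
  c3 <- setNames(r$criterion3$n, r$criterion3$rule_id)
  expect_equal(unname(c3["C3_STARTING_ENTITY"]),
               length(find_starting_entities(m)))
  expect_equal(unname(c3["C3_DEGRADING_ENTITY"]),
               length(find_degrading_entities(m)))
  expect_identical(write_pathway_model(m), write_pathway_model(chain_model()))
  expect_null(validate_pathway(m, criteria = c(1, 2))$criterion3)
})

test_that("the engine agrees with the brute-force oracle on small random fixtures", {
  for (seed in 1:4) {
    base <- mixed_fixture(seed = seed, extra = 10)
    plan <- c(WRONG_TYPE = 1, MISSING_OUTPUT = 1, WRONG_STOICHIOMETRY = 1,
              MISSING_UNIFICATIONXREF = 1, INVALID_CONNECTION = 1)
    m <- inject_violations(base, plan, seed = seed)
    expect_matches_oracle(m)
  }
})

test_that("report writers emit deterministic JSON and the per-event TSV shape", {
  m <- inject_violations(one_proc("ME_Dimerization"),
                         c(WRONG_STOICHIOMETRY = 1), seed = 1)
  r <- validate_pathway(m, criteria = c(1, 2))
  js <- jsonlite::fromJSON(write_report_json(r))
  expect_equal(js$counts_by_category$WRONG_STOICHIOMETRY, 1)
  tsv <- write_report_tsv(r)
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(lines[1], "event\tfrequency\twarnings\treasons")
  expect_match(lines[2], "^ME_Dimerization\t1\t1\tWRONG_STOICHIOMETRY \\(1\\)$")
})
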