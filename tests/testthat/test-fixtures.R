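test_that("generation is byte-deterministic under a seed", {
  sp <- fixture_spec(seed = 42, n_concepts = 30)
  b1 <- generate_base(sp); b2 <- generate_base(sp)
  expect_identical(write_turtle(b1$triples), write_turtle(b2$triples))
  fx1 <- plant_changes(b1, fixture_spec(seed = 42, n_concepts = 30,
                                        change_script = c("addLeafC", "toObsC")))
  fx2 <- plant_changes(b2, fixture_spec(seed = 42, n_concepts = 30,
                                        change_script = c("addLeafC", "toObsC")))
  expect_identical(write_turtle(fx1$new$triples), write_turtle(fx2$new$triples))
})

test_that("generated bases match a recount through the model indices", {
  sp <- fixture_spec(seed = 9, n_concepts = 50, branching = 3,
                     n_properties = 8, n_individuals = 5, n_obsolete = 2)
  b <- generate_base(sp)
  expect_equal(length(b$concepts), 50 + 2)           # incl. deprecated ones
  expect_gte(nrow(b$class_edges), 49)
  expect_equal(length(b$properties), 8 + 1)
  expect_equal(length(b$individuals), 5)
  expect_equal(nrow(b$type_assertions), 5)
  # every concept carries a label and a comment
  lab <- b$attributes[b$attributes$category == "label", ]
  expect_true(all(b$concepts %in% lab$entity))
})

test_that("infeasible specs and unknown script tokens fail with named errors", {
  expect_error(fixture_spec(n_concepts = 100, max_depth = 2, branching = 2),
               "hosts at most")
  sp <- fixture_spec(seed = 1, n_concepts = 10, change_script = "fooBar")
  expect_error(plant_changes(generate_base(sp), sp), "fooBar")
  # a merge needs two mergeable leaves: a 1-concept base cannot host it
  sp2 <- fixture_spec(seed = 1, n_concepts = 1, n_properties = 0,
                      n_individuals = 0, n_obsolete = 0, n_obsolete_props = 0,
                      change_script = "mergeC")
  expect_error(plant_changes(generate_base(sp2), sp2), "clean")
})

test_that("the standard suite plants every instantiable action with disjoint entity sets", {
  suite <- get_suite()
  planted <- unlist(lapply(suite, function(fx) fx$ledger$instances$action))
  residual_actions <- unlist(lapply(suite, function(fx) fx$ledger$basics$action))
  covered <- union(planted, residual_actions)
  tax <- load_taxonomy()
  leaves <- tax$classes$id[tax$classes$leaf]
  expect_length(leaves, 51)
  expect_true(all(leaves %in% covered))
  # the interior instantiable generalizations are planted too
  expect_true(all(c("moveC", "recastI") %in% planted))
  for (fx in suite) {
    sets <- lapply(fx$ledger$touch_sets, `[[`, "entities")
    expect_equal(anyDuplicated(unlist(sets)), 0)
  }
})

test_that("ledgers are internally consistent with their version pairs", {
  fx <- get_suite()$heuristic_concepts
  known <- c(fx$old$concepts, fx$old$properties, fx$old$individuals)
  expect_true(all(fx$ledger$mapping$source %in% known))
  known_new <- c(fx$new$concepts, fx$new$properties, fx$new$individuals)
  expect_true(all(fx$ledger$mapping$target %in% known_new))
  # every expected residual basic is backed by a real delta triple
  d <- compute_delta(fx$old, fx$new)
  delta_keys <- c(ontodiff:::render_ntriple(d$added),
                  ontodiff:::render_ntriple(d$deleted))
  for (i in seq_len(nrow(fx$ledger$basics))) {
    keys <- ontodiff:::render_ntriple(fx$ledger$basics$payload[[i]])
    expect_true(all(keys %in% delta_keys))
  }
})

test_that("randomized pairs are deterministic per seed", {
  a <- random_fixture_pair(99)
  b <- random_fixture_pair(99)
  expect_identical(write_turtle(a$new$triples), write_turtle(b$new$triples))
  expect_identical(instance_key_set(a$ledger$instances),
                   instance_key_set(b$ledger$instances))
})
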