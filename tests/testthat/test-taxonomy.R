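test_that("every basic action resolves to a Basic leaf; categories cover the table rows", {
  tax <- load_taxonomy()
  for (a in ontodiff:::BASIC_ACTIONS) {
    row <- tax$classes[tax$classes$id == a, ]
    expect_equal(nrow(row), 1, info = a)
    expect_equal(row$category, "Basic", info = a)
    expect_true(row$leaf, info = a)
  }
  heuristics <- c("renP", "renI", "mergeC", "mergeP", "mergeCInto", "mergePInto",
                  "splitC", "splitP", "splitCInto", "splitPInto",
                  "changeComment", "changeLabel", "changeOtherA")
  expect_setequal(tax$classes$id[tax$classes$category == "Heuristic" &
                                   tax$classes$leaf], heuristics)
  expect_true(all(c("renC", "moveC", "recastI") %in%
                    tax$classes$id[tax$classes$category == "Complex"]))
})

test_that("the reconciliation table matches the interior instantiable classes", {
  tax <- load_taxonomy()
  rec <- tax$reconciliation
  expect_setequal(unique(rec$generalization), c("moveC", "recastI"))
  expect_setequal(rec$specialized,
                  c("pullUpC", "pullDownC", "reclassIHigher", "reclassILower"))
  for (i in seq_len(nrow(rec))) {
    child <- tax$classes[tax$classes$id == rec$specialized[[i]], ]
    expect_equal(child$parent, rec$generalization[[i]])
  }
  # the interior generalizations stay instantiable (signature present)
  for (g in unique(rec$generalization)) {
    row <- tax$classes[tax$classes$id == g, ]
    expect_false(row$leaf)
    expect_false(is.null(row$signature[[1]]))
  }
  # the hierarchy is a tree with a single root and no abstract leaf
  expect_equal(sum(is.na(tax$classes$parent)), 1)
  expect_false(any(tax$classes$abstract & tax$classes$leaf))
})

test_that("instance validation enforces arity, roles and consumption", {
  tax <- load_taxonomy()
  bad_merge <- list(action = "mergeC",
                    arguments = list(sources = ex("a1"), target = ex("b")),
                    consumed = "x")
  rep <- validate_instance(bad_merge, tax)
  expect_true(any(grepl("at least 2", rep$message)))

  ok <- list(action = "addLeafC",
             arguments = list(entity = ex("c"), parent = ex("p")),
             consumed = c("b1", "b2"))
  expect_equal(nrow(validate_instance(ok, tax)), 0)

  missing_new <- list(action = "changeLabel",
                      arguments = list(entity = ex("c"), predicate = LABEL,
                                       old_value = "x"),
                      consumed = "b1")
  rep2 <- validate_instance(missing_new, tax)
  expect_true(any(grepl("new_value", rep2$message)))

  unknown <- list(action = "frobnicate", arguments = list(), consumed = "b")
  rep3 <- validate_instance(unknown, tax)
  expect_equal(nrow(rep3), 1)
  expect_match(rep3$message, "unknown change action")

  scaffold <- list(action = "BasicChange", arguments = list(), consumed = "b")
  expect_match(validate_instance(scaffold, tax)$message, "not instantiable")

  no_consumption <- list(action = "toObsC",
                         arguments = list(entity = ex("c")),
                         consumed = character(0))
  expect_match(validate_instance(no_consumption, tax)$message,
               "must consume")
})

test_that("serialization round-trips diff content in Turtle and JSON", {
  fx <- get_suite()$heuristic_concepts
  res <- compute_diff(fx$old, fx$new, mapping = fx$ledger$mapping)
  tax <- load_taxonomy()
  for (fmt in c("turtle", "json")) {
    doc <- serialize_changes(res, tax, format = fmt)
    back <- parse_changes(doc, format = fmt, tax = tax)
    expect_true(diff_content_equal(res, back), info = fmt)
  }
  # an empty diff serializes to a document with zero instances
  empty <- compute_diff(fx$old, fx$old, matcher = "none")
  parsed <- parse_changes(serialize_changes(empty, tax, "json"), "json", tax)
  expect_equal(nrow(parsed$instances), 0)
  expect_equal(nrow(parsed$residual), 0)
})

test_that("every action the engine can emit exists in the taxonomy", {
  tax <- load_taxonomy()
  engine_actions <- setdiff(plantable_actions(),
                            c("toObsC_label", "multiParentLeaf", "manyToMany",
                              "partialSubGraph"))
  expect_true(all(engine_actions %in% tax$classes$id))
})
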