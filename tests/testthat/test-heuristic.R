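# small helper: classify the delta of a mini pair
mini_basics <- function(old, new) {
  classify_basic(compute_delta(old, new), old, new)
}

test_that("two deleted sources mapped to one added target form a merge consuming all three", {
  old <- mini_version(cls("a1"), cls("a2"), cls("p"))
  new <- mini_version(cls("b"), cls("p"))
  b <- mini_basics(old, new)
  mp <- mapping_tbl(c(ex("a1"), ex("a2")), c(ex("b"), ex("b")), c(1, 1),
                    c("concept", "concept"))
  out <- detect_merges_splits(b, mp, old, new)
  expect_equal(out$instances$action, "mergeC")
  args <- out$instances$arguments[[1]]
  expect_setequal(args$sources, c(ex("a1"), ex("a2")))
  expect_equal(args$target, ex("b"))
  expect_equal(length(out$instances$consumed[[1]]), 3)
  # a persisting target instead gives mergeCInto, consuming only the deletions
  new2 <- mini_version(cls("b"), cls("p"), cls("a3"))
  old2 <- mini_version(cls("a1"), cls("a2"), cls("p"), cls("a3"))
  out2 <- detect_merges_splits(mini_basics(old2, new2),
                               mapping_tbl(c(ex("a1"), ex("a2")),
                                           c(ex("a3"), ex("a3")), c(1, 1),
                                           c("concept", "concept")),
                               old2, new2)
  expect_equal(out2$instances$action, "mergeCInto")
  expect_equal(length(out2$instances$consumed[[1]]), 2)
})

test_that("one deleted source mapped to two added targets forms a split", {
  old <- mini_version(cls("a"))
  new <- mini_version(cls("b1"), cls("b2"))
  b <- mini_basics(old, new)
  mp <- mapping_tbl(c(ex("a"), ex("a")), c(ex("b1"), ex("b2")), c(1, 1),
                    c("concept", "concept"))
  out <- detect_merges_splits(b, mp, old, new)
  expect_equal(out$instances$action, "splitC")
  expect_equal(out$instances$arguments[[1]]$source, ex("a"))
  expect_setequal(out$instances$arguments[[1]]$targets, c(ex("b1"), ex("b2")))
  # with an empty mapping nothing heuristic is possible
  out0 <- detect_merges_splits(b, mapping_tbl(), old, new)
  expect_equal(nrow(out0$instances), 0)
})

test_that("a 1:2 correspondence is a split, never a rename (precedence)", {
  old <- mini_version(cls("a"))
  new <- mini_version(cls("b1"), cls("b2"))
  b <- mini_basics(old, new)
  mp <- mapping_tbl(c(ex("a"), ex("a")), c(ex("b1"), ex("b2")), c(1, 1),
                    c("concept", "concept"))
  ms <- detect_merges_splits(b, mp, old, new)
  rn <- detect_renames(b[!(b$id %in% unlist(ms$claims$consumed)), ], mp,
                       old, new, exclude = ms$used)
  expect_equal(ms$instances$action, "splitC")
  expect_equal(nrow(rn$instances), 0)
})

test_that("strict 1:1 leftovers become renames; renC is categorized Complex", {
  old <- mini_version(cls("Old1"), prp("op"),
                      trow(ex("i"), RDF_TYPE_T, ex("K")), cls("K"))
  new <- mini_version(cls("New1"), prp("np"),
                      trow(ex("j"), RDF_TYPE_T, ex("K")), cls("K"))
  b <- mini_basics(old, new)
  mp <- mapping_tbl(c(ex("Old1"), ex("op"), ex("i")),
                    c(ex("New1"), ex("np"), ex("j")),
                    c(1, 1, 1), c("concept", "property", "individual"))
  rn <- detect_renames(b, mp, old, new)
  expect_setequal(rn$instances$action, c("renC", "renP", "renI"))
  expect_equal(rn$instances$category[rn$instances$action == "renC"], "Complex")
  expect_equal(rn$instances$category[rn$instances$action == "renI"], "Heuristic")
  renI_args <- rn$instances$arguments[[which(rn$instances$action == "renI")]]
  expect_equal(renI_args, list(old = ex("i"), new = ex("j")))
})

test_that("a slightly modified comment becomes changeComment(c, p, V_old, V_new)", {
  old <- mini_version(cls("s"), lrow(ex("s"), COMMENT, "heart atack"))
  new <- mini_version(cls("s"), lrow(ex("s"), COMMENT, "heart attack"))
  b <- mini_basics(old, new)
  out <- detect_value_changes(b, old, new)
  expect_equal(out$instances$action, "changeComment")
  a <- out$instances$arguments[[1]]
  expect_equal(a$entity, ex("s"))
  expect_equal(a$predicate, COMMENT)
  expect_equal(a$old_value, "heart atack")
  expect_equal(a$new_value, "heart attack")
  expect_equal(length(out$instances$consumed[[1]]), 2)
})

test_that("a deleted label without a counterpart stays a basic delLabel", {
  old <- mini_version(cls("s"), lrow(ex("s"), LABEL, "gone"))
  new <- mini_version(cls("s"))
  b <- mini_basics(old, new)
  out <- detect_value_changes(b, old, new)
  expect_equal(nrow(out$instances), 0)
})

test_that("2x2 label pairing equals the brute-force max-similarity assignment", {
  old <- mini_version(cls("s"),
                      lrow(ex("s"), LABEL, "cardiac arrest"),
                      lrow(ex("s"), LABEL, "renal failure"))
  new <- mini_version(cls("s"),
                      lrow(ex("s"), LABEL, "cardiac arrests"),
                      lrow(ex("s"), LABEL, "renal failures"))
  b <- mini_basics(old, new)
  out <- detect_value_changes(b, old, new)
  expect_equal(nrow(out$instances), 2)
  got <- lapply(out$instances$arguments, function(a) c(a$old_value, a$new_value))
  # oracle: enumerate both possible assignments, keep the higher-similarity one
  sim <- function(a, b) 1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
  olds <- c("cardiac arrest", "renal failure")
  news <- c("cardiac arrests", "renal failures")
  straight <- sim(olds[1], news[1]) + sim(olds[2], news[2])
  crossed <- sim(olds[1], news[2]) + sim(olds[2], news[1])
  want <- if (straight >= crossed) {
    list(c(olds[1], news[1]), c(olds[2], news[2]))
  } else {
    list(c(olds[1], news[2]), c(olds[2], news[1]))
  }
  expect_setequal(lapply(got, paste, collapse = "|"),
                  lapply(want, paste, collapse = "|"))
})

test_that("wholly different literals are not paired (similarity floor)", {
  old <- mini_version(cls("s"), lrow(ex("s"), ALTLABEL, "aaaaaaaaaa"))
  new <- mini_version(cls("s"), lrow(ex("s"), ALTLABEL, "zzzzzzzzzz"))
  b <- mini_basics(old, new)
  out <- detect_value_changes(b, old, new)
  expect_equal(nrow(out$instances), 0)
})
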