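test_that("the delta of a version with itself is empty and additions are exact", {
  v <- mini_version(cls("A"), lrow(ex("A"), LABEL, "x"))
  d <- compute_delta(v, v)
  expect_equal(nrow(d$added), 0)
  expect_equal(nrow(d$deleted), 0)
  v2 <- mini_version(cls("A"), lrow(ex("A"), LABEL, "x"), cls("B"))
  d2 <- compute_delta(v, v2)
  expect_equal(nrow(d2$added), 1)
  expect_equal(d2$added$subject, ex("B"))
  expect_equal(nrow(d2$deleted), 0)
})

test_that("delta equals a brute-force nested-loop symmetric difference", {
  set.seed(42)
  mk <- function(n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      trow(ex(sample(LETTERS[1:6], 1)), ex(sample(c("p", "q"), 1)),
           ex(sample(LETTERS[1:6], 1)))
    }))
  }
  t1 <- dplyr::distinct(mk(20)); t2 <- dplyr::distinct(mk(20))
  v1 <- ontology_version(t1); v2 <- ontology_version(t2)
  d <- compute_delta(v1, v2)
  eq_row <- function(a, b) all(unlist(a[1:3]) == unlist(b[1:3]))
  in_set <- function(row, tbl) {
    any(vapply(seq_len(nrow(tbl)), function(j) eq_row(row, tbl[j, ]), logical(1)))
  }
  brute_added <- t2[!vapply(seq_len(nrow(t2)),
                            function(i) in_set(t2[i, ], t1), logical(1)), ]
  brute_deleted <- t1[!vapply(seq_len(nrow(t1)),
                              function(i) in_set(t1[i, ], t2), logical(1)), ]
  expect_setequal(ontodiff:::render_ntriple(d$added),
                  ontodiff:::render_ntriple(brute_added))
  expect_setequal(ontodiff:::render_ntriple(d$deleted),
                  ontodiff:::render_ntriple(brute_deleted))
})

test_that("declaring a comment property plus comment literals yields addP + one addComment per class", {
  old <- mini_version(cls("A"), cls("B"))
  new <- mini_version(cls("A"), cls("B"),
                      trow(COMMENT, RDF_TYPE_T,
                           "http://www.w3.org/2002/07/owl#AnnotationProperty"),
                      lrow(ex("A"), COMMENT, "a description"),
                      lrow(ex("B"), COMMENT, "another description"))
  b <- classify_basic(compute_delta(old, new), old, new)
  expect_equal(sum(b$action == "addP"), 1)
  expect_equal(sum(b$action == "addComment"), 2)
  expect_equal(nrow(b), 3)
})

test_that("deleting a subclass edge is delSupC; individual folding collects all types", {
  old <- mini_version(cls("A"), cls("B"), sub_("A", "B"))
  new <- mini_version(cls("A"), cls("B"))
  b <- classify_basic(compute_delta(old, new), old, new)
  expect_equal(b$action, "delSupC")

  # an individual arriving with two type assertions folds into one addI
  old2 <- mini_version(cls("A"), cls("B"))
  new2 <- mini_version(cls("A"), cls("B"),
                       trow(ex("i"), RDF_TYPE_T, ex("A")),
                       trow(ex("i"), RDF_TYPE_T, ex("B")),
                       lrow(ex("i"), LABEL, "ind"))
  b2 <- classify_basic(compute_delta(old2, new2), old2, new2)
  expect_equal(sum(b2$action == "addI"), 1)
  expect_equal(nrow(b2$payload[[which(b2$action == "addI")]]), 2)
  expect_equal(sum(b2$action == "addLabel"), 1)
  # a type change on a persisting individual degrades to OtherR
  new3 <- mini_version(cls("A"), cls("B"), trow(ex("i"), RDF_TYPE_T, ex("B")))
  old3 <- mini_version(cls("A"), cls("B"), trow(ex("i"), RDF_TYPE_T, ex("A")))
  b3 <- classify_basic(compute_delta(old3, new3), old3, new3)
  expect_setequal(b3$action, c("addOtherR", "delOtherR"))
})

test_that("the all-basics fixture yields exactly 18 basic changes, one per action", {
  fx <- get_suite()$basics
  b <- classify_basic(compute_delta(fx$old, fx$new), fx$old, fx$new)
  expect_equal(nrow(b), 18)
  expect_setequal(b$action, ontodiff:::BASIC_ACTIONS)
})

test_that("classification is symmetric under version swap and conserves triples", {
  fx <- get_suite()$complex_concepts
  fwd <- classify_basic(compute_delta(fx$old, fx$new), fx$old, fx$new)
  rev <- classify_basic(compute_delta(fx$new, fx$old), fx$new, fx$old)
  expect_equal(sort(mirror_action(fwd$action)), sort(rev$action))
  d <- compute_delta(fx$old, fx$new)
  expect_equal(sum(vapply(fwd$payload, nrow, integer(1))),
               nrow(d$added) + nrow(d$deleted))
})
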