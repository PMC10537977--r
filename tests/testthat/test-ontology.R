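test_that("a 12-triple document indexes per the hand-enumerated categorization", {
  # 1 class decl, 1 property decl, 1 individual type, 1 subclass edge,
  # 1 subproperty edge (only one endpoint declared -> not an indexed edge),
  # label, comment, synonym, relationship, second class decl, 2 ind. labels
  v <- mini_version(
    cls("A"), cls("B"), prp("p"),
    sub_("A", "B"),
    trow(ex("q"), SUBPROP, ex("p")),
    trow(ex("i"), RDF_TYPE_T, ex("A")),
    lrow(ex("A"), LABEL, "a label"),
    lrow(ex("A"), COMMENT, "a comment"),
    lrow(ex("A"), ALTLABEL, "a synonym"),
    trow(ex("A"), ex("p"), ex("B")),
    lrow(ex("i"), LABEL, "ind one"),
    lrow(ex("i"), LABEL, "ind two"))
  expect_equal(nrow(v$triples), 12)
  expect_setequal(v$concepts, c(ex("A"), ex("B")))
  expect_equal(v$properties, ex("p"))
  expect_equal(v$individuals, ex("i"))
  expect_equal(nrow(v$class_edges), 1)
  expect_equal(nrow(v$property_edges), 0)  # ex:q is undeclared
  expect_equal(nrow(v$type_assertions), 1)
  expect_equal(nrow(v$attributes), 5)
  expect_setequal(v$attributes$category[v$attributes$entity == ex("A")],
                  c("label", "comment", "other"))
  expect_equal(nrow(v$relationships), 1)
  # re-derivation is a fixed point
  v2 <- ontology_version(v$triples, v$vocab)
  expect_identical(v[setdiff(names(v), "vocab")], v2[setdiff(names(v2), "vocab")])
})

test_that("entity-kind precedence is concept > property > individual", {
  v <- mini_version(cls("A"), cls("B"), prp("A"),
                    trow(ex("A"), RDF_TYPE_T, ex("B")))
  expect_equal(classify_entity(v, ex("A")), "concept")
  v2 <- mini_version(prp("p"), cls("B"), trow(ex("p"), RDF_TYPE_T, ex("B")))
  expect_equal(classify_entity(v2, ex("p")), "property")
  expect_equal(classify_entity(v2, ex("nowhere")), "unknown")
})

test_that("triple categorization is total, deterministic and vocab-driven", {
  old <- mini_version(cls("A"), cls("B"), prp("p"))
  new <- old
  tr <- dplyr::bind_rows(
    sub_("A", "B"),
    lrow(ex("A"), COMMENT, "a finding"),
    lrow(ex("A"), ALTLABEL, "tumour"),
    lrow(ex("A"), LABEL, "tumor"),
    trow(ex("A"), ex("p"), ex("B")),
    cls("A"), prp("p"),
    trow(ex("x"), RDF_TYPE_T, ex("A")),
    trow(ex("A"), ex("p"), ex("unknownEntity")))
  got <- categorize_triple(tr, old, new)
  expect_equal(got, c("subClassEdge", "comment", "otherAttribute", "label",
                      "otherRelationship", "conceptDecl", "propertyDecl",
                      "individualTypeAssertion", "otherRelationship"))
})

test_that("ancestors equals a brute-force matrix transitive closure", {
  # chain
  v <- mini_version(cls("A"), cls("B"), cls("C"),
                    sub_("A", "B"), sub_("B", "C"))
  expect_equal(ancestors(v, ex("A")), sort(c(ex("B"), ex("C"))))
  expect_equal(ancestors(v, ex("C")), character(0))
  # diamond, against an independent matrix-powering closure
  v2 <- mini_version(cls("A"), cls("B"), cls("C"), cls("D"),
                     sub_("A", "B"), sub_("A", "C"),
                     sub_("B", "D"), sub_("C", "D"))
  nodes <- sort(v2$concepts)
  M <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(v2$class_edges)))
    M[v2$class_edges$child[i], v2$class_edges$parent[i]] <- 1
  R <- M
  for (k in seq_len(4)) R <- pmin(R + R %*% M, 1)
  for (n in nodes) {
    expect_equal(ancestors(v2, n), sort(nodes[R[n, ] > 0]), info = n)
  }
})

test_that("cyclic subsumption terminates and excludes the entity itself", {
  v <- mini_version(cls("A"), cls("B"), sub_("A", "B"), sub_("B", "A"))
  expect_setequal(ancestors(v, ex("A")), ex("B"))
  expect_warning(out <- ancestors(v, ex("nope")), "not declared")
  expect_equal(out, character(0))
})

test_that("obsolescence markers: flag, obsolete superclass, label prefix", {
  v <- mini_version(
    cls("A"), trow(ex("A"), DEPRECATED, "true", "literal",
                   NA_character_, "http://www.w3.org/2001/XMLSchema#boolean"),
    cls("B"), lrow(ex("B"), LABEL, "OBSOLETE Heart finding"),
    cls("C"), trow(ex("C"), SUBCLASS,
                   "http://www.geneontology.org/formats/oboInOwl#ObsoleteClass"),
    cls("D"), lrow(ex("D"), LABEL, "healthy"))
  expect_true(is_obsolete(v, ex("A")))
  expect_true(is_obsolete(v, ex("B")))   # case-insensitive prefix
  expect_true(is_obsolete(v, ex("C")))
  expect_false(is_obsolete(v, ex("D")))
  expect_false(is_obsolete(v, ex("absent")))
})

test_that("vocabulary configuration validates disjointness and reads YAML", {
  expect_error(default_vocab(label_predicates = LABEL,
                             comment_predicates = LABEL),
               "overlap")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("label_predicates:",
               paste0("  - ", LABEL),
               "synonym_predicates:",
               paste0("  - ", ALTLABEL)), path)
  v <- read_vocab(path)
  expect_equal(v$label_predicates, LABEL)
  expect_equal(v$synonym_predicates, ALTLABEL)
  expect_equal(v$class_subsumption, SUBCLASS)  # defaulted
})
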