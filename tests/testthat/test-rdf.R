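test_that("turtle parsing handles prefixes, lists, literals and 'a'", {
  doc <- paste(
    "@prefix ex: <http://example.org/t#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "ex:A a <http://www.w3.org/2002/07/owl#Class> ;",
    "  rdfs:label \"heart finding\"@en , \"Herzbefund\"@de ;",
    "  rdfs:seeAlso ex:B .",
    "ex:B rdfs:label \"other\" ; ex:count 3 ; ex:flag true .",
    sep = "\n")
  tr <- parse_turtle(doc)
  expect_equal(nrow(tr), 7)
  expect_setequal(tr$object[tr$predicate == LABEL & tr$subject == ex("A")],
                  c("heart finding", "Herzbefund"))
  expect_equal(tr$lang[tr$subject == ex("A") & tr$object == "Herzbefund"], "de")
  expect_equal(tr$datatype[tr$object == "3"],
               "http://www.w3.org/2001/XMLSchema#integer")
  expect_equal(tr$datatype[tr$object == "true"],
               "http://www.w3.org/2001/XMLSchema#boolean")
  # 'a' expands to rdf:type
  expect_true(any(tr$predicate == RDF_TYPE_T & tr$object == OWL_CLASS))
})

test_that("string escapes round-trip through serialization", {
  weird <- "line1\nline2\t\"quoted\" \\slash\\ café"
  tr <- trow(ex("A"), LABEL, weird, "literal", "en")
  back <- parse_turtle(write_turtle(tr))
  expect_equal(back$object, weird)
  back_nt <- parse_turtle(write_ntriples(tr))
  expect_equal(back_nt$object, weird)
})

test_that("N-Triples documents parse as the Turtle subset they are", {
  doc <- paste0("<", ex("A"), "> <", RDF_TYPE_T, "> <", OWL_CLASS, "> .\n",
                "<", ex("A"), "> <", LABEL, "> \"x\"@en .\n")
  tr <- parse_turtle(doc)
  expect_equal(nrow(tr), 2)
  expect_equal(sort(tr$predicate), sort(c(RDF_TYPE_T, LABEL)))
})

test_that("parse errors name the position and unsupported syntax fails loudly", {
  expect_error(parse_turtle("ex:A ex:b ex:C ."), "undeclared prefix")
  expect_error(parse_turtle("@prefix ex: <http://x/> . ex:A ex:p (1 2) ."),
               "collections")
})

test_that("RDF/XML striped syntax parses: typed nodes, nesting, datatypes, xml:lang", {
  doc <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    ' xmlns:owl="http://www.w3.org/2002/07/owl#"',
    ' xmlns:ex="http://example.org/t#" xml:lang="en">',
    '<owl:Class rdf:about="http://example.org/t#A">',
    '<rdfs:label>heart finding</rdfs:label>',
    '<ex:count rdf:datatype="http://www.w3.org/2001/XMLSchema#integer">4</ex:count>',
    '<rdfs:subClassOf rdf:resource="http://example.org/t#B"/>',
    '<ex:part><owl:Class rdf:about="http://example.org/t#C"/></ex:part>',
    '</owl:Class></rdf:RDF>')
  tr <- parse_rdfxml(doc)
  expect_true(any(tr$subject == ex("A") & tr$predicate == RDF_TYPE_T &
                    tr$object == OWL_CLASS))
  expect_equal(tr$lang[tr$predicate == LABEL], "en")
  expect_equal(tr$datatype[tr$object == "4"],
               "http://www.w3.org/2001/XMLSchema#integer")
  expect_true(any(tr$subject == ex("A") & tr$predicate == SUBCLASS &
                    tr$object == ex("B")))
  expect_true(any(tr$subject == ex("C") & tr$object == OWL_CLASS))
  expect_true(any(tr$predicate == ex("part") & tr$object == ex("C")))
})

test_that("serialize -> parse round-trip is the identity on generated ontologies", {
  base <- generate_base(fixture_spec(seed = 3, n_concepts = 25))
  reparsed <- ontology_version(skolemize_triples(
    parse_turtle(write_turtle(base$triples))), default_vocab())
  expect_true(same_triples(base, reparsed))
  reparsed_nt <- ontology_version(skolemize_triples(
    parse_turtle(write_ntriples(base$triples))), default_vocab())
  expect_true(same_triples(base, reparsed_nt))
})

test_that("skolemization is deterministic on identical input and distinguishes bnodes", {
  doc <- paste(
    "@prefix ex: <http://example.org/t#> .",
    "ex:A ex:p _:b1 . _:b1 ex:q \"one\" .",
    "ex:A ex:p _:b2 . _:b2 ex:q \"two\" .",
    "ex:B ex:p [ ex:q \"anon\" ] .",
    sep = "\n")
  s1 <- skolemize_triples(parse_turtle(doc))
  s2 <- skolemize_triples(parse_turtle(doc))
  expect_identical(write_ntriples(s1), write_ntriples(s2))
  expect_false(any(startsWith(s1$subject, "_:")))
  expect_false(any(s1$object_kind == "bnode"))
  # the two labelled bnodes stay distinct after skolemization
  sk <- s1$object[s1$subject == ex("A")]
  expect_equal(length(unique(sk)), 2)
})
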