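test_that("identical normalized names across different IRIs score 1", {
  old <- mini_version(cls("Old1"), lrow(ex("Old1"), LABEL, "Myocardial infarct"))
  new <- mini_version(cls("New1"), lrow(ex("New1"), LABEL, "myocardial-infarct"))
  m <- builtin_match(old, new, threshold = 0.6)
  expect_equal(nrow(m), 1)
  expect_equal(m$source, ex("Old1"))
  expect_equal(m$target, ex("New1"))
  expect_equal(m$score, 1)
  expect_equal(m$kind, "concept")
})

test_that("obsolete entities are never matched, whatever the similarity", {
  old <- mini_version(cls("Old1"), lrow(ex("Old1"), LABEL, "finding"),
                      trow(ex("Old1"), DEPRECATED, "true", "literal",
                           NA_character_, "http://www.w3.org/2001/XMLSchema#boolean"))
  new <- mini_version(cls("New1"), lrow(ex("New1"), LABEL, "finding"))
  expect_equal(nrow(builtin_match(old, new, threshold = 0)), 0)
})

test_that("matching equals an exhaustive all-pairs scan with the same normalizer", {
  set.seed(7)
  labs_old <- c("kaslo finding", "miret disorder", "zuve process",
                "holun anomaly", "pexa state")
  labs_new <- c("kaslo findings", "mirret disorder", "zuve's process",
                "completely different", "pexa state")
  rows_o <- list(); rows_n <- list()
  for (i in 1:5) {
    rows_o[[i]] <- dplyr::bind_rows(cls(paste0("O", i)),
                                    lrow(ex(paste0("O", i)), LABEL, labs_old[i]))
    rows_n[[i]] <- dplyr::bind_rows(cls(paste0("N", i)),
                                    lrow(ex(paste0("N", i)), LABEL, labs_new[i]))
  }
  old <- mini_version(!!!rows_o); new <- mini_version(!!!rows_n)
  got <- builtin_match(old, new, threshold = 0.6)
  # oracle: enumerate every (old, new) pair over labels + IRI local names
  norm <- function(x) gsub("[^a-z0-9]+", "",
                           tolower(stringi::stri_trans_general(x, "Latin-ASCII")))
  sim <- function(a, b) {
    a <- norm(a); b <- norm(b)
    1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b), 1)
  }
  for (i in 1:5) for (j in 1:5) {
    names_i <- c(labs_old[i], paste0("O", i))
    names_j <- c(labs_new[j], paste0("N", j))
    best <- max(outer(names_i, names_j, Vectorize(sim)))
    hit <- any(got$source == ex(paste0("O", i)) & got$target == ex(paste0("N", j)))
    expect_equal(hit, best >= 0.6, info = paste(i, j))
    if (hit) {
      expect_equal(got$score[got$source == ex(paste0("O", i)) &
                               got$target == ex(paste0("N", j))],
                   best, tolerance = 1e-12)
    }
  }
})

test_that("raising the threshold never adds correspondences", {
  fx <- get_suite()$heuristic_concepts
  prev <- Inf
  for (th in c(0.2, 0.5, 0.8, 1)) {
    n <- nrow(builtin_match(fx$old, fx$new, threshold = th))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the built-in matcher transposes under version swap", {
  fx <- get_suite()$heuristic_concepts
  fwd <- builtin_match(fx$old, fx$new, threshold = 0.6)
  rev <- builtin_match(fx$new, fx$old, threshold = 0.6)
  expect_setequal(paste(fwd$source, fwd$target), paste(rev$target, rev$source))
})

test_that("TSV mappings load, filter to known entities, and report malformed rows", {
  old <- mini_version(cls("A"), cls("B"))
  new <- mini_version(cls("X"), cls("Y"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# source\ttarget\tscore",
               paste(ex("A"), ex("X"), "0.9", sep = "\t"),
               paste(ex("B"), ex("Y"), "0.7", sep = "\t"),
               paste(ex("A"), ex("Y"), "1.0", sep = "\t")), path)
  m <- load_mappings(path, "tsv", old, new)
  expect_equal(nrow(m), 3)
  expect_equal(attr(m, "dropped"), 0)
  # a row pointing at an entity absent from the new version is dropped + counted
  writeLines(c(paste(ex("A"), ex("X"), "0.9", sep = "\t"),
               paste(ex("A"), ex("Missing"), "0.9", sep = "\t")), path)
  expect_message(m2 <- load_mappings(path, "tsv", old, new), "dropped")
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "dropped"), 1)
  writeLines("only-one-column", path)
  expect_error(load_mappings(path, "tsv", old, new), "line 1")
})

test_that("Alignment-Format documents load both cells; thresholding is left to the engine", {
  old <- mini_version(cls("A"), cls("B"))
  new <- mini_version(cls("X"), cls("Y"))
  al <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns="http://knowledgeweb.semanticweb.org/heterogeneity/alignment#">',
    '<Alignment><map><Cell>',
    '<entity1 rdf:resource="', ex("A"), '"/>',
    '<entity2 rdf:resource="', ex("X"), '"/>',
    '<measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">0.9</measure>',
    '</Cell></map><map><Cell>',
    '<entity1 rdf:resource="', ex("B"), '"/>',
    '<entity2 rdf:resource="', ex("Y"), '"/>',
    '<measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">0.5</measure>',
    '</Cell></map></Alignment></rdf:RDF>')
  path <- withr::local_tempfile(fileext = ".rdf")
  writeLines(al, path)
  m <- load_mappings(path, "align", old, new)
  expect_equal(nrow(m), 2)
  expect_setequal(m$score, c(0.9, 0.5))
})
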