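#' Load an ontology version
#'
#' Reads an RDF document, deterministically skolemizes blank nodes, and builds
#' the derived indices (concepts, properties, individuals, subsumption edges,
#' attributes, relationships) the change rules operate on. Format is inferred
#' from the file extension when `format = "auto"` (`.ttl` Turtle, `.nt`
#' N-Triples, `.rdf`/`.owl`/`.xml` RDF/XML).
#'
#' @param source A file path, or a single string of RDF source when
#'   `format` is explicit and `text = TRUE`.
#' @param format `"auto"`, `"turtle"`, `"ntriples"` or `"rdfxml"`.
#' @param vocab A vocabulary configuration, see [default_vocab()].
#' @param text Treat `source` as document text rather than a path.
#' @return An `ontodiff_version` object; see [ontology_version()].
#' @export
load_ontology <- function(source, format = c("auto", "turtle", "ntriples", "rdfxml"),
                          vocab = default_vocab(), text = FALSE) {
  format <- match.arg(format)
  if (!text && !file.exists(source))
    stop("input file not found: ", source, call. = FALSE)
  if (format == "auto") {
    if (text) stop("format must be explicit when passing text", call. = FALSE)
    ext <- tolower(tools::file_ext(source))
    format <- switch(ext,
                     ttl = "turtle", turtle = "turtle",
                     nt = "ntriples", ntriples = "ntriples",
                     rdf = "rdfxml", owl = "rdfxml", xml = "rdfxml",
                     stop("cannot infer RDF format from extension '.", ext,
                          "'; pass format= explicitly", call. = FALSE))
  }
  tr <- switch(format,
    turtle = ,
    ntriples = {
      txt <- if (text) source else
        paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
      parse_turtle(txt, source = if (text) "<text>" else source)
    },
    rdfxml = parse_rdfxml(if (text) source else source,
                          source = if (text) "<text>" else source))
  ontology_version(skolemize_triples(tr), vocab)
}

#' Construct an ontology version from a triple table
#'
#' Derives all indices from the triples and the vocabulary. Entity-kind
#' conflicts are resolved with the precedence concept > property > individual:
#' a subject declared as a class is a concept even if it also carries a type
#' assertion to another class. Subsumption edges are indexed only between
#' declared entities of the right kind (a `rdfs:subClassOf` triple pointing at
#' an undeclared IRI — e.g. an obsolete-superclass marker — still exists in
#' `triples` and is seen by the rules as a triple, not as a hierarchy edge).
#' Re-deriving the indices from `x$triples` is a fixed point.
#'
#' @param triples A skolemized triple tibble.
#' @param vocab A vocabulary configuration.
#' @return An object of class `ontodiff_version` with fields `triples`,
#'   `vocab`, `concepts`, `properties`, `individuals`, `class_edges`,
#'   `property_edges`, `type_assertions`, `attributes`, `relationships`.
#' @export
ontology_version <- function(triples, vocab = default_vocab()) {
  tr <- normalize_triples(triples)
  decl <- tr$predicate == vocab$type_predicate & tr$object_kind != "literal"
  concepts <- unique(tr$subject[decl & tr$object %in% vocab$class_declaration_objects])
  properties <- setdiff(
    unique(tr$subject[decl & tr$object %in% vocab$property_declaration_objects]),
    concepts)
  typed <- decl & !(tr$object %in% c(vocab$class_declaration_objects,
                                     vocab$property_declaration_objects))
  individuals <- setdiff(unique(tr$subject[typed]), c(concepts, properties))

  sub_c <- tr$predicate == vocab$class_subsumption & tr$object_kind != "literal" &
    tr$subject %in% concepts & tr$object %in% concepts
  sub_p <- tr$predicate == vocab$property_subsumption & tr$object_kind != "literal" &
    tr$subject %in% properties & tr$object %in% properties
  class_edges <- tibble::tibble(child = tr$subject[sub_c], parent = tr$object[sub_c])
  property_edges <- tibble::tibble(child = tr$subject[sub_p], parent = tr$object[sub_p])

  ta <- typed & tr$subject %in% individuals
  type_assertions <- tibble::tibble(individual = tr$subject[ta], class = tr$object[ta])

  lit <- tr$object_kind == "literal"
  attr_cat <- dplyr::case_when(
    tr$predicate %in% vocab$label_predicates ~ "label",
    tr$predicate %in% vocab$comment_predicates ~ "comment",
    TRUE ~ "other")
  attributes <- tibble::tibble(
    entity = tr$subject[lit], predicate = tr$predicate[lit],
    value = tr$object[lit], lang = tr$lang[lit], datatype = tr$datatype[lit],
    category = attr_cat[lit])

  rel <- !lit & !decl &
    !(tr$predicate %in% c(vocab$class_subsumption, vocab$property_subsumption))
  relationships <- tibble::tibble(
    subject = tr$subject[rel], predicate = tr$predicate[rel], object = tr$object[rel])

  structure(list(triples = tr, vocab = vocab,
                 concepts = stable_sort(concepts),
                 properties = stable_sort(properties),
                 individuals = stable_sort(individuals),
                 class_edges = dplyr::distinct(class_edges),
                 property_edges = dplyr::distinct(property_edges),
                 type_assertions = dplyr::distinct(type_assertions),
                 attributes = attributes,
                 relationships = relationships),
            class = "ontodiff_version")
}

#' @export
print.ontodiff_version <- function(x, ...) {
  cat("<ontology version>", nrow(x$triples), "triples |",
      length(x$concepts), "concepts,", length(x$properties), "properties,",
      length(x$individuals), "individuals |",
      nrow(x$class_edges), "subclass edges\n")
  invisible(x)
}

#' Classify an entity of a version
#'
#' @param version An `ontodiff_version`.
#' @param entity Character vector of IRIs.
#' @return One of `"concept"`, `"property"`, `"individual"`, `"unknown"` per
#'   IRI (precedence concept > property > individual for conflicting
#'   declarations).
#' @export
classify_entity <- function(version, entity) {
  dplyr::case_when(entity %in% version$concepts ~ "concept",
                   entity %in% version$properties ~ "property",
                   entity %in% version$individuals ~ "individual",
                   TRUE ~ "unknown")
}

#' Categorize triples for the change rules
#'
#' Total, deterministic first-match-wins categorization: declaration triples,
#' then individual type assertions, then subsumption edges, then literal
#' attributes split into label / comment / other (synonym predicates are
#' deliberately *other*, so synonym edits never look like label changes), and
#' finally other relationships.
#'
#' @param tr A triple tibble.
#' @param old,new The two `ontodiff_version`s providing entity-kind context
#'   (an IRI is an individual if either version indexes it as one and neither
#'   declares it as a class or property).
#' @param vocab A vocabulary configuration.
#' @return Character vector: one of `conceptDecl`, `propertyDecl`,
#'   `individualTypeAssertion`, `subClassEdge`, `subPropertyEdge`, `label`,
#'   `comment`, `otherAttribute`, `otherRelationship` per row.
#' @export
categorize_triple <- function(tr, old, new, vocab = old$vocab) {
  concepts <- union(old$concepts, new$concepts)
  properties <- union(old$properties, new$properties)
  is_decl <- tr$predicate == vocab$type_predicate & tr$object_kind != "literal"
  cls_decl <- is_decl & tr$object %in% vocab$class_declaration_objects
  prp_decl <- is_decl & tr$object %in% vocab$property_declaration_objects
  ind_subj <- !(tr$subject %in% concepts) & !(tr$subject %in% properties)
  lit <- tr$object_kind == "literal"
  dplyr::case_when(
    cls_decl ~ "conceptDecl",
    prp_decl ~ "propertyDecl",
    is_decl & ind_subj ~ "individualTypeAssertion",
    tr$predicate == vocab$class_subsumption & !lit ~ "subClassEdge",
    tr$predicate == vocab$property_subsumption & !lit ~ "subPropertyEdge",
    lit & tr$predicate %in% vocab$label_predicates ~ "label",
    lit & tr$predicate %in% vocab$comment_predicates ~ "comment",
    lit ~ "otherAttribute",
    TRUE ~ "otherRelationship")
}

#' Transitive ancestors in the subsumption hierarchy
#'
#' Transitive closure over the chosen edge relation, excluding the entity
#' itself. Cycles are tolerated (visited-set traversal); an undeclared entity
#' yields an empty set with a warning.
#'
#' @param version An `ontodiff_version`.
#' @param entity A single IRI.
#' @param edge_kind `"class_edges"` or `"property_edges"`.
#' @return Character vector of ancestor IRIs (sorted).
#' @export
ancestors <- function(version, entity, edge_kind = c("class_edges", "property_edges")) {
  edge_kind <- match.arg(edge_kind)
  declared <- if (edge_kind == "class_edges") version$concepts else version$properties
  if (!entity %in% declared) {
    warning("entity not declared in this version: ", entity, call. = FALSE)
    return(character(0))
  }
  edges <- version[[edge_kind]]
  seen <- character(0)
  frontier <- entity
  while (length(frontier) > 0) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, c(seen, entity))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  stable_sort(seen)
}

descendants <- function(version, entity, edge_kind = "class_edges") {
  edges <- version[[edge_kind]]
  seen <- character(0)
  frontier <- entity
  while (length(frontier) > 0) {
    nxt <- unique(edges$child[edges$parent %in% frontier])
    nxt <- setdiff(nxt, c(seen, entity))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  stable_sort(seen)
}

direct_parents <- function(version, entity, edge_kind = "class_edges") {
  edges <- version[[edge_kind]]
  stable_sort(unique(edges$parent[edges$child == entity]))
}

#' Obsolescence test
#'
#' True iff any configured obsolescence marker matches the entity in this
#' version: a deprecation flag triple, an obsolete-superclass membership (via
#' type or subsumption), or a label starting (case-insensitively) with the
#' configured prefix.
#'
#' @inheritParams ancestors
#' @param vocab A vocabulary configuration.
#' @return Logical.
#' @export
is_obsolete <- function(version, entity, vocab = version$vocab) {
  tr <- version$triples
  mine <- tr[tr$subject == entity, , drop = FALSE]
  if (nrow(mine) == 0) return(FALSE)
  for (m in vocab$obsolescence_markers) {
    hit <- switch(m$kind,
      flag = any(mine$predicate == m$predicate & mine$object_kind == "literal" &
                   tolower(mine$object) %in% c(tolower(m$value), "1")),
      class = any(mine$object_kind != "literal" & mine$object == m$iri &
                    mine$predicate %in% c(vocab$type_predicate,
                                          vocab$class_subsumption)),
      label_prefix = any(mine$object_kind == "literal" &
                           mine$predicate %in% vocab$label_predicates &
                           startsWith(tolower(mine$object), tolower(m$prefix))),
      FALSE)
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

# vectorised over entities, used by the matcher
obsolete_entities <- function(version, entities, vocab = version$vocab) {
  entities[vapply(entities, function(e) is_obsolete(version, e, vocab), logical(1))]
}

# marker-triple flag used by the delta classifier: does this triple, on its
# own, encode an obsolescence marker?
triple_is_obsolescence_marker <- function(tr, vocab) {
  out <- rep(FALSE, nrow(tr))
  for (m in vocab$obsolescence_markers) {
    out <- out | switch(m$kind,
      flag = tr$predicate == m$predicate & tr$object_kind == "literal" &
        tolower(tr$object) %in% c(tolower(m$value), "1"),
      class = tr$object_kind != "literal" & tr$object == m$iri &
        tr$predicate %in% c(vocab$type_predicate, vocab$class_subsumption),
      label_prefix = tr$object_kind == "literal" &
        tr$predicate %in% vocab$label_predicates &
        startsWith(tolower(tr$object), tolower(m$prefix)),
      FALSE)
  }
  out
}
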