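#' Vocabulary configuration
#'
#' The change rules need to know which predicates carry labels, comments and
#' synonyms, which predicate encodes subsumption for classes and for
#' properties, and how obsolescence (deprecation without deletion) is marked.
#' `default_vocab()` returns the configuration used throughout the package:
#' RDFS/SKOS labels and comments, SKOS/oboInOwl synonyms, `rdfs:subClassOf` /
#' `rdfs:subPropertyOf` subsumption, and three obsolescence conventions
#' (an `owl:deprecated = true` flag, membership of an obsolete superclass as
#' used by OBO-derived ontologies, and a case-insensitive `"obsolete"` label
#' prefix).
#'
#' @param label_predicates,comment_predicates,synonym_predicates Character
#'   vectors of absolute predicate IRIs. The three sets must be pairwise
#'   disjoint.
#' @param class_subsumption,property_subsumption,type_predicate Single IRIs.
#' @param class_declaration_objects,property_declaration_objects Objects of a
#'   `type_predicate` triple that declare the subject to be a class resp. a
#'   property.
#' @param obsolescence_markers A list of marker rules; each rule is a list with
#'   a `kind` of `"flag"` (fields `predicate`, `value`), `"class"` (field
#'   `iri`: obsolete-superclass IRI, matched as `rdf:type` or subclass object)
#'   or `"label_prefix"` (field `prefix`, matched case-insensitively against
#'   label literals).
#' @return A `ontodiff_vocab` list.
#' @export
default_vocab <- function(
    label_predicates = c(RDFS_LABEL, paste0(NS$skos, "prefLabel")),
    comment_predicates = c(RDFS_COMMENT, paste0(NS$skos, "definition")),
    synonym_predicates = c(paste0(NS$skos, "altLabel"),
                           paste0(NS$obo, "hasExactSynonym"),
                           paste0(NS$obo, "hasRelatedSynonym")),
    class_subsumption = RDFS_SUBCLASS,
    property_subsumption = RDFS_SUBPROP,
    type_predicate = RDF_TYPE,
    class_declaration_objects = c(paste0(NS$owl, "Class"),
                                  paste0(NS$rdfs, "Class")),
    property_declaration_objects = c(paste0(NS$owl, "ObjectProperty"),
                                     paste0(NS$owl, "DatatypeProperty"),
                                     paste0(NS$owl, "AnnotationProperty"),
                                     paste0(NS$rdf, "Property")),
    obsolescence_markers = list(
      list(kind = "flag", predicate = OWL_DEPRECATED, value = "true"),
      list(kind = "class", iri = paste0(NS$obo, "ObsoleteClass")),
      list(kind = "label_prefix", prefix = "obsolete")
    )) {
  v <- list(
    label_predicates = label_predicates,
    comment_predicates = comment_predicates,
    synonym_predicates = synonym_predicates,
    class_subsumption = class_subsumption,
    property_subsumption = property_subsumption,
    type_predicate = type_predicate,
    class_declaration_objects = class_declaration_objects,
    property_declaration_objects = property_declaration_objects,
    obsolescence_markers = obsolescence_markers
  )
  validate_vocab(v)
  structure(v, class = "ontodiff_vocab")
}

validate_vocab <- function(v) {
  assert_that(length(v$label_predicates) > 0 && length(v$comment_predicates) > 0 &&
                length(v$synonym_predicates) > 0,
              "label, comment and synonym predicate sets must be non-empty")
  overlap <- c(intersect(v$label_predicates, v$comment_predicates),
               intersect(v$label_predicates, v$synonym_predicates),
               intersect(v$comment_predicates, v$synonym_predicates))
  assert_that(length(overlap) == 0,
              paste("label/comment/synonym predicate sets overlap:",
                    paste(overlap, collapse = ", ")))
  invisible(v)
}

#' Read a vocabulary configuration file
#'
#' The file is YAML with keys `label_predicates`, `comment_predicates`,
#' `synonym_predicates`, `class_subsumption`, `property_subsumption` and
#' `obsolescence_markers` (a list of marker rules as in [default_vocab()]).
#' Omitted keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `ontodiff_vocab` list.
#' @export
read_vocab <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  d <- default_vocab()
  take <- function(key) y[[key]] %||% d[[key]]
  markers <- y$obsolescence_markers %||% d$obsolescence_markers
  default_vocab(
    label_predicates = unlist(take("label_predicates")),
    comment_predicates = unlist(take("comment_predicates")),
    synonym_predicates = unlist(take("synonym_predicates")),
    class_subsumption = take("class_subsumption")[[1]],
    property_subsumption = take("property_subsumption")[[1]],
    obsolescence_markers = markers
  )
}
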