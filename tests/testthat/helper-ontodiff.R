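# Shared fixtures and oracles for the test suite. Expensive objects (the
# standard suite, the randomized-pair batch) are built once per session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

get_suite <- function() cached("suite", standard_suite())

get_suite_results <- function() cached("suite_results", {
  lapply(get_suite(), function(fx) {
    list(fx = fx, res = compute_diff(fx$old, fx$new, mapping = fx$ledger$mapping))
  })
})

# 200 randomized pairs, diffed with their perfect mapping
get_random_results <- function(n = 200) cached("random_results", {
  lapply(seq_len(n), function(s) {
    fx <- random_fixture_pair(s)
    list(fx = fx, res = compute_diff(fx$old, fx$new, mapping = fx$ledger$mapping))
  })
})

# small hand-built version pair: wrap triple rows into versions
mini_version <- function(...) {
  ontology_version(dplyr::bind_rows(...), default_vocab())
}

trow <- function(s, p, o, kind = "iri", lang = NA_character_, dt = NA_character_) {
  tibble::tibble(subject = s, predicate = p, object = o, object_kind = kind,
                 lang = lang, datatype = dt)
}
lrow <- function(s, p, v, lang = "en") trow(s, p, v, "literal", lang)

OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
OWL_OBJPROP <- "http://www.w3.org/2002/07/owl#ObjectProperty"
RDF_TYPE_T <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
SUBPROP <- "http://www.w3.org/2000/01/rdf-schema#subPropertyOf"
LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
COMMENT <- "http://www.w3.org/2000/01/rdf-schema#comment"
ALTLABEL <- "http://www.w3.org/2004/02/skos/core#altLabel"
DEPRECATED <- "http://www.w3.org/2002/07/owl#deprecated"
EX_ <- "http://example.org/t#"
ex <- function(x) paste0(EX_, x)

cls <- function(x) trow(ex(x), RDF_TYPE_T, OWL_CLASS)
prp <- function(x) trow(ex(x), RDF_TYPE_T, OWL_OBJPROP)
sub_ <- function(a, b) trow(ex(a), SUBCLASS, ex(b))
subp <- function(a, b) trow(ex(a), SUBPROP, ex(b))

# mirror tables for the symmetry property
mirror_action <- function(a) {
  swap <- c(addC = "delC", delC = "addC", addP = "delP", delP = "addP",
            addI = "delI", delI = "addI",
            addSupC = "delSupC", delSupC = "addSupC",
            addSupP = "delSupP", delSupP = "addSupP",
            addComment = "delComment", delComment = "addComment",
            addLabel = "delLabel", delLabel = "addLabel",
            addOtherA = "delOtherA", delOtherA = "addOtherA",
            addOtherR = "delOtherR", delOtherR = "addOtherR",
            mergeC = "splitC", splitC = "mergeC",
            mergeCInto = "splitCInto", splitCInto = "mergeCInto",
            mergeP = "splitP", splitP = "mergeP",
            mergePInto = "splitPInto", splitPInto = "mergePInto",
            pullUpC = "pullDownC", pullDownC = "pullUpC",
            pullUpP = "pullDownP", pullDownP = "pullUpP",
            toObsC = "revObsC", revObsC = "toObsC",
            toObsP = "revObsP", revObsP = "toObsP",
            addLeafC = "delLeafC", delLeafC = "addLeafC",
            addLeafP = "delLeafP", delLeafP = "addLeafP",
            addSubGraphC = "delSubGraphC", delSubGraphC = "addSubGraphC",
            addSubGraphP = "delSubGraphP", delSubGraphP = "addSubGraphP",
            reclassIHigher = "reclassILower", reclassILower = "reclassIHigher")
  if (length(a) == 0) return(character(0))
  ifelse(a %in% names(swap), unname(swap[a]), a)
}

mirror_args <- function(action, args) {
  if (action %in% c("mergeC", "mergeP", "mergeCInto", "mergePInto"))
    return(list(source = args$target, targets = args$sources))
  if (action %in% c("splitC", "splitP", "splitCInto", "splitPInto"))
    return(list(sources = args$targets, target = args$source))
  if (action %in% c("renC", "renP", "renI"))
    return(list(old = args$new, new = args$old))
  if (!is.null(args$old_parents))
    return(list(entity = args$entity, old_parents = args$new_parents,
                new_parents = args$old_parents))
  if (!is.null(args$old_type))
    return(list(individual = args$individual, old_type = args$new_type,
                new_type = args$old_type))
  if (!is.null(args$old_value))
    return(list(entity = args$entity, predicate = args$predicate,
                old_value = args$new_value, old_lang = args$new_lang,
                new_value = args$old_value, new_lang = args$old_lang))
  args
}

transpose_mapping <- function(m) {
  mapping_tbl(m$target, m$source, m$score, m$kind)
}

result_instances <- function(res) {
  dplyr::bind_rows(res$heuristic, res$complex)
}

instance_key_set <- function(inst) {
  vapply(seq_len(nrow(inst)), function(i)
    ontodiff:::canonical_instance_key(inst$action[[i]], inst$arguments[[i]]),
    character(1))
}

mirrored_key_set <- function(inst) {
  vapply(seq_len(nrow(inst)), function(i)
    ontodiff:::canonical_instance_key(
      mirror_action(inst$action[[i]]),
      mirror_args(inst$action[[i]], inst$arguments[[i]])),
    character(1))
}
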