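OC_NS <- "https://w3id.org/ontochange#"

#' Load the bundled change-action taxonomy
#'
#' Parses the Turtle taxonomy shipped with the package: 60 change-action
#' classes (51 leaves plus 9 interior classes) forming a tree, 9 object
#' properties and 7 data properties. Two interior classes (`moveC`,
#' `recastI`) are instantiable generalizations of their directional
#' specializations; the shipped reconciliation table
#' (`taxonomy-reconciliation.csv`) records this authoring decision.
#'
#' @param path Path to a taxonomy Turtle file; defaults to the bundled one.
#' @return An `ontodiff_taxonomy`: list with `classes` (tibble: `id`, `iri`,
#'   `parent`, `category`, `abstract`, `leaf`, `signature` list-column),
#'   `object_properties`, `data_properties`, `reconciliation`.
#' @export
load_taxonomy <- function(path = system.file("extdata", "change-taxonomy.ttl",
                                             package = "ontodiff")) {
  if (!nzchar(path) || !file.exists(path))
    stop("bundled taxonomy file not found", call. = FALSE)
  tr <- parse_turtle(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                           collapse = "\n"), source = path)
  owl_class <- paste0(NS$owl, "Class")
  cls_iri <- tr$subject[tr$predicate == RDF_TYPE & tr$object == owl_class]
  obj_props <- tr$subject[tr$predicate == RDF_TYPE &
                            tr$object == paste0(NS$owl, "ObjectProperty")]
  dat_props <- tr$subject[tr$predicate == RDF_TYPE &
                            tr$object == paste0(NS$owl, "DatatypeProperty")]
  parent_of <- function(iri) {
    p <- tr$object[tr$subject == iri & tr$predicate == RDFS_SUBCLASS]
    if (length(p) == 0) NA_character_ else p[[1]]
  }
  flag_of <- function(iri, pred) {
    v <- tr$object[tr$subject == iri & tr$predicate == paste0(OC_NS, pred)]
    if (length(v) == 0) NA_character_ else v[[1]]
  }
  classes <- tibble::tibble(
    iri = stable_sort(cls_iri),
    id = iri_local_name(stable_sort(cls_iri)))
  classes$parent <- iri_local_name(unname(vapply(classes$iri, parent_of, character(1))))
  classes$abstract <- unname(!is.na(vapply(classes$iri, flag_of, character(1),
                                           pred = "abstract")))
  classes$leaf <- !(classes$id %in% classes$parent)
  classes$signature <- lapply(
    vapply(classes$iri, flag_of, character(1), pred = "signature"),
    parse_signature)
  # category = top-level branch below the root
  root <- classes$id[is.na(classes$parent)]
  assert_that(length(root) == 1, "taxonomy must have a single root class")
  classes$category <- unname(vapply(classes$id, function(id) {
    anc <- id
    repeat {
      p <- classes$parent[classes$id == anc]
      if (is.na(p)) return(NA_character_)
      if (p == root) return(switch(anc, BasicChange = "Basic",
                                   HeuristicChange = "Heuristic",
                                   ComplexChange = "Complex", NA_character_))
      anc <- p
    }
  }, character(1)))

  recon_path <- file.path(dirname(path), "taxonomy-reconciliation.csv")
  reconciliation <- if (file.exists(recon_path)) {
    readr::read_csv(recon_path, show_col_types = FALSE)
  } else tibble::tibble()

  assert_that(!anyDuplicated(classes$id), "taxonomy class ids must be unique")
  structure(list(classes = classes,
                 object_properties = stable_sort(obj_props),
                 data_properties = stable_sort(dat_props),
                 reconciliation = reconciliation,
                 namespace = OC_NS),
            class = "ontodiff_taxonomy")
}

parse_signature <- function(sig) {
  if (is.na(sig)) return(NULL)
  roles <- strsplit(sig, ";", fixed = TRUE)[[1]]
  out <- lapply(roles, function(r) {
    kv <- strsplit(r, ":", fixed = TRUE)[[1]]
    type <- kv[[2]]
    min_n <- 1L
    m <- regmatches(type, regexpr("[0-9]+$", type))
    if (length(m) == 1 && nzchar(m)) {
      min_n <- as.integer(m)
      type <- sub("[0-9]+$", "", type)
    }
    if (type == "parentSet") min_n <- 0L
    list(role = kv[[1]], type = type, min = min_n)
  })
  stats::setNames(out, vapply(out, `[[`, "", "role"))
}

#' @export
print.ontodiff_taxonomy <- function(x, ...) {
  cat("<change taxonomy>", nrow(x$classes), "classes (",
      sum(x$classes$leaf), "leaves,", sum(!x$classes$leaf), "interior ),",
      length(x$object_properties), "object properties,",
      length(x$data_properties), "data properties\n")
  invisible(x)
}

#' Validate a change instance against the taxonomy
#'
#' Checks that the action exists and is instantiable (carries a signature),
#' that every signature role is bound with the right cardinality (e.g. a
#' merge's source set needs at least two entities), and that composite
#' instances record a non-empty consumption list while basic instances record
#' none. Problems are reported, never thrown.
#'
#' @param inst A one-row slice of an instances tibble, or a list with fields
#'   `action`, `arguments`, `consumed`.
#' @param tax An `ontodiff_taxonomy`.
#' @return A tibble of validation failures (`field`, `message`); zero rows
#'   means valid.
#' @export
validate_instance <- function(inst, tax) {
  fails <- list()
  add_fail <- function(field, message) {
    fails[[length(fails) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  action <- if (is.data.frame(inst)) inst$action[[1]] else inst$action
  arguments <- if (is.data.frame(inst)) inst$arguments[[1]] else inst$arguments
  consumed <- if (is.data.frame(inst)) inst$consumed[[1]] else inst$consumed %||% character(0)

  row <- tax$classes[tax$classes$id == action, , drop = FALSE]
  if (nrow(row) == 0) {
    add_fail("action", paste0("unknown change action '", action, "'"))
    return(dplyr::bind_rows(fails))
  }
  sig <- row$signature[[1]]
  if (is.null(sig)) {
    add_fail("action", paste0("'", action, "' is not instantiable"))
    return(dplyr::bind_rows(fails))
  }
  for (role in sig) {
    v <- arguments[[role$role]]
    if (is.null(v) || length(v) == 0 || all(is.na(v))) {
      if (role$min > 0)
        add_fail(role$role, paste0("missing required argument '", role$role, "'"))
      next
    }
    if (length(v) < role$min)
      add_fail(role$role, paste0(
        "argument '", role$role, "' must contain at least ", role$min,
        if (role$type == "entitySet") " entities" else " values"))
    if (role$type %in% c("entity", "predicate") && length(v) != 1)
      add_fail(role$role, paste0("argument '", role$role, "' must be a single IRI"))
  }
  extra <- setdiff(names(arguments),
                   c(names(sig), "old_lang", "new_lang", "old_datatype",
                     "new_datatype", "score"))
  if (length(extra) > 0)
    add_fail("arguments", paste0("unknown argument role(s): ",
                                 paste(extra, collapse = ", ")))
  category <- row$category[[1]]
  if (category %in% c("Heuristic", "Complex") && length(consumed) == 0)
    add_fail("consumed", "composite instances must consume at least one basic change")
  if (identical(category, "Basic") && length(consumed) > 0)
    add_fail("consumed", "basic changes do not consume other changes")
  if (length(fails) == 0) {
    tibble::tibble(field = character(0), message = character(0))
  } else dplyr::bind_rows(fails)
}
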