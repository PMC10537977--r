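#' Entity mappings between versions
#'
#' A mapping is a tibble of scored correspondences `source` (old-version IRI),
#' `target` (new-version IRI), `score` in \[0, 1\] and `kind`
#' (`concept`/`property`/`individual`). Heuristic change detection is gated
#' entirely on these correspondences; an empty mapping disables
#' merge/split/rename detection.
#'
#' @param source,target Character vectors of IRIs.
#' @param score Numeric in \[0, 1\].
#' @param kind Character: `concept`, `property` or `individual`.
#' @return An `ontodiff_mapping` tibble.
#' @export
mapping_tbl <- function(source = character(), target = character(),
                        score = numeric(), kind = character()) {
  assert_that(all(score >= 0 & score <= 1), "mapping scores must lie in [0, 1]")
  out <- tibble::tibble(source = as.character(source),
                        target = as.character(target),
                        score = as.numeric(score), kind = as.character(kind))
  out <- dplyr::distinct(out, source, target, .keep_all = TRUE)
  out <- out[stable_order(-out$score, out$source, out$target), , drop = FALSE]
  class(out) <- c("ontodiff_mapping", class(out))
  out
}

# strip the mapping subclass so dplyr verbs return plain tibbles internally
as_plain <- function(x) { class(x) <- setdiff(class(x), "ontodiff_mapping"); x }

# lexical normalizer shared by the matcher and its test oracle: lowercase,
# fold to ASCII, collapse punctuation/whitespace runs
normalize_name <- function(x) {
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- tolower(x)
  gsub("[^a-z0-9]+", "", x)
}

# normalized Levenshtein similarity between two string vectors (pairwise max
# handled by callers); returns in [0, 1]
edit_similarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(numeric(0))
  d <- utils::adist(a, b)
  ml <- outer(nchar(a), nchar(b), pmax)
  s <- 1 - d / pmax(ml, 1L)
  s[ml == 0] <- 1  # two empty names are identical
  s
}

# names the matcher consults for an entity: labels + synonyms + IRI local name
entity_names <- function(version, entities, vocab = version$vocab) {
  at <- version$attributes
  nm <- at[at$entity %in% entities &
             at$predicate %in% c(vocab$label_predicates, vocab$synonym_predicates), ,
           drop = FALSE]
  base <- tibble::tibble(entity = entities, name = iri_local_name(entities))
  dplyr::bind_rows(base, tibble::tibble(entity = nm$entity, name = nm$value))
}

#' Built-in lexical matcher
#'
#' Scores candidate pairs between delta-affected entities (deleted-side x
#' added-side, per entity kind) by the best normalized edit similarity over
#' the union of their labels, synonyms and IRI local names; local-name
#' equality scores 1. Obsolete entities are excluded on both sides, and pairs
#' below `threshold` are dropped. Many-to-many correspondences are kept
#' (merges need N:1, splits 1:N). Persisting entities are not enumerated here:
#' the engine treats them as implicitly identity-mapped.
#'
#' @param old,new `ontodiff_version` objects.
#' @param vocab Vocabulary configuration.
#' @param threshold Minimum similarity in \[0, 1\]; the default mirrors the
#'   60% alignment threshold commonly used for biomedical ontology matching.
#' @return An `ontodiff_mapping` tibble, ordered by descending score then
#'   lexicographic IRIs (the deterministic tie-break used downstream).
#' @export
builtin_match <- function(old, new, vocab = old$vocab, threshold = 0.6) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must lie in [0, 1]")
  out <- list()
  for (kind in c("concept", "property", "individual")) {
    slot <- switch(kind, concept = "concepts", property = "properties",
                   individual = "individuals")
    gone <- setdiff(old[[slot]], new[[slot]])
    came <- setdiff(new[[slot]], old[[slot]])
    gone <- setdiff(gone, obsolete_entities(old, gone, vocab))
    came <- setdiff(came, obsolete_entities(new, came, vocab))
    if (length(gone) == 0 || length(came) == 0) next
    nm_old <- entity_names(old, gone, vocab)
    nm_new <- entity_names(new, came, vocab)
    nm_old$norm <- normalize_name(nm_old$name)
    nm_new$norm <- normalize_name(nm_new$name)
    sim <- edit_similarity(nm_old$norm, nm_new$norm)
    # best name-pair score per entity pair
    best <- stats::aggregate(
      sim ~ s + t,
      data = data.frame(s = rep(nm_old$entity, times = nrow(nm_new)),
                        t = rep(nm_new$entity, each = nrow(nm_old)),
                        sim = as.vector(sim)),
      FUN = max)
    keep <- best[best$sim >= threshold, , drop = FALSE]
    if (nrow(keep) > 0) {
      out[[kind]] <- tibble::tibble(source = keep$s, target = keep$t,
                                    score = pmin(keep$sim, 1), kind = kind)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(mapping_tbl())
  mapping_tbl(res$source, res$target, res$score, res$kind)
}

#' Load an entity mapping file
#'
#' Two dialects: `tsv` — three tab-separated columns
#' `source_iri<TAB>target_iri<TAB>score`, `#`-prefixed header/comment lines
#' ignored; `align` — Alignment-Format RDF/XML (`Cell` elements with
#' `entity1`/`entity2`/`measure`). Rows whose source is absent from the old
#' version or whose target is absent from the new version are dropped (the
#' count is reported in a message and in the `dropped` attribute), as are
#' correspondences involving an entity obsolete in its own version. Kinds are
#' inferred with [classify_entity()]. No threshold is applied here; filtering
#' is the engine's job.
#'
#' @param path Path to the mapping file.
#' @param format `"tsv"` or `"align"`.
#' @param old,new `ontodiff_version` objects used for filtering and kind
#'   inference.
#' @return An `ontodiff_mapping` tibble with attribute `dropped`.
#' @export
load_mappings <- function(path, format = c("tsv", "align"), old, new) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  raw <- if (format == "tsv") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2)
    if (length(bad) > 0)
      stop("malformed mapping row at line ", keep[bad[1]], " of ", path,
           call. = FALSE)
    score <- vapply(parts, function(p) {
      if (length(p) >= 3) suppressWarnings(as.numeric(p[[3]])) else 1
    }, numeric(1))
    if (anyNA(score))
      stop("non-numeric score at line ", keep[which(is.na(score))[1]], " of ",
           path, call. = FALSE)
    tibble::tibble(source = vapply(parts, `[[`, "", 1L),
                   target = vapply(parts, `[[`, "", 2L),
                   score = score)
  } else {
    tr <- parse_rdfxml(path, source = path)
    cells <- unique(tr$subject[tr$predicate == paste0(ALIGN_NS, "entity1")])
    purrr::map_dfr(cells, function(cl) {
      rs <- tr[tr$subject == cl, , drop = FALSE]
      e1 <- rs$object[rs$predicate == paste0(ALIGN_NS, "entity1")]
      e2 <- rs$object[rs$predicate == paste0(ALIGN_NS, "entity2")]
      ms <- rs$object[rs$predicate == paste0(ALIGN_NS, "measure")]
      if (length(e1) == 0 || length(e2) == 0) return(NULL)
      tibble::tibble(source = e1[[1]], target = e2[[1]],
                     score = if (length(ms) > 0) as.numeric(ms[[1]]) else 1)
    })
  }
  if (nrow(raw) == 0) return(mapping_tbl())

  known_old <- c(old$concepts, old$properties, old$individuals)
  known_new <- c(new$concepts, new$properties, new$individuals)
  in_version <- raw$source %in% known_old & raw$target %in% known_new
  obsolete <- rep(FALSE, nrow(raw))
  obsolete[in_version] <-
    raw$source[in_version] %in% obsolete_entities(old, unique(raw$source[in_version])) |
    raw$target[in_version] %in% obsolete_entities(new, unique(raw$target[in_version]))
  keep <- in_version & !obsolete
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " mapping row(s) dropped (unknown entity or obsolete)")
  raw <- raw[keep, , drop = FALSE]
  kind <- classify_entity(old, raw$source)
  res <- mapping_tbl(raw$source, raw$target, pmin(pmax(raw$score, 0), 1), kind)
  attr(res, "dropped") <- dropped
  res
}

ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment#"
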