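#' Low-level delta between two versions
#'
#' Exact syntactic set difference of the (skolemized) triple sets, split by
#' direction: `added` are triples of the new version absent from the old,
#' `deleted` the converse. No entailment is computed.
#'
#' @param old,new `ontodiff_version` objects loaded with the same vocabulary.
#' @return An `ontodiff_delta`: list with triple tibbles `added` and `deleted`.
#' @export
compute_delta <- function(old, new) {
  k_old <- render_ntriple(old$triples)
  k_new <- render_ntriple(new$triples)
  structure(list(added = new$triples[!(k_new %in% k_old), , drop = FALSE],
                 deleted = old$triples[!(k_old %in% k_new), , drop = FALSE]),
            class = "ontodiff_delta")
}

#' @export
print.ontodiff_delta <- function(x, ...) {
  cat("<triple delta>", nrow(x$added), "added,", nrow(x$deleted), "deleted\n")
  invisible(x)
}

# the 18 basic change action ids
BASIC_ACTIONS <- c("addC", "delC", "addP", "delP", "addI", "delI",
                   "addSupC", "delSupC", "addSupP", "delSupP",
                   "addComment", "delComment", "addLabel", "delLabel",
                   "addOtherA", "delOtherA", "addOtherR", "delOtherR")

empty_basics <- function() {
  tibble::tibble(id = character(), action = character(), direction = character(),
                 subject = character(), predicate = character(),
                 object = character(), lang = character(), datatype = character(),
                 obs_flag = logical(), payload = list())
}

basic_row <- function(action, direction, subject, payload, obs_flag = FALSE) {
  one <- nrow(payload) == 1
  tibble::tibble(
    id = content_hash(paste(action, direction,
                            paste(stable_sort(render_ntriple(payload)), collapse = "|"))),
    action = action, direction = direction, subject = subject,
    predicate = if (one) payload$predicate else NA_character_,
    object = if (one) payload$object else NA_character_,
    lang = if (one) payload$lang else NA_character_,
    datatype = if (one) payload$datatype else NA_character_,
    obs_flag = obs_flag, payload = list(payload))
}

# canonical comparison key for a basic change (independent of the hash)
basic_key <- function(basics) {
  vapply(seq_len(nrow(basics)), function(i) {
    paste0(basics$action[[i]], "|",
           paste(stable_sort(render_ntriple(basics$payload[[i]])), collapse = "|"))
  }, character(1))
}

#' Classify the delta into basic changes
#'
#' Every delta triple is covered by exactly one basic change, following the
#' total categorization of [categorize_triple()] plus the individual-folding
#' rule: `addI(i)` fires once for an individual absent from the old version
#' and consumes all of `i`'s added type-assertion triples (`delI`
#' symmetrically); type-assertion edits on an individual present in both
#' versions become `addOtherR`/`delOtherR`, which the reclassification rules
#' can later pair. Triples that on their own encode an obsolescence marker are
#' classified normally but flagged, so the obsolescence rules get first claim
#' on them.
#'
#' @param delta An `ontodiff_delta` derived from `(old, new)`.
#' @inheritParams compute_delta
#' @param vocab Vocabulary configuration (defaults to the old version's).
#' @return A tibble of basic changes: `id`, `action`, `direction`, `subject`,
#'   single-triple convenience columns, `obs_flag` and a `payload` list-column
#'   of backing triples.
#' @export
classify_basic <- function(delta, old, new, vocab = old$vocab) {
  classify_side <- function(tr, direction, this, other) {
    if (nrow(tr) == 0) return(empty_basics())
    cat <- categorize_triple(tr, old, new, vocab)
    obs <- triple_is_obsolescence_marker(tr, vocab)
    add <- direction == "add"
    act <- dplyr::case_when(
      cat == "conceptDecl" ~ if (add) "addC" else "delC",
      cat == "propertyDecl" ~ if (add) "addP" else "delP",
      cat == "subClassEdge" ~ if (add) "addSupC" else "delSupC",
      cat == "subPropertyEdge" ~ if (add) "addSupP" else "delSupP",
      cat == "label" ~ if (add) "addLabel" else "delLabel",
      cat == "comment" ~ if (add) "addComment" else "delComment",
      cat == "otherAttribute" ~ if (add) "addOtherA" else "delOtherA",
      cat == "individualTypeAssertion" ~ "TYPE",
      TRUE ~ if (add) "addOtherR" else "delOtherR")

    rows <- list()
    plain <- which(act != "TYPE")
    for (i in plain) {
      rows[[length(rows) + 1L]] <-
        basic_row(act[[i]], direction, tr$subject[[i]],
                  tr[i, , drop = FALSE], obs[[i]])
    }
    # individual type assertions: fold or degrade to OtherR
    typ <- which(act == "TYPE")
    if (length(typ) > 0) {
      for (s in unique(tr$subject[typ])) {
        idx <- typ[tr$subject[typ] == s]
        fresh <- !(s %in% other$individuals) &&
          !(s %in% other$concepts) && !(s %in% other$properties)
        if (fresh) {
          payload <- tr[idx, , drop = FALSE]
          payload <- payload[stable_order(render_ntriple(payload)), , drop = FALSE]
          rows[[length(rows) + 1L]] <-
            basic_row(if (add) "addI" else "delI", direction, s, payload,
                      any(obs[idx]))
        } else {
          for (i in idx) {
            rows[[length(rows) + 1L]] <-
              basic_row(if (add) "addOtherR" else "delOtherR", direction, s,
                        tr[i, , drop = FALSE], obs[[i]])
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(classify_side(delta$added, "add", new, old),
                          classify_side(delta$deleted, "del", old, new))
  if (nrow(out) == 0) return(empty_basics())
  out[stable_order(out$action, out$subject, basic_key(out)), , drop = FALSE]
}
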