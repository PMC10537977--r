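#' Heuristic change detection (matcher-gated)
#'
#' The three detectors below consume basic changes into the matcher-dependent
#' change actions: merges and splits, renames, and attribute-value changes.
#' They are pure functions of the unclaimed basics, the mapping and the two
#' versions; each returns `list(instances, claims)` where `claims` maps every
#' emitted instance to the basic-change ids it consumed. The engine enforces
#' that claims from distinct consumers never overlap (unambiguity).
#'
#' @name heuristic-changes
NULL

claims_of <- function(instances) {
  tibble::tibble(consumer = instances$instance_id, consumed = instances$consumed)
}

# basics available (not yet claimed) as a filtered view
unclaimed <- function(basics, claimed_ids) {
  basics[!(basics$id %in% claimed_ids), , drop = FALSE]
}

persists <- function(entity, old, new, slot) {
  entity %in% old[[slot]] & entity %in% new[[slot]]
}

#' Detect merges and splits
#'
#' For each new-version target `b` with at least two mapped deleted sources
#' `S`: `mergeC(S, b)` when `b` is itself newly added, `mergeCInto(S, b)` when
#' `b` persists. Symmetrically, one deleted/persisting source with at least
#' two mapped added targets yields `splitC`/`splitCInto` (the bundled
#' taxonomy documents that the split is one source to many targets). The same
#' logic applies to properties (`mergeP`, `splitPInto`, ...). Merge candidates
#' outrank split candidates; within a rank, larger groups win and ties break
#' on the lexicographic pivot IRI. Every entity participates in at most one
#' instance. Claims cover the member declaration basics present in the delta.
#'
#' @param basics Unclaimed basic changes.
#' @param mapping An `ontodiff_mapping`, already filtered to the score
#'   threshold.
#' @param old,new `ontodiff_version` objects.
#' @return `list(instances, claims)`.
#' @export
detect_merges_splits <- function(basics, mapping, old, new) {
  out <- list()
  used <- character(0)
  for (knd in c("concept", "property")) {
    slot <- if (knd == "concept") "concepts" else "properties"
    suffix <- if (knd == "concept") "C" else "P"
    del_act <- paste0("del", suffix)
    add_act <- paste0("add", suffix)
    del_by_subj <- basics[basics$action == del_act, , drop = FALSE]
    add_by_subj <- basics[basics$action == add_act, , drop = FALSE]
    mp <- as_plain(mapping)
    mp <- mp[mp$kind == knd, , drop = FALSE]
    if (nrow(mp) == 0) next

    # candidate merges: target <- mapped deleted sources (>= 2)
    cand <- list()
    for (b in stable_sort(unique(mp$target))) {
      S <- stable_sort(unique(mp$source[mp$target == b &
                                          mp$source %in% del_by_subj$subject]))
      if (length(S) < 2) next
      b_added <- b %in% add_by_subj$subject
      b_persists <- persists(b, old, new, slot)
      if (!b_added && !b_persists) next
      cand[[length(cand) + 1L]] <- list(
        shape = "merge", pivot = b, members = c(S, b), sources = S, target = b,
        added = b_added, size = length(S))
    }
    # candidate splits: source -> mapped added targets (>= 2)
    for (a in stable_sort(unique(mp$source))) {
      T_ <- stable_sort(unique(mp$target[mp$source == a &
                                           mp$target %in% add_by_subj$subject]))
      if (length(T_) < 2) next
      a_deleted <- a %in% del_by_subj$subject
      a_persists <- persists(a, old, new, slot)
      if (!a_deleted && !a_persists) next
      cand[[length(cand) + 1L]] <- list(
        shape = "split", pivot = a, members = c(a, T_), sources = a,
        target = T_, added = NA, deleted = a_deleted, size = length(T_))
    }
    if (length(cand) == 0) next
    ord <- order(vapply(cand, function(x) x$shape != "merge", logical(1)),
                 -vapply(cand, function(x) x$size, numeric(1)),
                 vapply(cand, function(x) x$pivot, character(1)),
                 method = "radix")
    for (cd in cand[ord]) {
      if (any(cd$members %in% used)) next
      used <- c(used, cd$members)
      if (cd$shape == "merge") {
        action <- paste0("merge", suffix, if (cd$added) "" else "Into")
        consumed <- c(del_by_subj$id[del_by_subj$subject %in% cd$sources],
                      if (cd$added) add_by_subj$id[add_by_subj$subject == cd$target])
        inst <- new_instance(action, "Heuristic",
                             list(sources = cd$sources, target = cd$target),
                             consumed)
      } else {
        action <- paste0("split", suffix, if (cd$deleted) "" else "Into")
        consumed <- c(if (cd$deleted) del_by_subj$id[del_by_subj$subject == cd$sources],
                      add_by_subj$id[add_by_subj$subject %in% cd$target])
        inst <- new_instance(action, "Heuristic",
                             list(source = cd$sources, targets = cd$target),
                             consumed)
      }
      out[[length(out) + 1L]] <- inst
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances), used = used)
}

#' Detect renames
#'
#' After merges and splits have claimed their entities, every remaining
#' strictly 1:1 correspondence between a deleted and an added entity of the
#' same kind is a rename: `renC`, `renP` or `renI`, recording `(id1, id2)` and
#' consuming the two declaration basics. `renC` is reported in the Complex
#' category, matching the bundled taxonomy's placement of class renames.
#'
#' @inheritParams detect_merges_splits
#' @param exclude Entities already claimed by merges/splits.
#' @return `list(instances, claims, pairs)`; `pairs` is a tibble of the
#'   accepted `(source, target, kind)` used downstream by value-change
#'   pairing across renamed subjects.
#' @export
detect_renames <- function(basics, mapping, old, new, exclude = character(0)) {
  out <- list()
  pairs <- list()
  mp <- as_plain(mapping)
  for (knd in c("concept", "property", "individual")) {
    suffix <- switch(knd, concept = "C", property = "P", individual = "I")
    del_act <- paste0("del", suffix)
    add_act <- paste0("add", suffix)
    action <- paste0("ren", suffix)
    category <- if (knd == "concept") "Complex" else "Heuristic"
    dels <- basics[basics$action == del_act, , drop = FALSE]
    adds <- basics[basics$action == add_act, , drop = FALSE]
    m <- mp[mp$kind == knd &
              !(mp$source %in% exclude) & !(mp$target %in% exclude) &
              mp$source %in% dels$subject & mp$target %in% adds$subject, ,
            drop = FALSE]
    if (nrow(m) == 0) next
    src_n <- table(m$source)
    tgt_n <- table(m$target)
    one2one <- m[src_n[m$source] == 1 & tgt_n[m$target] == 1, , drop = FALSE]
    one2one <- one2one[stable_order(one2one$source), , drop = FALSE]
    for (i in seq_len(nrow(one2one))) {
      a <- one2one$source[[i]]; b <- one2one$target[[i]]
      consumed <- c(dels$id[dels$subject == a], adds$id[adds$subject == b])
      out[[length(out) + 1L]] <-
        new_instance(action, category, list(old = a, new = b), consumed)
      pairs[[length(pairs) + 1L]] <-
        tibble::tibble(source = a, target = b, kind = knd)
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances),
       pairs = dplyr::bind_rows(pairs))
}

#' Detect attribute-value changes
#'
#' For each subject present in both versions (identically, or across an
#' accepted rename pair) and each predicate, deleted and added literals are
#' paired into `changeLabel` / `changeComment` / `changeOtherA`
#' `(entity, att_name, V_old, V_new)` greedily by descending lexical
#' similarity with deterministic tie-breaking. Pairs below similarity 0.1 are
#' not formed (a wholly different literal is an add plus a delete), and a
#' literal identical on both sides (possible only across a rename) is never a
#' "change". Obsolescence-flagged basics are invisible here so the
#' obsolescence rules can claim them. Unpaired basics stay in the residual.
#'
#' @inheritParams detect_merges_splits
#' @param rename_pairs Tibble `(source, target, kind)` from [detect_renames()].
#' @param floor Minimum similarity for pairing.
#' @return `list(instances, claims)`.
#' @export
detect_value_changes <- function(basics, old, new,
                                 rename_pairs = NULL, floor = 0.1) {
  vocab <- old$vocab
  att <- basics[!basics$obs_flag &
                  basics$action %in% c("addLabel", "delLabel", "addComment",
                                       "delComment", "addOtherA", "delOtherA"), ,
                drop = FALSE]
  if (nrow(att) == 0)
    return(list(instances = empty_instances(), claims = claims_of(empty_instances())))

  old_subjects <- unique(old$triples$subject)
  new_subjects <- unique(new$triples$subject)
  shared <- intersect(unique(att$subject), intersect(old_subjects, new_subjects))
  pair_tbl <- tibble::tibble(a = shared, b = shared)
  if (!is.null(rename_pairs) && nrow(rename_pairs) > 0) {
    pair_tbl <- dplyr::bind_rows(pair_tbl,
                                 tibble::tibble(a = rename_pairs$source,
                                                b = rename_pairs$target))
  }
  pair_tbl <- pair_tbl[stable_order(pair_tbl$b), , drop = FALSE]

  action_for <- function(pred) {
    if (pred %in% vocab$label_predicates) "changeLabel"
    else if (pred %in% vocab$comment_predicates) "changeComment"
    else "changeOtherA"
  }

  out <- list()
  for (i in seq_len(nrow(pair_tbl))) {
    a <- pair_tbl$a[[i]]; b <- pair_tbl$b[[i]]
    dels <- att[att$direction == "del" & att$subject == a, , drop = FALSE]
    adds <- att[att$direction == "add" & att$subject == b, , drop = FALSE]
    for (pred in stable_sort(intersect(unique(dels$predicate),
                                       unique(adds$predicate)))) {
      d <- dels[dels$predicate == pred, , drop = FALSE]
      g <- adds[adds$predicate == pred, , drop = FALSE]
      d <- d[stable_order(d$object, ifelse(is.na(d$lang), "", d$lang)), , drop = FALSE]
      g <- g[stable_order(g$object, ifelse(is.na(g$lang), "", g$lang)), , drop = FALSE]
      sim <- edit_similarity(d$object, g$object)
      # identical full literals are not value changes
      same <- outer(seq_len(nrow(d)), seq_len(nrow(g)), Vectorize(function(x, y) {
        d$object[[x]] == g$object[[y]] &&
          identical(d$lang[[x]], g$lang[[y]]) &&
          identical(d$datatype[[x]], g$datatype[[y]])
      }))
      sim[same] <- -Inf
      while (nrow(d) > 0 && nrow(g) > 0 && any(is.finite(sim) & sim >= floor)) {
        best <- which(sim == max(sim[is.finite(sim)]), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        di <- best[[1]]; gi <- best[[2]]
        out[[length(out) + 1L]] <- new_instance(
          action_for(pred), "Heuristic",
          list(entity = b, predicate = pred,
               old_value = d$object[[di]],
               old_lang = d$lang[[di]] %|NA|% "",
               new_value = g$object[[gi]],
               new_lang = g$lang[[gi]] %|NA|% ""),
          c(d$id[[di]], g$id[[gi]]))
        d <- d[-di, , drop = FALSE]
        g <- g[-gi, , drop = FALSE]
        sim <- sim[-di, -gi, drop = FALSE]
      }
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances))
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x
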