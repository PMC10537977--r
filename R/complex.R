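#' Complex change detection (matcher-independent)
#'
#' Deterministic rules that consume basic changes into the high-level actions
#' of the Complex branch of the taxonomy: obsolescence flips, whole added or
#' deleted subgraphs, leaf additions/deletions, hierarchy moves (including
#' pull-up and pull-down), and individual reclassification. All detectors are
#' functions of the two versions and the unclaimed basics only — never of the
#' mapping — and are run by the engine in the order obsolescence, subgraphs,
#' leaves, moves, reclassifications (larger or rarer aggregations first).
#'
#' @name complex-changes
NULL

# internal transitive closure that does not warn on undeclared entities
closure_of <- function(version, entities, edge_kind, direction = c("up", "down")) {
  direction <- match.arg(direction)
  edges <- version[[edge_kind]]
  from <- if (direction == "up") "child" else "parent"
  to <- if (direction == "up") "parent" else "child"
  seen <- character(0)
  frontier <- entities
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(edges[[to]][edges[[from]] %in% frontier]),
                   c(seen, entities))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Detect obsolescence flips
#'
#' For every entity declared (as the same kind) in both versions whose
#' obsolescence status flips, emits `toObsC`/`toObsP` (false to true) or
#' `revObsC`/`revObsP` (true to false), consuming the marker-triple basics —
#' and, when obsolescence is encoded by a label rewrite (`"X"` to
#' `"obsolete X"`), the paired label basic as well, so no `changeLabel` is
#' ever emitted for a deprecation.
#'
#' @param basics Unclaimed basic changes.
#' @param old,new `ontodiff_version` objects.
#' @param vocab Vocabulary configuration.
#' @return `list(instances, claims)`.
#' @export
detect_obsolescence <- function(basics, old, new, vocab = old$vocab) {
  out <- list()
  prefix_rules <- Filter(function(m) m$kind == "label_prefix",
                         vocab$obsolescence_markers)
  strip_prefix <- function(v) {
    for (m in prefix_rules) {
      re <- paste0("(?i)^", m$prefix, "[ :_-]*")
      v <- sub(re, "", v, perl = TRUE)
    }
    v
  }
  for (knd in c("concept", "property")) {
    slot <- if (knd == "concept") "concepts" else "properties"
    suffix <- if (knd == "concept") "C" else "P"
    both <- intersect(old[[slot]], new[[slot]])
    flagged <- basics[basics$obs_flag & basics$subject %in% both, , drop = FALSE]
    if (nrow(flagged) == 0) next
    for (e in stable_sort(unique(flagged$subject))) {
      was <- is_obsolete(old, e, vocab)
      is_ <- is_obsolete(new, e, vocab)
      if (was == is_) next
      to_obs <- !was && is_
      side <- if (to_obs) "add" else "del"
      mine <- flagged[flagged$subject == e & flagged$direction == side, , drop = FALSE]
      if (nrow(mine) == 0) next
      consumed <- mine$id
      # label-encoded obsolescence: claim the counterpart label basic too
      lab_rows <- mine[mine$action %in% c("addLabel", "delLabel"), , drop = FALSE]
      if (nrow(lab_rows) > 0) {
        other_side <- if (to_obs) "del" else "add"
        counter <- basics[basics$subject == e & basics$direction == other_side &
                            basics$action %in% c("addLabel", "delLabel") &
                            !basics$obs_flag, , drop = FALSE]
        stripped <- strip_prefix(lab_rows$object)
        hit <- counter$id[counter$object %in% stripped]
        consumed <- c(consumed, hit)
      }
      out[[length(out) + 1L]] <- new_instance(
        paste0(if (to_obs) "toObs" else "revObs", suffix),
        "Complex", list(entity = e), consumed)
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances))
}

#' Detect added and deleted subgraphs
#'
#' A subgraph root is an added (resp. deleted) entity whose direct parents in
#' the relevant version all persist (or are absent), with a non-empty set `B`
#' of added (deleted) descendants reachable through added-only (deleted-only)
#' subsumption chains. Emits `addSubGraphC(c, B)` / `delSubGraphC` /
#' `addSubGraphP` / `delSubGraphP`, consuming the member declarations, the
#' internal subsumption-edge basics, and the root's attachment edges to
#' persisting parents. A member's edge to a persisting parent outside the
#' subgraph is *not* consumed (it survives as a basic), which keeps claims
#' disjoint for partially added diamonds.
#'
#' @inheritParams detect_obsolescence
#' @return `list(instances, claims)`.
#' @export
detect_subgraphs <- function(basics, old, new) {
  out <- list()
  for (knd in c("concept", "property")) {
    slot <- if (knd == "concept") "concepts" else "properties"
    edge_kind <- if (knd == "concept") "class_edges" else "property_edges"
    csuffix <- if (knd == "concept") "C" else "P"
    for (dir in c("add", "del")) {
      ver <- if (dir == "add") new else old
      other <- if (dir == "add") old else new
      decl_act <- paste0(dir, csuffix)
      edge_act <- paste0(dir, "Sup", csuffix)
      decls <- basics[basics$action == decl_act, , drop = FALSE]
      edges_b <- basics[basics$action == edge_act, , drop = FALSE]
      changed <- unique(decls$subject)            # added/deleted entities
      persisting <- intersect(old[[slot]], new[[slot]])
      if (length(changed) == 0) next
      edges <- ver[[edge_kind]]
      # subsumption edges whose basic is present (they changed)
      ekey <- paste(edges$child, edges$parent)
      bkey <- paste(edges_b$subject, edges_b$object)
      chg_edges <- edges[ekey %in% bkey, , drop = FALSE]
      claimed_local <- character(0)
      roots <- stable_sort(changed)
      for (r in roots) {
        if (r %in% claimed_local) next
        par <- unique(edges$parent[edges$child == r])
        if (!all(par %in% persisting)) next   # root attaches only to persisting (or none)
        # members: changed entities reachable down through changed edges
        members <- character(0)
        frontier <- r
        repeat {
          nxt <- unique(chg_edges$child[chg_edges$parent %in% frontier])
          nxt <- setdiff(intersect(nxt, changed), c(members, r, claimed_local))
          if (length(nxt) == 0) break
          members <- c(members, nxt)
          frontier <- nxt
        }
        if (length(members) == 0) next
        grp <- c(r, members)
        internal <- edges_b$id[edges_b$subject %in% grp & edges_b$object %in% grp]
        attach <- edges_b$id[edges_b$subject == r & edges_b$object %in% persisting]
        consumed <- c(decls$id[decls$subject %in% grp], internal, attach)
        out[[length(out) + 1L]] <- new_instance(
          paste0(dir, "SubGraph", csuffix), "Complex",
          list(root = r, members = stable_sort(members)), consumed)
        claimed_local <- c(claimed_local, grp)
        decls <- decls[!(decls$subject %in% grp), , drop = FALSE]
        edges_b <- edges_b[!(edges_b$id %in% consumed), , drop = FALSE]
      }
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances))
}

#' Detect leaf additions and deletions
#'
#' After subgraph claims, every remaining added entity with a single
#' persisting parent and no children in the new version becomes
#' `addLeafC(c, p)` (resp. `addLeafP`), consuming its declaration and its one
#' attachment edge; `delLeafC`/`delLeafP` are symmetric on the old version.
#' Multi-parent candidates are excluded (the action's signature is
#' single-parent); their basics survive.
#'
#' @inheritParams detect_obsolescence
#' @return `list(instances, claims)`.
#' @export
detect_leaves <- function(basics, old, new) {
  out <- list()
  for (knd in c("concept", "property")) {
    slot <- if (knd == "concept") "concepts" else "properties"
    edge_kind <- if (knd == "concept") "class_edges" else "property_edges"
    csuffix <- if (knd == "concept") "C" else "P"
    persisting <- intersect(old[[slot]], new[[slot]])
    for (dir in c("add", "del")) {
      ver <- if (dir == "add") new else old
      decl_act <- paste0(dir, csuffix)
      edge_act <- paste0(dir, "Sup", csuffix)
      decls <- basics[basics$action == decl_act, , drop = FALSE]
      edges_b <- basics[basics$action == edge_act, , drop = FALSE]
      edges <- ver[[edge_kind]]
      for (c_ in stable_sort(unique(decls$subject))) {
        par <- unique(edges$parent[edges$child == c_])
        kids <- unique(edges$child[edges$parent == c_])
        if (length(par) != 1 || length(kids) > 0) next
        if (!(par %in% persisting)) next
        eb <- edges_b[edges_b$subject == c_ & edges_b$object == par, , drop = FALSE]
        if (nrow(eb) == 0) next
        consumed <- c(decls$id[decls$subject == c_], eb$id)
        out[[length(out) + 1L]] <- new_instance(
          paste0(dir, "Leaf", csuffix), "Complex",
          list(entity = c_, parent = par), consumed)
      }
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances))
}

#' Detect hierarchy moves
#'
#' For every persisting entity with at least one unclaimed deleted and one
#' unclaimed added subsumption edge, compares the direct parent sets `B1`
#' (old) and `B2` (new): `pullUpC(c, B1, B2)` when every new parent is a
#' strict ancestor of the old parents in the *old* hierarchy (the pre-change
#' frame of reference), `pullDownC` when every new parent is a strict
#' descendant, otherwise the lateral `moveC(c, B1, B2)`. All of the entity's
#' unclaimed subsumption-edge basics are consumed. `pullUpP`/`pullDownP`/
#' `moveP` are the property analogues.
#'
#' @inheritParams detect_obsolescence
#' @return `list(instances, claims)`.
#' @export
detect_moves <- function(basics, old, new) {
  out <- list()
  for (knd in c("concept", "property")) {
    slot <- if (knd == "concept") "concepts" else "properties"
    edge_kind <- if (knd == "concept") "class_edges" else "property_edges"
    csuffix <- if (knd == "concept") "C" else "P"
    add_e <- basics[basics$action == paste0("addSup", csuffix), , drop = FALSE]
    del_e <- basics[basics$action == paste0("delSup", csuffix), , drop = FALSE]
    cands <- intersect(unique(add_e$subject), unique(del_e$subject))
    cands <- cands[persists(cands, old, new, slot)]
    for (c_ in stable_sort(cands)) {
      b1 <- direct_parents(old, c_, edge_kind)
      b2 <- direct_parents(new, c_, edge_kind)
      up <- closure_of(old, b1, edge_kind, "up")
      down <- closure_of(old, b1, edge_kind, "down")
      action <- if (length(b2) > 0 && all(b2 %in% setdiff(up, b1))) {
        paste0("pullUp", csuffix)
      } else if (length(b2) > 0 && all(b2 %in% setdiff(down, b1))) {
        paste0("pullDown", csuffix)
      } else paste0("move", csuffix)
      consumed <- c(add_e$id[add_e$subject == c_], del_e$id[del_e$subject == c_])
      out[[length(out) + 1L]] <- new_instance(
        action, "Complex",
        list(entity = c_, old_parents = b1, new_parents = b2), consumed)
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances))
}

#' Detect individual reclassifications
#'
#' For every individual present in both versions with a deleted type
#' assertion to `B1` and an added one to `B2` (surfaced by the delta
#' classifier as `delOtherR`/`addOtherR` on the type predicate):
#' `reclassIHigher(i, B1, B2)` when `B2` is a strict ancestor of `B1` in the
#' new hierarchy, `reclassILower` when a strict descendant, and the generic
#' sibling retype `recastI(i, B1, B2)` otherwise. Hierarchy-related pairs are
#' formed first; both type-assertion basics are consumed per instance.
#'
#' @inheritParams detect_obsolescence
#' @return `list(instances, claims)`.
#' @export
detect_reclassifications <- function(basics, old, new, vocab = old$vocab) {
  out <- list()
  both <- intersect(old$individuals, new$individuals)
  typ <- basics[basics$predicate %in% vocab$type_predicate &
                  basics$action %in% c("addOtherR", "delOtherR") &
                  basics$subject %in% both, , drop = FALSE]
  for (i_ in stable_sort(unique(typ$subject))) {
    dels <- typ[typ$subject == i_ & typ$action == "delOtherR", , drop = FALSE]
    adds <- typ[typ$subject == i_ & typ$action == "addOtherR", , drop = FALSE]
    if (nrow(dels) == 0 || nrow(adds) == 0) next
    dels <- dels[stable_order(dels$object), , drop = FALSE]
    adds <- adds[stable_order(adds$object), , drop = FALSE]
    related <- function(b1, b2) {
      anc <- closure_of(new, b1, "class_edges", "up")
      if (b2 %in% anc) return("reclassIHigher")
      dsc <- closure_of(new, b1, "class_edges", "down")
      if (b2 %in% dsc) return("reclassILower")
      "recastI"
    }
    while (nrow(dels) > 0 && nrow(adds) > 0) {
      # prefer a hierarchy-related pair; fall back to the first remaining
      pick <- NULL
      for (di in seq_len(nrow(dels))) {
        for (gi in seq_len(nrow(adds))) {
          act <- related(dels$object[[di]], adds$object[[gi]])
          if (act != "recastI") { pick <- c(di, gi, act); break }
        }
        if (!is.null(pick)) break
      }
      if (is.null(pick)) pick <- c(1L, 1L, "recastI")
      di <- as.integer(pick[[1]]); gi <- as.integer(pick[[2]])
      out[[length(out) + 1L]] <- new_instance(
        pick[[3]], "Complex",
        list(individual = i_, old_type = dels$object[[di]],
             new_type = adds$object[[gi]]),
        c(dels$id[[di]], adds$id[[gi]]))
      dels <- dels[-di, , drop = FALSE]
      adds <- adds[-gi, , drop = FALSE]
    }
  }
  instances <- bind_instances(!!!out)
  list(instances = instances, claims = claims_of(instances))
}
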