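# Planting functions: each applies one scripted change to the working copy of
# the new version and records the expected outcome (instance, residual basics,
# perfect-mapping rows) in the state. Every function marks the entities it
# relies on as touched so scripted actions never overlap.

plant_fns <- function() list(

  ## -- basic residual changes -------------------------------------------------
  addC = function(st) {
    c_ <- fresh_iri(st)
    r <- row1(c_, RDF_TYPE, paste0(NS$owl, "Class"))
    add_rows(st, r)
    expect_basic(st, "addC", c_, r)
    touch(st, "addC", c_)
  },
  delC = function(st) {
    a <- fx_clean_leaf(st, "concept", action = "delC")
    r <- row1(a, RDF_TYPE, paste0(NS$owl, "Class"))
    del_rows(st, r)
    expect_basic(st, "delC", a, r)
    touch(st, "delC", a)
  },
  addP = function(st) {
    p_ <- fresh_iri(st, "NP")
    r <- row1(p_, RDF_TYPE, paste0(NS$owl, "ObjectProperty"))
    add_rows(st, r)
    expect_basic(st, "addP", p_, r)
    touch(st, "addP", p_)
  },
  delP = function(st) {
    p <- fx_untouched(st, "property", action = "delP")
    r <- row1(p, RDF_TYPE, paste0(NS$owl, "ObjectProperty"))
    del_rows(st, r)
    expect_basic(st, "delP", p, r)
    touch(st, "delP", p)
  },
  addI = function(st) {
    i_ <- fresh_iri(st, "NI")
    t_ <- fx_untouched(st, "concept", action = "addI")
    r <- row1(i_, RDF_TYPE, t_)
    add_rows(st, r)
    expect_basic(st, "addI", i_, r)
    touch(st, "addI", i_, reserve = t_)
  },
  delI = function(st) {
    i <- fx_untouched(st, "individual", action = "delI")
    r <- subject_rows(st, i)
    r <- r[r$predicate == RDF_TYPE, , drop = FALSE]
    del_rows(st, r)
    r <- r[stable_order(render_ntriple(r)), , drop = FALSE]
    expect_basic(st, "delI", i, r)
    touch(st, "delI", i)
  },
  addSupC = function(st) plant_add_edge(st, "concept"),
  delSupC = function(st) {
    pool <- fx_pool(st, "concept")
    hit <- NULL
    for (e in pool) {
      pa <- fx_parents(st, e)
      if (length(pa) >= 2 && !any(pa %in% st$touched)) { hit <- e; break }
    }
    if (is.null(hit)) pick_fail("delSupC", "no untouched multi-parent concept")
    pa <- fx_parents(st, hit)
    r <- row1(hit, RDFS_SUBCLASS, pa[[1]])
    del_rows(st, r)
    expect_basic(st, "delSupC", hit, r)
    touch(st, "delSupC", hit, reserve = pa)
  },
  addSupP = function(st) plant_add_edge(st, "property"),
  delSupP = function(st) {
    pool <- fx_pool(st, "property")
    hit <- NULL
    for (e in pool) {
      pa <- fx_parents(st, e, "property_edges")
      if (length(pa) >= 1 && !any(pa %in% st$touched)) { hit <- e; break }
    }
    if (is.null(hit)) pick_fail("delSupP", "no untouched child property")
    pa <- fx_parents(st, hit, "property_edges")
    r <- row1(hit, RDFS_SUBPROP, pa[[1]])
    del_rows(st, r)
    expect_basic(st, "delSupP", hit, r)
    touch(st, "delSupP", hit, reserve = pa)
  },
  addComment = function(st) {
    e <- fx_untouched(st, "concept", action = "addComment")
    r <- lit_row(e, RDFS_COMMENT, paste("added note", mk_word(3)))
    add_rows(st, r)
    expect_basic(st, "addComment", e, r)
    touch(st, "addComment", e)
  },
  delComment = function(st) {
    e <- fx_untouched(st, "concept", action = "delComment")
    r <- subject_rows(st, e)
    r <- r[r$predicate == RDFS_COMMENT, , drop = FALSE][1, , drop = FALSE]
    del_rows(st, r)
    expect_basic(st, "delComment", e, r)
    touch(st, "delComment", e)
  },
  addLabel = function(st) {
    e <- fx_untouched(st, "concept", action = "addLabel")
    r <- lit_row(e, paste0(NS$skos, "prefLabel"), mk_label())
    add_rows(st, r)
    expect_basic(st, "addLabel", e, r)
    touch(st, "addLabel", e)
  },
  delLabel = function(st) {
    e <- fx_untouched(st, "concept", action = "delLabel")
    r <- subject_rows(st, e)
    r <- r[r$predicate == RDFS_LABEL, , drop = FALSE][1, , drop = FALSE]
    del_rows(st, r)
    expect_basic(st, "delLabel", e, r)
    touch(st, "delLabel", e)
  },
  addOtherA = function(st) {
    e <- fx_untouched(st, "concept", action = "addOtherA")
    r <- lit_row(e, paste0(NS$skos, "altLabel"), mk_label())
    add_rows(st, r)
    expect_basic(st, "addOtherA", e, r)
    touch(st, "addOtherA", e)
  },
  delOtherA = function(st) {
    pool <- fx_pool(st, "concept")
    syn <- paste0(NS$skos, "altLabel")
    hit <- NULL
    for (e in pool) {
      r <- subject_rows(st, e)
      r <- r[r$predicate == syn, , drop = FALSE]
      if (nrow(r) > 0) { hit <- e; break }
    }
    if (is.null(hit)) pick_fail("delOtherA", "no untouched concept with a synonym")
    r <- subject_rows(st, hit)
    r <- r[r$predicate == syn, , drop = FALSE][1, , drop = FALSE]
    del_rows(st, r)
    expect_basic(st, "delOtherA", hit, r)
    touch(st, "delOtherA", hit)
  },
  addOtherR = function(st) {
    picks <- fx_untouched(st, "concept", 2, action = "addOtherR")
    pr <- fx_untouched(st, "property", action = "addOtherR")
    r <- row1(picks[[1]], pr, picks[[2]])
    add_rows(st, r)
    expect_basic(st, "addOtherR", picks[[1]], r)
    touch(st, "addOtherR", picks[[1]], reserve = c(picks[[2]], pr))
  },
  delOtherR = function(st) {
    rel <- st$base$relationships
    ok <- !(rel$subject %in% st$touched) & !(rel$object %in% st$touched)
    if (!any(ok)) pick_fail("delOtherR", "no untouched cross-relationship")
    i <- which(ok)[[1]]
    r <- row1(rel$subject[[i]], rel$predicate[[i]], rel$object[[i]])
    del_rows(st, r)
    expect_basic(st, "delOtherR", rel$subject[[i]], r)
    touch(st, "delOtherR", rel$subject[[i]], reserve = rel$object[[i]])
  },

  ## -- heuristic: merges and splits ------------------------------------------
  mergeC = function(st) plant_merge(st, "concept", into = FALSE),
  mergeCInto = function(st) plant_merge(st, "concept", into = TRUE),
  mergeP = function(st) plant_merge(st, "property", into = FALSE),
  mergePInto = function(st) plant_merge(st, "property", into = TRUE),
  splitC = function(st) plant_split(st, "concept", into = FALSE),
  splitCInto = function(st) plant_split(st, "concept", into = TRUE),
  splitP = function(st) plant_split(st, "property", into = FALSE),
  splitPInto = function(st) plant_split(st, "property", into = TRUE),

  ## -- renames ---------------------------------------------------------------
  renC = function(st) plant_rename(st, "concept"),
  renP = function(st) plant_rename(st, "property"),
  renI = function(st) plant_rename(st, "individual"),

  ## -- attribute value changes -------------------------------------------------
  changeLabel = function(st) plant_value_change(st, RDFS_LABEL, "changeLabel"),
  changeComment = function(st) plant_value_change(st, RDFS_COMMENT, "changeComment"),
  changeOtherA = function(st) plant_value_change(st, paste0(NS$skos, "altLabel"),
                                                 "changeOtherA"),

  ## -- moves -------------------------------------------------------------------
  pullUpC = function(st) plant_pull_up(st, "concept"),
  pullUpP = function(st) plant_pull_up(st, "property"),
  pullDownC = function(st) plant_pull_down(st, "concept"),
  pullDownP = function(st) plant_pull_down(st, "property"),
  moveC = function(st) plant_lateral_move(st, "concept"),
  moveP = function(st) plant_lateral_move(st, "property"),

  ## -- obsolescence ------------------------------------------------------------
  toObsC = function(st) plant_to_obs(st, "concept"),
  toObsP = function(st) plant_to_obs(st, "property"),
  revObsC = function(st) plant_rev_obs(st, "concept"),
  revObsP = function(st) plant_rev_obs(st, "property"),
  toObsC_label = function(st) {
    e <- fx_untouched(st, "concept", action = "toObsC_label")
    old_lab <- subject_rows(st, e)
    old_lab <- old_lab[old_lab$predicate == RDFS_LABEL, , drop = FALSE][1, , drop = FALSE]
    new_lab <- lit_row(e, RDFS_LABEL, paste("obsolete", old_lab$object))
    del_rows(st, old_lab)
    add_rows(st, new_lab)
    expect_instance(st, "toObsC", "Complex", list(entity = e))
    touch(st, "toObsC_label", e)
  },

  ## -- leaves and subgraphs ------------------------------------------------------
  addLeafC = function(st) plant_add_leaf(st, "concept"),
  addLeafP = function(st) plant_add_leaf(st, "property"),
  delLeafC = function(st) plant_del_leaf(st, "concept"),
  delLeafP = function(st) plant_del_leaf(st, "property"),
  addSubGraphC = function(st) plant_add_subgraph(st, "concept"),
  addSubGraphP = function(st) plant_add_subgraph(st, "property"),
  delSubGraphC = function(st) plant_del_subgraph(st, "concept"),
  delSubGraphP = function(st) plant_del_subgraph(st, "property"),

  ## -- individual reclassification ---------------------------------------------
  recastI = function(st) plant_retype(st, "sibling"),
  reclassIHigher = function(st) plant_retype(st, "up"),
  reclassILower = function(st) plant_retype(st, "down"),

  ## -- adversarial ---------------------------------------------------------------
  multiParentLeaf = function(st) {
    c_ <- fresh_iri(st)
    ps <- fx_untouched(st, "concept", 2, action = "multiParentLeaf")
    rows <- dplyr::bind_rows(row1(c_, RDF_TYPE, paste0(NS$owl, "Class")),
                             row1(c_, RDFS_SUBCLASS, ps[[1]]),
                             row1(c_, RDFS_SUBCLASS, ps[[2]]))
    add_rows(st, rows)
    expect_basic(st, "addC", c_, rows[1, ])
    expect_basic(st, "addSupC", c_, rows[2, ])
    expect_basic(st, "addSupC", c_, rows[3, ])
    touch(st, "multiParentLeaf", c_, reserve = ps)
  },
  manyToMany = function(st) {
    srcs <- fx_clean_leaf(st, "concept", 2, action = "manyToMany")
    b1 <- fresh_iri(st); b2 <- fresh_iri(st)
    stopifnot(b1 < b2)  # fresh IRIs are sequential; b1 is the merge pivot
    dels <- dplyr::bind_rows(lapply(srcs, function(a) subject_rows(st, a)))
    del_rows(st, dels)
    adds <- dplyr::bind_rows(row1(b1, RDF_TYPE, paste0(NS$owl, "Class")),
                             row1(b2, RDF_TYPE, paste0(NS$owl, "Class")))
    add_rows(st, adds)
    for (a in srcs) for (b in c(b1, b2)) expect_map(st, a, b, "concept")
    # merge beats split; among equal-size merge groups the lexicographically
    # first pivot wins, so b1 absorbs both sources and addC(b2) survives
    expect_instance(st, "mergeC", "Heuristic", list(sources = srcs, target = b1))
    expect_basic(st, "addC", b2, adds[2, ])
    decls <- dels[dels$predicate == RDF_TYPE, , drop = FALSE]
    expect_residuals(st, dels, "del", skip = decls)
    touch(st, "manyToMany", c(srcs, b1, b2))
  },
  partialSubGraph = function(st) {
    ps <- fx_untouched(st, "concept", 2, action = "partialSubGraph")
    r_ <- fresh_iri(st); x_ <- fresh_iri(st)
    rows <- dplyr::bind_rows(
      row1(r_, RDF_TYPE, paste0(NS$owl, "Class")),
      row1(x_, RDF_TYPE, paste0(NS$owl, "Class")),
      row1(r_, RDFS_SUBCLASS, ps[[1]]),
      row1(x_, RDFS_SUBCLASS, r_),
      row1(x_, RDFS_SUBCLASS, ps[[2]]))   # diamond edge out of the subgraph
    add_rows(st, rows)
    expect_instance(st, "addSubGraphC", "Complex",
                    list(root = r_, members = x_))
    expect_basic(st, "addSupC", x_, rows[5, ])
    touch(st, "partialSubGraph", c(r_, x_), reserve = ps)
  }
)

# --- shared planting implementations ----------------------------------------

# add an extra subsumption edge (no deletion -> stays a residual basic);
# the new parent must not be a descendant of the child (no cycles)
plant_add_edge <- function(st, kind) {
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
  action <- if (kind == "concept") "addSupC" else "addSupP"
  pool <- fx_pool(st, kind)
  for (c_ in pool) {
    bad <- c(descendants(st$base, c_, edge_kind), c_,
             fx_parents(st, c_, edge_kind), st$touched)
    g <- setdiff(pool, bad)
    if (length(g) >= 1) {
      g <- g[[1]]
      r <- row1(c_, pred, g)
      add_rows(st, r)
      expect_basic(st, action, c_, r)
      touch(st, action, c_, reserve = g)
      return(invisible())
    }
  }
  pick_fail(action, "no acyclic attachment pair available")
}

decl_row_of <- function(st, e, kind) {
  obj <- if (kind == "concept") paste0(NS$owl, "Class") else paste0(NS$owl, "ObjectProperty")
  row1(e, RDF_TYPE, obj)
}

full_delete <- function(st, e) {
  rows <- subject_rows(st, e)
  del_rows(st, rows)
  rows
}

new_entity_rows <- function(st, kind, label, parent = NULL) {
  e <- fresh_iri(st, if (kind == "concept") "N" else "NP")
  rows <- decl_row_of(st, e, kind)
  if (!is.null(label)) rows <- dplyr::bind_rows(rows, lit_row(e, RDFS_LABEL, label))
  if (!is.null(parent)) {
    pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
    rows <- dplyr::bind_rows(rows, row1(e, pred, parent))
  }
  add_rows(st, rows)
  list(iri = e, rows = rows)
}

label_of <- function(st, e) {
  r <- st$base$attributes
  v <- r$value[r$entity == e & r$predicate == RDFS_LABEL]
  if (length(v) == 0) iri_local_name(e) else v[[1]]
}

plant_merge <- function(st, kind, into) {
  suffix <- if (kind == "concept") "C" else "P"
  token <- paste0("merge", suffix, if (into) "Into" else "")
  srcs <- fx_clean_leaf(st, kind, 2, action = token)
  if (into) {
    tgt <- fx_untouched(st, kind, 1, exclude = srcs, action = token)
    tgt_rows <- NULL
  } else {
    made <- new_entity_rows(st, kind, paste(label_of(st, srcs[[1]]), "combined"),
                            parent = fx_parents(st, srcs[[1]],
                                                if (kind == "concept") "class_edges"
                                                else "property_edges")[1])
    tgt <- made$iri
    tgt_rows <- made$rows
  }
  dels <- dplyr::bind_rows(lapply(srcs, function(a) full_delete(st, a)))
  for (a in srcs) expect_map(st, a, tgt, kind)
  expect_instance(st, paste0("merge", suffix, if (into) "Into" else ""),
                  "Heuristic", list(sources = srcs, target = tgt))
  decls <- dels[dels$predicate == RDF_TYPE & dels$object_kind != "literal", , drop = FALSE]
  expect_residuals(st, dels, "del", skip = decls)
  if (!into) {
    expect_residuals(st, tgt_rows, "add",
                     skip = tgt_rows[tgt_rows$predicate == RDF_TYPE, , drop = FALSE])
  }
  touch(st, paste0("merge", suffix, if (into) "Into" else ""), c(srcs, tgt),
        reserve = fx_parents(st, srcs[[1]],
                             if (kind == "concept") "class_edges" else "property_edges"))
}

plant_split <- function(st, kind, into) {
  suffix <- if (kind == "concept") "C" else "P"
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  token <- paste0("split", suffix, if (into) "Into" else "")
  if (into) {
    pool <- fx_pool(st, kind)
    pool <- pool[vapply(pool, function(e)
      length(fx_parents(st, e, edge_kind)) >= 1, logical(1))]
    if (length(pool) == 0) pick_fail(token, "no untouched non-root entity")
    src <- pool[[1]]
  } else {
    src <- fx_clean_leaf(st, kind, 1, action = token)
  }
  par <- fx_parents(st, src, if (kind == "concept") "class_edges" else "property_edges")[1]
  lab <- label_of(st, src)
  t1 <- new_entity_rows(st, kind, paste(lab, "part one"), parent = par)
  t2 <- new_entity_rows(st, kind, paste(lab, "part two"), parent = par)
  tgts <- c(t1$iri, t2$iri)
  for (b in tgts) expect_map(st, src, b, kind)
  expect_instance(st, paste0("split", suffix, if (into) "Into" else ""),
                  "Heuristic", list(source = src, targets = tgts))
  if (!into) {
    dels <- full_delete(st, src)
    decls <- dels[dels$predicate == RDF_TYPE & dels$object_kind != "literal", , drop = FALSE]
    expect_residuals(st, dels, "del", skip = decls)
  }
  for (t_ in list(t1, t2)) {
    expect_residuals(st, t_$rows, "add",
                     skip = t_$rows[t_$rows$predicate == RDF_TYPE, , drop = FALSE])
  }
  touch(st, paste0("split", suffix, if (into) "Into" else ""), c(src, tgts),
        reserve = par)
}

plant_rename <- function(st, kind) {
  suffix <- switch(kind, concept = "C", property = "P", individual = "I")
  category <- if (kind == "concept") "Complex" else "Heuristic"
  token <- paste0("ren", suffix)
  if (kind == "individual") {
    src <- fx_untouched(st, "individual", action = token)
    src_rows <- subject_rows(st, src)
    type_tgt <- src_rows$object[src_rows$predicate == RDF_TYPE][1]
    dels <- full_delete(st, src)
    i_ <- fresh_iri(st, "NI")
    adds <- dplyr::bind_rows(row1(i_, RDF_TYPE, type_tgt),
                             lit_row(i_, RDFS_LABEL, label_of(st, src)))
    add_rows(st, adds)
    tgt <- i_
    expect_residuals(st, dels, "del",
                     skip = dels[dels$predicate == RDF_TYPE, , drop = FALSE],
                     individual_subjects = src)
    expect_residuals(st, adds, "add",
                     skip = adds[adds$predicate == RDF_TYPE, , drop = FALSE],
                     individual_subjects = tgt)
  } else {
    src <- fx_clean_leaf(st, kind, 1, action = token)
    par <- fx_parents(st, src, if (kind == "concept") "class_edges" else "property_edges")[1]
    made <- new_entity_rows(st, kind, label_of(st, src), parent = par)
    tgt <- made$iri
    dels <- full_delete(st, src)
    decls <- dels[dels$predicate == RDF_TYPE & dels$object_kind != "literal", , drop = FALSE]
    expect_residuals(st, dels, "del", skip = decls)
    expect_residuals(st, made$rows, "add",
                     skip = made$rows[made$rows$predicate == RDF_TYPE, , drop = FALSE])
  }
  expect_map(st, src, tgt, kind)
  expect_instance(st, paste0("ren", suffix), category, list(old = src, new = tgt))
  touch(st, paste0("ren", suffix), c(src, tgt))
}

plant_value_change <- function(st, pred, action) {
  pool <- fx_pool(st, "concept")
  hit <- NULL
  for (e in pool) {
    r <- subject_rows(st, e)
    if (any(r$predicate == pred)) { hit <- e; break }
  }
  if (is.null(hit)) pick_fail(action, "no untouched concept carries the attribute")
  old <- subject_rows(st, hit)
  old <- old[old$predicate == pred, , drop = FALSE][1, , drop = FALSE]
  new_val <- paste(old$object, "revised")
  new <- lit_row(hit, pred, new_val, old$lang)
  del_rows(st, old)
  add_rows(st, new)
  expect_instance(st, action, "Heuristic",
                  list(entity = hit, predicate = pred,
                       old_value = old$object, old_lang = old$lang %|NA|% "",
                       new_value = new_val, new_lang = new$lang %|NA|% ""))
  touch(st, action, hit)
}

plant_pull_up <- function(st, kind) {
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
  pool <- fx_pool(st, kind)
  hit <- NULL
  for (e in pool) {
    pa <- fx_parents(st, e, edge_kind)
    if (length(pa) != 1 || pa %in% st$touched) next
    gp <- fx_parents(st, pa, edge_kind)
    gp <- setdiff(gp, st$touched)
    if (length(gp) >= 1) { hit <- e; p <- pa; g <- gp[[1]]; break }
  }
  if (is.null(hit)) pick_fail(paste0("pullUp", if (kind == "concept") "C" else "P"),
                              "no untouched child-parent-grandparent chain")
  del_rows(st, row1(hit, pred, p))
  add_rows(st, row1(hit, pred, g))
  expect_instance(st, paste0("pullUp", if (kind == "concept") "C" else "P"),
                  "Complex",
                  list(entity = hit, old_parents = p, new_parents = g))
  touch(st, "pullUp", hit, reserve = c(p, g))
}

plant_pull_down <- function(st, kind) {
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
  pool <- fx_pool(st, kind)
  hit <- NULL
  for (e in pool) {
    pa <- fx_parents(st, e, edge_kind)
    if (length(pa) != 1 || pa %in% st$touched) next
    sibs <- setdiff(fx_children(st, pa, edge_kind), e)
    sibs <- setdiff(sibs, c(st$touched, descendants(st$base, e, edge_kind)))
    if (length(sibs) >= 1) { hit <- e; g <- pa; p <- stable_sort(sibs)[[1]]; break }
  }
  if (is.null(hit)) pick_fail(paste0("pullDown", if (kind == "concept") "C" else "P"),
                              "no untouched parent with two children")
  del_rows(st, row1(hit, pred, g))
  add_rows(st, row1(hit, pred, p))
  expect_instance(st, paste0("pullDown", if (kind == "concept") "C" else "P"),
                  "Complex",
                  list(entity = hit, old_parents = g, new_parents = p))
  touch(st, "pullDown", hit, reserve = c(g, p))
}

plant_lateral_move <- function(st, kind) {
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
  pool <- fx_pool(st, kind)
  hit <- NULL
  for (e in pool) {
    pa <- fx_parents(st, e, edge_kind)
    if (length(pa) != 1 || pa %in% st$touched) next
    related <- c(ancestors_nowarn(st$base, pa, edge_kind),
                 descendants(st$base, pa, edge_kind), pa, e,
                 descendants(st$base, e, edge_kind))
    q <- setdiff(pool, c(related, st$touched))
    if (length(q) >= 1) { hit <- e; p1 <- pa; q_ <- q[[1]]; break }
  }
  if (is.null(hit)) pick_fail(paste0("move", if (kind == "concept") "C" else "P"),
                              "no unrelated reattachment point")
  del_rows(st, row1(hit, pred, p1))
  add_rows(st, row1(hit, pred, q_))
  expect_instance(st, paste0("move", if (kind == "concept") "C" else "P"),
                  "Complex",
                  list(entity = hit, old_parents = p1, new_parents = q_))
  touch(st, "move", hit, reserve = c(p1, q_))
}

ancestors_nowarn <- function(version, entity, edge_kind) {
  closure_of(version, entity, edge_kind, "up")
}

plant_to_obs <- function(st, kind) {
  e <- fx_untouched(st, kind,
                    action = paste0("toObs", if (kind == "concept") "C" else "P"))
  r <- row1(e, OWL_DEPRECATED, "true", "literal", NA_character_, XSD_BOOLEAN)
  add_rows(st, r)
  expect_instance(st, paste0("toObs", if (kind == "concept") "C" else "P"),
                  "Complex", list(entity = e))
  touch(st, "toObs", e)
}

plant_rev_obs <- function(st, kind) {
  slot <- if (kind == "concept") "concepts" else "properties"
  pool <- setdiff(intersect(st$base[[slot]], st$obsolete), st$touched)
  if (length(pool) == 0) pick_fail(paste0("revObs", if (kind == "concept") "C" else "P"),
                                  "no deprecated entity in the base")
  e <- stable_sort(pool)[[1]]
  r <- row1(e, OWL_DEPRECATED, "true", "literal", NA_character_, XSD_BOOLEAN)
  del_rows(st, r)
  expect_instance(st, paste0("revObs", if (kind == "concept") "C" else "P"),
                  "Complex", list(entity = e))
  touch(st, "revObs", e)
}

plant_add_leaf <- function(st, kind) {
  p <- fx_untouched(st, kind,
                    action = paste0("addLeaf", if (kind == "concept") "C" else "P"))
  made <- new_entity_rows(st, kind, mk_label(), parent = p)
  expect_instance(st, paste0("addLeaf", if (kind == "concept") "C" else "P"),
                  "Complex", list(entity = made$iri, parent = p))
  lab <- made$rows[made$rows$object_kind == "literal", , drop = FALSE]
  expect_residuals(st, lab, "add")
  touch(st, "addLeaf", made$iri, reserve = p)
}

plant_del_leaf <- function(st, kind) {
  e <- fx_clean_leaf(st, kind, 1, need_single_parent = TRUE,
                     action = paste0("delLeaf", if (kind == "concept") "C" else "P"))
  p <- fx_parents(st, e, if (kind == "concept") "class_edges" else "property_edges")
  dels <- full_delete(st, e)
  pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
  consumed <- dels[(dels$predicate == RDF_TYPE & dels$object_kind != "literal") |
                     dels$predicate == pred, , drop = FALSE]
  expect_instance(st, paste0("delLeaf", if (kind == "concept") "C" else "P"),
                  "Complex", list(entity = e, parent = p))
  expect_residuals(st, dels, "del", skip = consumed)
  touch(st, "delLeaf", e, reserve = p)
}

plant_add_subgraph <- function(st, kind) {
  p <- fx_untouched(st, kind,
                    action = paste0("addSubGraph", if (kind == "concept") "C" else "P"))
  r_ <- new_entity_rows(st, kind, mk_label(), parent = p)
  x_ <- new_entity_rows(st, kind, mk_label(), parent = r_$iri)
  y_ <- new_entity_rows(st, kind, mk_label(), parent = r_$iri)
  expect_instance(st, paste0("addSubGraph", if (kind == "concept") "C" else "P"),
                  "Complex", list(root = r_$iri, members = c(x_$iri, y_$iri)))
  labs <- dplyr::bind_rows(r_$rows, x_$rows, y_$rows)
  expect_residuals(st, labs[labs$object_kind == "literal", , drop = FALSE], "add")
  touch(st, "addSubGraph", c(r_$iri, x_$iri, y_$iri), reserve = p)
}

plant_del_subgraph <- function(st, kind) {
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  pred <- if (kind == "concept") RDFS_SUBCLASS else RDFS_SUBPROP
  pool <- fx_pool(st, kind)
  typed <- unique(st$base$type_assertions$class)
  hit <- NULL
  for (e in pool) {
    ds <- descendants(st$base, e, edge_kind)
    # keep deleted subtrees small so one action does not eat the hierarchy
    if (length(ds) == 0 || length(ds) > 5) next
    grp <- c(e, ds)
    clean <- !any(grp %in% st$touched) && !any(grp %in% typed) &&
      !any(grp %in% st$rel_subjects) &&
      all(vapply(ds, function(d) all(fx_parents(st, d, edge_kind) %in% grp),
                 logical(1))) &&
      length(fx_parents(st, e, edge_kind)) >= 1 &&
      !any(fx_parents(st, e, edge_kind) %in% st$touched)
    if (clean) { hit <- e; members <- ds; break }
  }
  if (is.null(hit)) pick_fail(paste0("delSubGraph", if (kind == "concept") "C" else "P"),
                              "no clean deletable subtree")
  grp <- c(hit, members)
  dels <- dplyr::bind_rows(lapply(grp, function(g) full_delete(st, g)))
  consumed <- dels[(dels$predicate == RDF_TYPE & dels$object_kind != "literal") |
                     dels$predicate == pred, , drop = FALSE]
  expect_instance(st, paste0("delSubGraph", if (kind == "concept") "C" else "P"),
                  "Complex", list(root = hit, members = members))
  expect_residuals(st, dels, "del", skip = consumed)
  touch(st, "delSubGraph", grp, reserve = fx_parents(st, hit, edge_kind))
}

plant_retype <- function(st, mode) {
  pool <- fx_pool(st, "individual")
  hit <- NULL
  for (i_ in pool) {
    rows <- subject_rows(st, i_)
    b1 <- rows$object[rows$predicate == RDF_TYPE]
    if (length(b1) != 1 || b1 %in% st$touched) next
    b2 <- switch(mode,
      up = {
        anc <- setdiff(ancestors_nowarn(st$base, b1, "class_edges"), st$touched)
        if (length(anc) > 0) stable_sort(anc)[[1]] else NULL
      },
      down = {
        ds <- setdiff(descendants(st$base, b1, "class_edges"), st$touched)
        if (length(ds) > 0) stable_sort(ds)[[1]] else NULL
      },
      sibling = {
        rel <- c(ancestors_nowarn(st$base, b1, "class_edges"),
                 descendants(st$base, b1, "class_edges"), b1)
        q <- setdiff(fx_pool(st, "concept"), rel)
        if (length(q) > 0) q[[1]] else NULL
      })
    if (!is.null(b2)) { hit <- i_; break }
  }
  if (is.null(hit)) pick_fail(switch(mode, up = "reclassIHigher",
                                     down = "reclassILower", sibling = "recastI"),
                              "no individual with a suitable target type")
  del_rows(st, row1(hit, RDF_TYPE, b1))
  add_rows(st, row1(hit, RDF_TYPE, b2))
  action <- switch(mode, up = "reclassIHigher", down = "reclassILower",
                   sibling = "recastI")
  expect_instance(st, action, "Complex",
                  list(individual = hit, old_type = b1, new_type = b2))
  # reserve (but do not claim) the hierarchy context the rule consults
  touch(st, action, c(hit, b1, b2),
        reserve = c(ancestors_nowarn(st$base, b1, "class_edges"),
                    ancestors_nowarn(st$base, b2, "class_edges")))
}
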