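#' Synthetic versioned-ontology fixtures with planted changes
#'
#' The generator emulates the shape of versioned biomedical ontologies — a
#' rooted class DAG with labels, comments and synonyms, a property hierarchy,
#' typed individuals, cross-relationships and deprecated entities — and then
#' applies a scripted list of change actions to produce an (old, new) version
#' pair together with a ground-truth ledger: the heuristic/complex instances
#' a correct diff must recover, the residual basic changes it must leave, and
#' the perfect entity mapping for the matcher-dependent actions. The ledger
#' is constructed action by action from the script, never by running the diff
#' engine, so it is an independent oracle.
#'
#' @param seed Integer seed; identical specs generate identical versions.
#' @param n_concepts,max_depth,branching Class hierarchy shape.
#' @param n_properties Number of properties (arranged as a binary subsumption
#'   tree, giving chains and siblings for the move rules).
#' @param n_individuals Number of typed individuals.
#' @param n_obsolete,n_obsolete_props Pre-deprecated concepts/properties
#'   (material for the revoke-obsolescence rules).
#' @param change_script Character vector of plantable action tokens; see
#'   [plantable_actions()].
#' @return A `ontodiff_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_concepts = 30L, max_depth = 5L,
                         branching = 4L, n_properties = 8L,
                         n_individuals = 6L, n_obsolete = 2L,
                         n_obsolete_props = 1L, change_script = character(0)) {
  assert_that(n_concepts >= 1 && branching >= 1 && max_depth >= 1,
              "fixture spec sizes must be positive")
  capacity <- sum(branching^(0:max_depth))
  assert_that(n_concepts <= capacity,
              sprintf("infeasible spec: depth %d / branching %d hosts at most %d concepts",
                      max_depth, branching, capacity))
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 max_depth = as.integer(max_depth), branching = as.integer(branching),
                 n_properties = as.integer(n_properties),
                 n_individuals = as.integer(n_individuals),
                 n_obsolete = as.integer(n_obsolete),
                 n_obsolete_props = as.integer(n_obsolete_props),
                 change_script = change_script),
            class = "ontodiff_fixture_spec")
}

EX <- "http://example.org/onto#"

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.syllables <- c("ka", "lo", "mi", "ta", "re", "su", "ve", "no", "bi", "du",
                "fa", "ge", "hy", "pe", "tro", "car", "dia", "neo", "len", "zu")

mk_word <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:4, 1)
  paste(sample(.syllables, n, replace = TRUE), collapse = "")
}

mk_label <- function() {
  k <- sample(1:2, 1)
  paste(vapply(seq_len(k), function(i) mk_word(), character(1)), collapse = " ")
}

row1 <- function(s, p, o, kind = "iri", lang = NA_character_, dt = NA_character_) {
  triple_tbl(s, p, o, kind, lang, dt)
}
lit_row <- function(s, p, v, lang = "en") row1(s, p, v, "literal", lang)

#' Generate a base ontology version
#'
#' @param spec A [fixture_spec()].
#' @return An `ontodiff_version`, deterministic under the spec's seed.
#' @export
generate_base <- function(spec) {
  local_seed(spec$seed, {
    rows <- list()
    add <- function(r) rows[[length(rows) + 1L]] <<- r
    ci <- function(i) paste0(EX, "C", sprintf("%03d", i))
    pi_ <- function(i) paste0(EX, "P", sprintf("%03d", i))
    ii <- function(i) paste0(EX, "I", sprintf("%03d", i))

    depth <- integer(spec$n_concepts)
    kids <- integer(spec$n_concepts)
    for (i in seq_len(spec$n_concepts)) {
      c_ <- ci(i)
      add(row1(c_, RDF_TYPE, paste0(NS$owl, "Class")))
      add(lit_row(c_, RDFS_LABEL, mk_label()))
      add(lit_row(c_, RDFS_COMMENT, paste("definition of", mk_word(3))))
      if (i %% 3 == 0) add(lit_row(c_, paste0(NS$skos, "altLabel"), mk_label()))
      if (i > 1) {
        cand <- which(depth[seq_len(i - 1)] < spec$max_depth &
                        kids[seq_len(i - 1)] < spec$branching)
        assert_that(length(cand) > 0,
                    "infeasible spec: no parent slot available for a concept")
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        add(row1(c_, RDFS_SUBCLASS, ci(j)))
        depth[i] <- depth[j] + 1L
        kids[j] <- kids[j] + 1L
        if (i %% 9 == 0 && length(cand) > 1) {
          k <- setdiff(cand, j)
          k <- if (length(k) == 1) k else sample(k, 1)
          add(row1(c_, RDFS_SUBCLASS, ci(k)))
        }
      }
    }
    for (k in seq_len(spec$n_obsolete)) {
      o_ <- paste0(EX, "OBS", sprintf("%03d", k))
      add(row1(o_, RDF_TYPE, paste0(NS$owl, "Class")))
      add(lit_row(o_, RDFS_LABEL, mk_label()))
      add(row1(o_, RDFS_SUBCLASS, ci(1)))
      add(row1(o_, OWL_DEPRECATED, "true", "literal", NA_character_, XSD_BOOLEAN))
    }
    for (i in seq_len(spec$n_properties)) {
      p_ <- pi_(i)
      add(row1(p_, RDF_TYPE, paste0(NS$owl, "ObjectProperty")))
      add(lit_row(p_, RDFS_LABEL, mk_label()))
      if (i > 1) add(row1(p_, RDFS_SUBPROP, pi_(i %/% 2)))
    }
    for (k in seq_len(spec$n_obsolete_props)) {
      o_ <- paste0(EX, "OBSP", sprintf("%03d", k))
      add(row1(o_, RDF_TYPE, paste0(NS$owl, "ObjectProperty")))
      add(lit_row(o_, RDFS_LABEL, mk_label()))
      add(row1(o_, OWL_DEPRECATED, "true", "literal", NA_character_, XSD_BOOLEAN))
    }
    if (spec$n_individuals > 0) {
      assert_that(spec$n_concepts >= 2,
                  "infeasible spec: individuals need a non-root concept to be typed to")
      for (i in seq_len(spec$n_individuals)) {
        t_ <- sample(2:spec$n_concepts, 1)
        add(row1(ii(i), RDF_TYPE, ci(t_)))
        add(lit_row(ii(i), RDFS_LABEL, mk_label()))
      }
    }
    if (spec$n_properties >= 1 && spec$n_concepts >= 8) {
      for (i in seq(5, spec$n_concepts, by = 7)) {
        add(row1(ci(i), pi_(1), ci(i - 2)))
      }
    }
    ontology_version(dplyr::bind_rows(rows), default_vocab())
  })
}

#' Plantable change-action tokens
#'
#' Script tokens accepted by [plant_changes()]. Most tokens name the change
#' action they plant; `toObsC_label` plants a label-encoded deprecation
#' (expected to surface as `toObsC`), and `multiParentLeaf`, `manyToMany`,
#' `partialSubGraph` plant the adversarial shapes whose expected outcome is
#' residual basics or a precedence-resolved instance.
#'
#' @return Character vector of tokens.
#' @export
plantable_actions <- function() {
  c(BASIC_ACTIONS,
    "mergeC", "mergeCInto", "splitC", "splitCInto",
    "mergeP", "mergePInto", "splitP", "splitPInto",
    "renC", "renP", "renI",
    "changeLabel", "changeComment", "changeOtherA",
    "pullUpC", "pullDownC", "moveC", "pullUpP", "pullDownP", "moveP",
    "toObsC", "revObsC", "toObsP", "revObsP", "toObsC_label",
    "addLeafC", "delLeafC", "addLeafP", "delLeafP",
    "addSubGraphC", "delSubGraphC", "addSubGraphP", "delSubGraphP",
    "recastI", "reclassIHigher", "reclassILower",
    "multiParentLeaf", "manyToMany", "partialSubGraph")
}

# --- planting state -----------------------------------------------------------

new_plant_state <- function(base, spec) {
  st <- new.env(parent = emptyenv())
  st$base <- base
  st$vocab <- base$vocab
  st$new_tr <- base$triples
  st$touched <- character(0)
  st$touch_sets <- list()
  st$instances <- list()
  st$basics <- list()
  st$mapping <- list()
  st$fresh_n <- 0L
  st$rel_subjects <- unique(base$relationships$subject)
  all_entities <- c(base$concepts, base$properties, base$individuals)
  st$obsolete <- all_entities[vapply(all_entities, function(e)
    is_obsolete(base, e, base$vocab), logical(1))]
  st
}

fresh_iri <- function(st, stem = "N") {
  st$fresh_n <- st$fresh_n + 1L
  paste0(EX, stem, sprintf("%03d", st$fresh_n))
}

# `core` entities belong to this action alone (asserted pairwise disjoint);
# `reserve` entities are additionally made invisible to later pickers (e.g. the
# ancestor path a reclassification rule will consult) but may be shared.
touch <- function(st, action, core, reserve = character(0)) {
  st$touch_sets[[length(st$touch_sets) + 1L]] <-
    list(action = action, entities = unique(core))
  st$touched <- union(st$touched, c(core, reserve))
}

add_rows <- function(st, rows) st$new_tr <- dplyr::bind_rows(st$new_tr, rows)

del_rows <- function(st, rows) {
  st$new_tr <- st$new_tr[!(render_ntriple(st$new_tr) %in% render_ntriple(rows)), ,
                         drop = FALSE]
}

subject_rows <- function(st, entity) {
  st$new_tr[st$new_tr$subject == entity, , drop = FALSE]
}

expect_instance <- function(st, action, category, args) {
  st$instances[[length(st$instances) + 1L]] <-
    new_instance(action, category, args, consumed = "planted")
}

expect_basic <- function(st, action, subject, payload) {
  st$basics[[length(st$basics) + 1L]] <-
    tibble::tibble(action = action, subject = subject, payload = list(payload))
}

expect_map <- function(st, source, target, kind) {
  st$mapping[[length(st$mapping) + 1L]] <-
    tibble::tibble(source = source, target = target, score = 1, kind = kind)
}

# fixtures' own single-triple classifier (mirror of the basic-change table;
# deliberately independent of the engine's classifier)
fx_action_for_row <- function(row, direction, vocab, individual_subject = FALSE) {
  pfx <- if (direction == "add") "add" else "del"
  if (row$predicate == vocab$type_predicate && row$object_kind != "literal") {
    if (row$object %in% vocab$class_declaration_objects) return(paste0(pfx, "C"))
    if (row$object %in% vocab$property_declaration_objects) return(paste0(pfx, "P"))
    return(if (individual_subject) paste0(pfx, "I") else paste0(pfx, "OtherR"))
  }
  if (row$predicate == vocab$class_subsumption && row$object_kind != "literal")
    return(paste0(pfx, "SupC"))
  if (row$predicate == vocab$property_subsumption && row$object_kind != "literal")
    return(paste0(pfx, "SupP"))
  if (row$object_kind == "literal") {
    if (row$predicate %in% vocab$label_predicates) return(paste0(pfx, "Label"))
    if (row$predicate %in% vocab$comment_predicates) return(paste0(pfx, "Comment"))
    return(paste0(pfx, "OtherA"))
  }
  paste0(pfx, "OtherR")
}

# record residual basics for a set of edited rows, skipping the triples a
# planted instance consumes; individual type rows are folded per subject
expect_residuals <- function(st, rows, direction, skip = NULL,
                             individual_subjects = character(0)) {
  if (!is.null(skip) && nrow(skip) > 0)
    rows <- rows[!(render_ntriple(rows) %in% render_ntriple(skip)), , drop = FALSE]
  if (nrow(rows) == 0) return(invisible())
  type_fold <- rows$predicate == st$vocab$type_predicate &
    rows$object_kind != "literal" & rows$subject %in% individual_subjects
  for (s in unique(rows$subject[type_fold])) {
    payload <- rows[type_fold & rows$subject == s, , drop = FALSE]
    payload <- payload[stable_order(render_ntriple(payload)), , drop = FALSE]
    expect_basic(st, if (direction == "add") "addI" else "delI", s, payload)
  }
  rest <- rows[!type_fold, , drop = FALSE]
  for (i in seq_len(nrow(rest))) {
    r <- rest[i, , drop = FALSE]
    expect_basic(st, fx_action_for_row(r, direction, st$vocab), r$subject, r)
  }
  invisible()
}

# --- structural pickers (all deterministic: scan sorted IRIs) ----------------

pick_fail <- function(action, why) {
  stop("cannot plant '", action, "': ", why, call. = FALSE)
}

fx_children <- function(st, entity, kind = "class_edges") {
  e <- st$base[[kind]]
  stable_sort(unique(e$child[e$parent == entity]))
}
fx_parents <- function(st, entity, kind = "class_edges") {
  e <- st$base[[kind]]
  stable_sort(unique(e$parent[e$child == entity]))
}

fx_pool <- function(st, kind) {
  pool <- if (kind == "concept") st$base$concepts
          else if (kind == "property") st$base$properties
          else st$base$individuals
  setdiff(pool, c(st$touched, st$obsolete))
}

# does the entity still carry its declaration in the working new version?
fx_persists_new <- function(st, e, kind) {
  obj <- if (kind == "concept") paste0(NS$owl, "Class")
         else paste0(NS$owl, "ObjectProperty")
  any(st$new_tr$subject == e & st$new_tr$predicate == RDF_TYPE &
        st$new_tr$object == obj)
}

# a clean entity can be deleted wholesale without side effects on others:
# childless, not typed by individuals, not the subject of cross-relationships,
# attached to parents that still persist in the working new version
fx_clean_leaf <- function(st, kind, n = 1, need_single_parent = FALSE,
                          action = "(picker)") {
  edge_kind <- if (kind == "concept") "class_edges" else "property_edges"
  pool <- fx_pool(st, kind)
  typed <- unique(st$base$type_assertions$class)
  ok <- vapply(pool, function(e) {
    ch <- fx_children(st, e, edge_kind)
    pa <- fx_parents(st, e, edge_kind)
    length(ch) == 0 && !(e %in% typed) && !(e %in% st$rel_subjects) &&
      length(pa) >= 1 && (!need_single_parent || length(pa) == 1) &&
      all(vapply(pa, fx_persists_new, logical(1), st = st, kind = kind))
  }, logical(1))
  hits <- pool[ok]
  if (length(hits) < n) pick_fail(action, paste("need", n, "clean", kind, "leaves"))
  hits[seq_len(n)]
}

fx_untouched <- function(st, kind, n = 1, exclude = character(0),
                         action = "(picker)") {
  pool <- setdiff(fx_pool(st, kind), exclude)
  if (length(pool) < n) pick_fail(action, paste("need", n, "untouched", kind))
  pool[seq_len(n)]
}

#' Apply a change script to a base version
#'
#' Plants every scripted action on entities untouched by the other actions
#' (erroring with the action name and reason when the base cannot host one),
#' and returns the old/new pair plus the ground-truth ledger. The ledger is
#' derived from the script alone; the diff engine is never consulted.
#'
#' @param base An `ontodiff_version` from [generate_base()].
#' @param spec The [fixture_spec()] carrying `change_script`.
#' @return A list `old`, `new`, `ledger`; the ledger (class `ontodiff_ledger`)
#'   holds `instances` (expected heuristic/complex instances), `basics`
#'   (expected residual basic changes), `mapping` (the perfect mapping for the
#'   matcher-dependent actions) and `touch_sets` (per-action entity sets,
#'   pairwise disjoint).
#' @export
plant_changes <- function(base, spec) {
  st <- new_plant_state(base, spec)
  fns <- plant_fns()
  local_seed(spec$seed + 1000L, {
    for (tok in spec$change_script) {
      fn <- fns[[tok]]
      if (is.null(fn))
        stop("unknown change-script token '", tok, "'", call. = FALSE)
      fn(st)
    }
  })
  sets <- lapply(st$touch_sets, `[[`, "entities")
  if (length(sets) > 1) {
    all_e <- unlist(sets)
    assert_that(!anyDuplicated(all_e),
                "script actions overlap in touched entities")
  }
  mapping <- if (length(st$mapping) > 0) {
    m <- dplyr::bind_rows(st$mapping)
    mapping_tbl(m$source, m$target, m$score, m$kind)
  } else mapping_tbl()
  basics <- if (length(st$basics) > 0) dplyr::bind_rows(st$basics) else
    tibble::tibble(action = character(), subject = character(), payload = list())
  ledger <- structure(list(instances = bind_instances(!!!st$instances),
                           basics = basics, mapping = mapping,
                           touch_sets = st$touch_sets),
                      class = "ontodiff_ledger")
  list(old = base, new = ontology_version(st$new_tr, st$vocab), ledger = ledger)
}

#' @export
print.ontodiff_ledger <- function(x, ...) {
  cat("<ground-truth ledger>", nrow(x$instances), "expected instances,",
      nrow(x$basics), "expected residual basics,",
      nrow(x$mapping), "perfect-mapping rows\n")
  invisible(x)
}

ledger_basic_keys <- function(ledger) {
  b <- ledger$basics
  if (nrow(b) == 0) return(character(0))
  vapply(seq_len(nrow(b)), function(i) {
    paste0(b$action[[i]], "|",
           paste(stable_sort(render_ntriple(b$payload[[i]])), collapse = "|"))
  }, character(1))
}

#' Compare a diff result against a ground-truth ledger
#'
#' Exact recovery check: the result's heuristic + complex instances must
#' equal the planted instances (same actions, same arguments) and the
#' residual basics must equal the planted residual, both as sets.
#'
#' @param result An `ontodiff_result`.
#' @param ledger An `ontodiff_ledger`.
#' @return TRUE on exact recovery; otherwise FALSE with attributes
#'   `missing_instances`, `extra_instances`, `missing_basics`, `extra_basics`.
#' @export
ledger_matches <- function(result, ledger) {
  got_i <- instance_keys(bind_instances(result$heuristic, result$complex))
  want_i <- instance_keys(ledger$instances)
  got_b <- basic_key(result$basic_residual)
  want_b <- ledger_basic_keys(ledger)
  ok <- setequal(got_i, want_i) && setequal(got_b, want_b)
  if (ok) return(TRUE)
  structure(FALSE,
            missing_instances = setdiff(want_i, got_i),
            extra_instances = setdiff(got_i, want_i),
            missing_basics = setdiff(want_b, got_b),
            extra_basics = setdiff(got_b, want_b))
}

#' The standard fixture suite
#'
#' Six fixed-seed version pairs that together plant every instantiable change
#' action of the taxonomy at least once — all 18 basic actions, all 13
#' heuristic actions, all complex actions including the interior
#' generalizations — plus the adversarial shapes (multi-parent leaf,
#' many-to-many mapping, label-encoded obsolescence, partially added
#' subgraph).
#'
#' @return Named list of `list(old, new, ledger, spec)` fixtures.
#' @export
standard_suite <- function() {
  specs <- list(
    basics = fixture_spec(
      seed = 11, n_concepts = 40, max_depth = 5, branching = 4,
      n_properties = 10, n_individuals = 6,
      change_script = BASIC_ACTIONS),
    heuristic_concepts = fixture_spec(
      seed = 12, n_concepts = 60, max_depth = 5, branching = 5,
      n_properties = 8, n_individuals = 4,
      change_script = c("mergeC", "mergeCInto", "splitC", "splitCInto",
                        "renC", "changeLabel", "changeComment", "changeOtherA")),
    heuristic_properties = fixture_spec(
      seed = 13, n_concepts = 20, max_depth = 4, branching = 4,
      n_properties = 24, n_individuals = 6,
      change_script = c("mergeP", "mergePInto", "splitP", "splitPInto",
                        "renP", "renI")),
    complex_concepts = fixture_spec(
      seed = 14, n_concepts = 60, max_depth = 6, branching = 3,
      n_properties = 6, n_individuals = 4, n_obsolete = 2,
      change_script = c("delSubGraphC", "addSubGraphC", "pullUpC", "pullDownC",
                        "moveC", "addLeafC", "delLeafC", "toObsC", "revObsC",
                        "toObsC_label")),
    complex_properties_individuals = fixture_spec(
      seed = 15, n_concepts = 40, max_depth = 5, branching = 4,
      n_properties = 28, n_individuals = 10, n_obsolete_props = 1,
      change_script = c("delSubGraphP", "addSubGraphP", "pullUpP", "pullDownP",
                        "moveP", "addLeafP", "delLeafP", "toObsP", "revObsP",
                        "recastI", "reclassIHigher", "reclassILower")),
    adversarial = fixture_spec(
      seed = 16, n_concepts = 40, max_depth = 5, branching = 4,
      n_properties = 8, n_individuals = 4,
      change_script = c("multiParentLeaf", "manyToMany", "partialSubGraph"))
  )
  lapply(specs, function(sp) {
    fx <- plant_changes(generate_base(sp), sp)
    fx$spec <- sp
    fx
  })
}

#' One randomized fixture pair
#'
#' Samples a random subset of plantable actions under the given seed and
#' plants it on a base large enough to host any combination; used by the
#' property-style partition and reconstruction checks.
#'
#' @param seed Integer seed.
#' @param n_actions Number of distinct actions to sample (default 3-8,
#'   seed-dependent).
#' @return As [plant_changes()].
#' @export
random_fixture_pair <- function(seed, n_actions = NULL) {
  tokens <- local_seed(seed * 13L + 7L, {
    k <- n_actions %||% sample(3:8, 1)
    sample(plantable_actions(), min(k, length(plantable_actions())))
  })
  # a sampled combination can exhaust the base's structural material (e.g.
  # several property-subtree deletions); drop the action the planter rejects
  # and retry — deterministic, since planting errors name their token
  repeat {
    sp <- fixture_spec(seed = seed, n_concepts = 45, max_depth = 6, branching = 3,
                       n_properties = 20, n_individuals = 8, n_obsolete = 2,
                       n_obsolete_props = 1, change_script = tokens)
    fx <- tryCatch(plant_changes(generate_base(sp), sp), error = identity)
    if (!inherits(fx, "error")) return(fx)
    msg <- conditionMessage(fx)
    tok <- sub("^cannot plant '([^']+)'.*$", "\\1", msg)
    if (!grepl("^cannot plant", msg) || !(tok %in% tokens) || length(tokens) <= 1)
      stop(fx)
    tokens <- tokens[-match(tok, tokens)]
  }
}
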