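# Serialization of diff results as instances of the bundled change taxonomy.
#
# Per-action mapping from argument roles to taxonomy object properties; each
# map is bijective within its action so parsing is unambiguous.

role_property_map <- function(action) {
  if (action %in% c("mergeC", "mergeP", "mergeCInto", "mergePInto"))
    return(c(sources = "hasSourceEntity", target = "hasTargetEntity"))
  if (action %in% c("splitC", "splitP", "splitCInto", "splitPInto"))
    return(c(source = "hasSourceEntity", targets = "hasTargetEntity"))
  if (action %in% c("renC", "renP", "renI"))
    return(c(old = "hasSourceEntity", new = "hasTargetEntity"))
  if (action %in% c("changeLabel", "changeComment", "changeOtherA"))
    return(c(entity = "hasEntity", predicate = "hasPredicate"))
  if (action %in% c("moveC", "moveP", "pullUpC", "pullUpP",
                    "pullDownC", "pullDownP"))
    return(c(entity = "hasEntity", old_parents = "hasOldParent",
             new_parents = "hasNewParent"))
  if (action %in% c("addLeafC", "addLeafP"))
    return(c(entity = "hasEntity", parent = "hasNewParent"))
  if (action %in% c("delLeafC", "delLeafP"))
    return(c(entity = "hasEntity", parent = "hasOldParent"))
  if (action %in% c("addSubGraphC", "addSubGraphP",
                    "delSubGraphC", "delSubGraphP"))
    return(c(root = "hasEntity", members = "hasTargetEntity"))
  if (action %in% c("toObsC", "toObsP", "revObsC", "revObsP"))
    return(c(entity = "hasEntity"))
  if (action %in% c("recastI", "reclassIHigher", "reclassILower"))
    return(c(individual = "hasEntity", old_type = "hasOldType",
             new_type = "hasNewType"))
  c(entity = "hasEntity")
}

#' Serialize a diff result
#'
#' Emits every heuristic/complex instance as a typed instance of its taxonomy
#' class, with argument and provenance (consumption) properties, plus the
#' residual basic changes with their backing triples. Turtle output types
#' instances against the taxonomy namespace; JSON output is an object with
#' `changes` and `residual` arrays. Both round-trip through
#' [parse_changes()] to the same diff content. Instances are validated first;
#' an invalid instance aborts with its validation report.
#'
#' @param result An `ontodiff_result`.
#' @param tax An `ontodiff_taxonomy`.
#' @param format `"turtle"` or `"json"`.
#' @param path Optional output file.
#' @return The serialized document as a single string (invisibly when
#'   written to `path`).
#' @export
serialize_changes <- function(result, tax = load_taxonomy(),
                              format = c("turtle", "json"), path = NULL) {
  format <- match.arg(format)
  instances <- bind_instances(result$heuristic, result$complex)
  for (i in seq_len(nrow(instances))) {
    rep <- validate_instance(instances[i, ], tax)
    if (nrow(rep) > 0)
      stop("invalid change instance ", instances$instance_id[[i]], ": ",
           paste(rep$message, collapse = "; "), call. = FALSE)
  }
  res <- result$basic_residual
  out <- if (format == "json") {
    jsonlite::toJSON(list(
      changes = lapply(seq_len(nrow(instances)), function(i) {
        list(instanceId = instances$instance_id[[i]],
             action = instances$action[[i]],
             category = instances$category[[i]],
             arguments = instances$arguments[[i]],
             consumed = instances$consumed[[i]])
      }),
      residual = lapply(seq_len(nrow(res)), function(i) {
        list(id = res$id[[i]], action = res$action[[i]],
             subject = res$subject[[i]],
             triples = stable_sort(render_ntriple(res$payload[[i]])))
      })), auto_unbox = TRUE, pretty = TRUE, null = "null")
  } else {
    serialize_changes_turtle(instances, res)
  }
  out <- as.character(out)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

serialize_changes_turtle <- function(instances, residual) {
  oc <- function(x) paste0("oc:", x)
  lit <- function(v, lang = NA_character_) {
    paste0("\"", escape_literal(v), "\"",
           if (!is.na(lang) && nzchar(lang)) paste0("@", lang) else "")
  }
  iri <- function(x) paste0("<", x, ">")
  lines <- c(paste0("@prefix oc: <", OC_NS, "> ."), "")
  for (i in seq_len(nrow(instances))) {
    action <- instances$action[[i]]
    args <- instances$arguments[[i]]
    pm <- role_property_map(action)
    body <- c(paste0("  a ", oc(action)),
              paste0("  oc:changeId ", lit(instances$instance_id[[i]])))
    for (role in names(pm)) {
      v <- args[[role]]
      if (is.null(v) || length(v) == 0) next
      body <- c(body, paste0("  ", oc(pm[[role]]), " ",
                             paste(iri(v), collapse = ", ")))
    }
    if (action %in% c("changeLabel", "changeComment", "changeOtherA")) {
      body <- c(body,
                paste0("  oc:oldValue ", lit(args$old_value, args$old_lang %||% NA)),
                paste0("  oc:newValue ", lit(args$new_value, args$new_lang %||% NA)))
    }
    cons <- instances$consumed[[i]]
    if (length(cons) > 0)
      body <- c(body, paste0("  oc:consumesBasicChange ",
                             paste(iri(paste0(OC_NS, "basic-", cons)),
                                   collapse = ", ")))
    lines <- c(lines, paste0(iri(paste0(OC_NS, "inst-", instances$instance_id[[i]]))),
               paste0(body, c(rep(" ;", length(body) - 1), " .")), "")
  }
  for (i in seq_len(nrow(residual))) {
    body <- c(paste0("  a ", oc(residual$action[[i]])),
              paste0("  oc:changeId ", lit(residual$id[[i]])),
              paste0("  oc:hasEntity ", iri(residual$subject[[i]])),
              vapply(stable_sort(render_ntriple(residual$payload[[i]])),
                     function(tl) paste0("  oc:literalValue ", lit(tl)),
                     character(1)))
    lines <- c(lines, paste0(iri(paste0(OC_NS, "basic-", residual$id[[i]]))),
               paste0(body, c(rep(" ;", length(body) - 1), " .")), "")
  }
  paste(c(lines, ""), collapse = "\n")
}

#' Parse serialized changes back into diff content
#'
#' Inverse of [serialize_changes()]: reconstructs the heuristic/complex
#' instances (action, category, arguments, consumption) and the residual
#' basic changes with their backing triples.
#'
#' @param x Serialized text, or a path to a file.
#' @param format `"turtle"` or `"json"`.
#' @param tax An `ontodiff_taxonomy` used to type instances.
#' @return A list with `instances` and `residual` tibbles.
#' @export
parse_changes <- function(x, format = c("turtle", "json"), tax = load_taxonomy()) {
  format <- match.arg(format)
  if (length(x) == 1 && file.exists(x))
    x <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  if (format == "json") {
    doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
    inst <- bind_instances(!!!lapply(doc$changes, function(ch) {
      args <- lapply(ch$arguments, function(v) unlist(v))
      tibble::tibble(instance_id = ch$instanceId, action = ch$action,
                     category = ch$category, arguments = list(args),
                     consumed = list(unlist(ch$consumed) %||% character(0)))
    }))
    res <- purrr::map_dfr(doc$residual, function(r) {
      payload <- parse_turtle(paste(unlist(r$triples), collapse = "\n"))
      tibble::tibble(id = r$id, action = r$action, subject = r$subject,
                     payload = list(payload))
    })
    return(list(instances = inst, residual = res))
  }
  tr <- parse_turtle(x, source = "<changes>")
  typed <- tr[tr$predicate == RDF_TYPE & startsWith(tr$object, OC_NS), , drop = FALSE]
  typed$action <- iri_local_name(typed$object)
  cls <- tax$classes
  insts <- list()
  resid <- list()
  for (i in seq_len(nrow(typed))) {
    node <- typed$subject[[i]]
    action <- typed$action[[i]]
    row <- cls[cls$id == action, , drop = FALSE]
    if (nrow(row) == 0) next
    mine <- tr[tr$subject == node, , drop = FALSE]
    val <- function(prop) mine$object[mine$predicate == paste0(OC_NS, prop)]
    lang_of <- function(prop) mine$lang[mine$predicate == paste0(OC_NS, prop)]
    cid <- val("changeId")[1]
    if (row$category[[1]] == "Basic") {
      payload <- parse_turtle(paste(val("literalValue"), collapse = "\n"))
      resid[[length(resid) + 1L]] <- tibble::tibble(
        id = cid, action = action, subject = val("hasEntity")[1],
        payload = list(payload))
    } else {
      pm <- role_property_map(action)
      args <- list()
      for (role in names(pm)) {
        v <- stable_sort(val(pm[[role]]))
        if (length(v) > 0) args[[role]] <- if (length(v) == 1) v else v
      }
      if (action %in% c("changeLabel", "changeComment", "changeOtherA")) {
        args$old_value <- val("oldValue")[1]
        args$old_lang <- lang_of("oldValue")[1] %|NA|% ""
        args$new_value <- val("newValue")[1]
        args$new_lang <- lang_of("newValue")[1] %|NA|% ""
      }
      consumed <- sub(paste0("^", OC_NS, "basic-"), "",
                      val("consumesBasicChange"))
      insts[[length(insts) + 1L]] <- tibble::tibble(
        instance_id = cid, action = action, category = row$category[[1]],
        arguments = list(args), consumed = list(stable_sort(consumed)))
    }
  }
  list(instances = bind_instances(!!!insts), residual = dplyr::bind_rows(resid))
}

#' Structural equality of diff content
#'
#' Compares two diff results (or parsed-changes lists) on canonical instance
#' keys and residual basic-change content, ignoring ordering and internal
#' identifiers.
#'
#' @param a,b `ontodiff_result` objects or [parse_changes()] outputs.
#' @return TRUE iff both carry the same instances and residual basics.
#' @export
diff_content_equal <- function(a, b) {
  inst_a <- if (inherits(a, "ontodiff_result")) bind_instances(a$heuristic, a$complex) else a$instances
  inst_b <- if (inherits(b, "ontodiff_result")) bind_instances(b$heuristic, b$complex) else b$instances
  res_a <- if (inherits(a, "ontodiff_result")) a$basic_residual else a$residual
  res_b <- if (inherits(b, "ontodiff_result")) b$basic_residual else b$residual
  res_key <- function(res) {
    if (nrow(res) == 0) return(character(0))
    vapply(seq_len(nrow(res)), function(i) {
      paste0(res$action[[i]], "|",
             paste(stable_sort(render_ntriple(res$payload[[i]])), collapse = "|"))
    }, character(1))
  }
  setequal(instance_keys(inst_a), instance_keys(inst_b)) &&
    setequal(res_key(res_a), res_key(res_b))
}
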