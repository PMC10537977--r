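# Internal representation of heuristic/complex change instances.
#
# Instances live in a tibble with columns: instance_id, action, category
# ("Heuristic"/"Complex"), arguments (list-column of named lists; set-valued
# roles are sorted character vectors) and consumed (list-column of basic
# change ids). The canonical key (action + flattened arguments) makes
# instances comparable across the engine and the fixture ground truth.

empty_instances <- function() {
  tibble::tibble(instance_id = character(), action = character(),
                 category = character(), arguments = list(), consumed = list())
}

canonical_instance_key <- function(action, arguments) {
  arguments <- arguments[lengths(arguments) > 0]
  nm <- stable_sort(names(arguments))
  parts <- vapply(nm, function(n) {
    v <- arguments[[n]]
    v <- if (is.character(v)) stable_sort(v) else as.character(v)
    paste0(n, "=", paste(v, collapse = ""))
  }, character(1))
  paste0(action, "|", paste(parts, collapse = "|"))
}

new_instance <- function(action, category, arguments, consumed) {
  # sort set-valued roles once so keys and serialization are deterministic
  arguments <- lapply(arguments, function(v) {
    if (is.character(v) && length(v) > 1) stable_sort(v) else v
  })
  key <- canonical_instance_key(action, arguments)
  tibble::tibble(instance_id = paste0(action, "-", content_hash(key)),
                 action = action, category = category,
                 arguments = list(arguments),
                 consumed = list(stable_sort(unique(consumed))))
}

instance_keys <- function(instances) {
  if (nrow(instances) == 0) return(character(0))
  vapply(seq_len(nrow(instances)),
         function(i) canonical_instance_key(instances$action[[i]],
                                            instances$arguments[[i]]),
         character(1))
}

bind_instances <- function(...) {
  out <- dplyr::bind_rows(...)
  if (nrow(out) == 0) return(empty_instances())
  out[stable_order(out$category, out$action, instance_keys(out)), , drop = FALSE]
}
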