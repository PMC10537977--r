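#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

primary_entity <- function(args) {
  for (role in c("entity", "individual", "root", "source", "target",
                 "old", "new", "sources", "targets")) {
    v <- args[[role]]
    if (!is.null(v) && length(v) > 0) return(v[[1]])
  }
  NA_character_
}

#' Tidy a diff result
#'
#' One row per change: residual basic changes and heuristic/complex
#' instances, with the change category, action id, primary entity and the
#' number of basic changes consumed.
#'
#' @param x An `ontodiff_result`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `category`, `action`, `entity`,
#'   `n_consumed`.
#' @export
tidy.ontodiff_result <- function(x, ...) {
  inst <- bind_instances(x$heuristic, x$complex)
  rows <- list()
  if (nrow(inst) > 0) {
    rows[[1]] <- tibble::tibble(
      id = inst$instance_id, category = inst$category, action = inst$action,
      entity = vapply(inst$arguments, primary_entity, character(1)),
      n_consumed = lengths(inst$consumed))
  }
  if (nrow(x$basic_residual) > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = x$basic_residual$id, category = "Basic",
      action = x$basic_residual$action, entity = x$basic_residual$subject,
      n_consumed = 0L)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(id = character(), category = character(),
                          action = character(), entity = character(),
                          n_consumed = integer())
  out[stable_order(out$category, out$action, out$entity), , drop = FALSE]
}

#' One-row summary of a diff result
#'
#' @inheritParams tidy.ontodiff_result
#' @return A one-row tibble with the delta sizes, change counts, the
#'   consumed-basic fraction and the composite-to-low-level ratio.
#' @export
glance.ontodiff_result <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    n_triples_added = s$n_triples_added,
    n_triples_deleted = s$n_triples_deleted,
    n_basic_total = s$n_basic_total,
    n_basic_residual = s$n_basic_residual,
    n_heuristic = s$n_heuristic,
    n_complex = s$n_complex,
    n_composite = s$n_composite,
    consumed_basic_fraction = s$consumed_basic_fraction,
    composite_to_lowlevel_ratio = s$composite_to_lowlevel_ratio)
}

#' Plot the change-action profile of a diff
#'
#' Horizontal bar chart of per-action change counts, coloured by category
#' (basic residual, heuristic, complex).
#'
#' @param object An `ontodiff_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ontodiff_result <- function(object, ...) {
  td <- tidy(object)
  if (nrow(td) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no changes") +
             ggplot2::theme_void())
  }
  counts <- dplyr::count(td, .data$category, .data$action)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$n,
                               y = stats::reorder(.data$action, .data$n),
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "changes", y = NULL, fill = NULL,
                  title = "Detected change actions") +
    ggplot2::theme_minimal()
}
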