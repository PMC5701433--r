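# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a process graph into a statement table
#'
#' Flattens the graph into subject–predicate–object triples covering
#' participants, composition roles, localization/binding edges and the
#' class hierarchy.
#'
#' @param x A `process_graph`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `predicate`, `object`.
#' @method tidy process_graph
#' @export
tidy.process_graph <- function(x, ...) {
  rows <- list()
  emit <- function(subject, predicate, object) {
    if (length(object) > 0) {
      rows[[length(rows) + 1L]] <<- tibble(subject = subject,
                                           predicate = predicate,
                                           object = object)
    }
  }
  ent <- x$entities
  for (i in seq_len(nrow(ent))) {
    for (f in c("located_in", "binds_to", "is_motif_of", "has_template")) {
      emit(ent$id[i], f, ent[[f]][[i]])
    }
    emit(ent$id[i], "has_function", ent$functions[[i]])
  }
  prc <- x$processes
  for (i in seq_len(nrow(prc))) {
    for (f in c("inputs", "outputs", "catalysts", "starts_with", "ends_with",
                "intermediates", "forks", "cyclication_of")) {
      pred <- c(inputs = "has_input", outputs = "has_output",
                catalysts = "has_catalyst", starts_with = "starts_with",
                ends_with = "ends_with",
                intermediates = "has_intermediate_process",
                forks = "has_fork_process",
                cyclication_of = "cyclication_of")[[f]]
      emit(prc$id[i], pred, prc[[f]][[i]])
    }
  }
  if (nrow(x$is_a) > 0) {
    rows[[length(rows) + 1L]] <- tibble(subject = x$is_a$child,
                                        predicate = "is_a",
                                        object = x$is_a$parent)
  }
  if (length(rows) == 0) {
    return(tibble(subject = character(), predicate = character(),
                  object = character()))
  }
  arrange(bind_rows(rows), .data$subject, .data$predicate, .data$object)
}

#' @rdname tidy.process_graph
#' @method glance process_graph
#' @export
glance.process_graph <- function(x, ...) {
  tibble(
    n_entities = nrow(x$entities),
    n_processes = nrow(x$processes),
    n_elementary = sum(x$processes$kind == "elementary"),
    n_aggregated = sum(x$processes$kind == "aggregated"),
    n_is_a = nrow(x$is_a),
    n_violations = nrow(validate_graph(x))
  )
}

#' Tidy an inference bundle into a fact table
#'
#' @param x An `inference_bundle` from [saturate()].
#' @param ... Unused.
#' @return A tibble with columns `predicate`, `subject`, `object` listing
#'   every derived fact (inferred I/O, precedes, consumes, key elements,
#'   affects).
#' @method tidy inference_bundle
#' @export
tidy.inference_bundle <- function(x, ...) {
  out <- bind_rows(
    tibble(predicate = ifelse(x$io$direction == "input", "has_input",
                              "has_output"),
           subject = x$io$process_id, object = x$io$entity_id),
    tibble(predicate = "precedes", subject = x$precedes$from,
           object = x$precedes$to),
    tibble(predicate = "consumes", subject = x$consumed$agg_id,
           object = x$consumed$entity_id),
    tibble(predicate = "has_key_element", subject = x$key_elements$process_id,
           object = x$key_elements$entity_id),
    tibble(predicate = "affects", subject = x$affects$function_label,
           object = x$affects$process_id)
  )
  arrange(out, .data$predicate, .data$subject, .data$object)
}

#' @rdname tidy.inference_bundle
#' @method glance inference_bundle
#' @export
glance.inference_bundle <- function(x, ...) {
  tibble(
    mode = x$mode, scope = x$scope,
    n_aggregates = length(unique(x$io$process_id)),
    n_precedes = nrow(x$precedes),
    n_consumed = nrow(x$consumed),
    n_key_elements = nrow(x$key_elements),
    n_affects = nrow(x$affects)
  )
}

#' Tidy a model assignment
#'
#' @param x A `model_assignment` from [assign_models()].
#' @param ... Unused.
#' @return The `assigned` tibble (`process_id`, `category`, `template`,
#'   `sbo_xref`, `parameters`).
#' @method tidy model_assignment
#' @export
tidy.model_assignment <- function(x, ...) x$assigned

#' @rdname tidy.model_assignment
#' @method glance model_assignment
#' @export
glance.model_assignment <- function(x, ...) {
  tibble(n_modeled = length(unique(x$assigned$process_id)),
         n_unmodeled = length(x$unmodeled),
         n_templates = length(unique(x$assigned$template)))
}

#' Plot the multi-scale composition of a process graph
#'
#' Draws the composition DAG (aggregates above their sub-processes) with
#' elementary and aggregated processes distinguished by shape.
#'
#' @param object A `process_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot process_graph
#' @export
autoplot.process_graph <- function(object, ...) {
  prc <- object$processes
  subs <- subprocess_sets(object)
  edges <- bind_rows(imap(subs, ~ if (length(.x) > 0)
    tibble(from = .y, to = .x) else NULL))
  depth <- stats::setNames(rep(0L, nrow(prc)), prc$id)
  changed <- TRUE
  while (changed && nrow(edges) > 0) {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      d <- depth[[edges$from[k]]] + 1L
      if (depth[[edges$to[k]]] < d) { depth[[edges$to[k]]] <- d; changed <- TRUE }
    }
  }
  nodes <- tibble(id = prc$id, kind = prc$kind,
                  depth = unname(depth[prc$id]))
  nodes <- nodes |>
    group_by(.data$depth) |>
    mutate(x = seq_along(.data$id)) |>
    ungroup() |>
    mutate(y = -.data$depth)
  if (nrow(edges) > 0) {
    edges <- edges |>
      left_join(nodes, by = c("from" = "id")) |>
      rename(x0 = "x", y0 = "y") |>
      select(-"kind", -"depth") |>
      left_join(nodes, by = c("to" = "id")) |>
      rename(x1 = "x", y1 = "y")
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      colour = "grey60")
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$kind),
      size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 3) +
    ggplot2::labs(x = NULL, y = "granularity level", shape = "process kind") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot the inferred ordering of sub-processes
#'
#' Shows the `precedes` chain of one aggregate as an arrow diagram.
#'
#' @param object An `inference_bundle`.
#' @param agg_id Aggregate to display; defaults to the first.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot inference_bundle
#' @export
autoplot.inference_bundle <- function(object, agg_id = NULL, ...) {
  prec <- object$precedes
  agg_id <- agg_id %||% (if (nrow(prec) > 0) prec$agg_id[1] else
    unique(object$io$process_id)[1])
  prec <- prec[prec$agg_id == agg_id, ]
  nodes <- unique(c(prec$from, prec$to))
  g <- igraph::graph_from_data_frame(prec[c("from", "to")],
                                     vertices = nodes)
  ord <- names(igraph::topo_sort(g))
  pos <- tibble(id = ord, x = seq_along(ord), y = 0)
  edges <- prec |>
    left_join(pos, by = c("from" = "id")) |>
    rename(x0 = "x") |>
    left_join(pos, by = c("to" = "id")) |>
    rename(x1 = "x")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0 + 0.15, xend = .data$x1 - 0.15, y = 0,
                   yend = 0),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = 0, label = .data$id)) +
    ggplot2::labs(title = sprintf("precedes ordering in %s", agg_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}
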