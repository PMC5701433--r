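# Forward-chaining inference over the multi-scale hierarchy.
#
# Rules implemented (saturated bottom-up over the composition DAG):
#   * precedes   — p1 precedes p2 when an output of p1 is an input of p2
#   * aggregate inputs/outputs — Step 1 seeds (inputs of starters and
#     forks; outputs of enders) plus Step 2 propagation of participants not
#     covered by an internal producer/consumer
#   * consumes   — intermediates produced and then consumed strictly inside
#     the aggregate (guards: the producer is no ender, the consumer no
#     starter or fork)
#   * has_key_element — an entity that is both input and output of the same
#     process (e.g. the enzyme of an enzymatic step)
#   * affects    — molecular functions of key elements propagate to the
#     process and to every aggregate of higher level
#
# `cyclication_of` members are recycling arrows and take no part in any of
# the rules; they are kept in the graph for export only.

INFER_MODES <- c("set_semantics", "strict_swrl")
KEY_SCOPES <- c("macromolecules_only", "all_chemicals")

# lightweight tibble builder for hot loops
fast_tbl <- function(...) {
  cols <- list(...)
  new_tibble(cols, nrow = length(cols[[1]]))
}

proc_row <- function(graph, id) {
  i <- match(id, graph$processes$id)
  if (is.na(i)) pg_abort(sprintf("unknown process: %s", id),
                         "pg_error_unknown_id")
  graph$processes[i, ]
}

check_aggregated <- function(graph, agg_id) {
  row <- proc_row(graph, agg_id)
  if (row$kind != "aggregated") {
    pg_abort(sprintf("process '%s' is %s, not aggregated", agg_id, row$kind),
             "pg_error_wrong_kind")
  }
  row
}

# authored I/O of elementary processes, optionally expanding catalysts into
# both sides before inference
authored_io <- function(graph, catalysts_as_io = FALSE) {
  p <- graph$processes
  io <- pmap(list(p$inputs, p$outputs, p$catalysts, p$kind),
             function(ins, outs, cats, kind) {
               if (kind != "elementary") return(NULL)
               if (catalysts_as_io && length(cats) > 0) {
                 ins <- unique(c(ins, cats))
                 outs <- unique(c(outs, cats))
               }
               list(inputs = ins, outputs = outs)
             })
  stats::setNames(io, p$id)
}

# resolve the I/O table for the direct sub-processes of one aggregate;
# errors if a nested aggregate has no entry yet
sub_io <- function(graph, subs, io) {
  res <- io[subs]
  unresolved <- subs[map_lgl(res, is.null)]
  if (length(unresolved) > 0) {
    pg_abort(sprintf(
      "sub-process(es) %s have no resolved inputs/outputs yet; run saturate()",
      paste(unresolved, collapse = ", ")), "pg_error_unresolved_io")
  }
  res
}

#' Sub-process ordering within an aggregate
#'
#' Derives the `precedes` relation among the direct sub-processes of one
#' aggregated process: `p1` precedes `p2` when they are distinct and some
#' entity is an output of `p1` and an input of `p2`.
#'
#' @param graph A process graph.
#' @param agg_id Id of an aggregated process.
#' @param io Optional named list `process id -> list(inputs, outputs)` of
#'   resolved participant sets; defaults to the authored I/O of elementary
#'   processes ([saturate()] supplies resolved sets for nested aggregates).
#' @return A tibble with columns `from`, `to`, ordered lexicographically.
#' @export
compute_precedes <- function(graph, agg_id, io = authored_io(graph)) {
  row <- check_aggregated(graph, agg_id)
  subs <- unique(c(row$starts_with[[1]], row$intermediates[[1]],
                   row$ends_with[[1]], row$forks[[1]]))
  sio <- sub_io(graph, subs, io)
  from <- character(0); to <- character(0)
  for (p1 in subs) {
    for (p2 in subs) {
      if (p1 != p2 &&
          length(intersect(sio[[p1]]$outputs, sio[[p2]]$inputs)) > 0) {
        from <- c(from, p1); to <- c(to, p2)
      }
    }
  }
  ord <- order(from, to, method = "radix")
  fast_tbl(from = from[ord], to = to[ord])
}

#' Infer the effective inputs and outputs of an aggregated process
#'
#' Step 1 seeds the aggregate's inputs with the inputs of every
#' `starts_with` and fork sub-process, and its outputs with the outputs of
#' every `ends_with` sub-process. Step 2 then adds, in `set_semantics` mode,
#' every sub-process input that is not produced by a *different*
#' sub-process of the same aggregate (symmetrically for outputs); in
#' `strict_swrl` mode it applies the literal pairwise rule over `precedes`
#' pairs. On linear chains with unique intermediates the two modes agree;
#' on branched topologies the literal rule can over-assert, so
#' `set_semantics` is the normative default.
#'
#' @inheritParams compute_precedes
#' @param mode `"set_semantics"` (default) or `"strict_swrl"`.
#' @return A list with character-vector elements `inputs` and `outputs`
#'   (sorted).
#' @export
infer_io <- function(graph, agg_id, mode = c("set_semantics", "strict_swrl"),
                     io = authored_io(graph)) {
  mode <- match.arg(mode)
  row <- check_aggregated(graph, agg_id)
  starters <- unique(c(row$starts_with[[1]], row$forks[[1]]))
  enders <- row$ends_with[[1]]
  subs <- unique(c(starters, row$intermediates[[1]], enders))
  sio <- sub_io(graph, subs, io)

  seed_in <- unique(unlist(map(sio[starters], "inputs"), use.names = FALSE))
  seed_out <- unique(unlist(map(sio[intersect(enders, subs)], "outputs"),
                            use.names = FALSE))

  if (mode == "set_semantics") {
    step2_in <- unlist(map(subs, function(p) {
      other_out <- unique(unlist(map(sio[setdiff(subs, p)], "outputs"),
                                 use.names = FALSE))
      setdiff(sio[[p]]$inputs, other_out)
    }), use.names = FALSE)
    step2_out <- unlist(map(subs, function(p) {
      other_in <- unique(unlist(map(sio[setdiff(subs, p)], "inputs"),
                                use.names = FALSE))
      setdiff(sio[[p]]$outputs, other_in)
    }), use.names = FALSE)
  } else {
    prec <- compute_precedes(graph, agg_id, io = io)
    step2_in <- character(0)
    step2_out <- character(0)
    if (nrow(prec) > 0) {
      for (k in seq_len(nrow(prec))) {
        o1 <- sio[[prec$from[k]]]$outputs
        i2 <- sio[[prec$to[k]]]$inputs
        witnesses <- intersect(o1, i2)
        # chem_j must differ from some shared intermediate chem_i
        step2_in <- c(step2_in,
                      i2[map_lgl(i2, ~ length(setdiff(witnesses, .x)) > 0 ||
                                   !.x %in% witnesses)])
        step2_out <- c(step2_out,
                       o1[map_lgl(o1, ~ length(setdiff(witnesses, .x)) > 0 ||
                                    !.x %in% witnesses)])
      }
    }
  }
  list(inputs = sort(unique(c(seed_in, step2_in))),
       outputs = sort(unique(c(seed_out, step2_out))))
}

#' Infer the consumed intermediates of an aggregated process
#'
#' An entity is consumed when it is an output of one sub-process and an
#' input of a different sub-process, with two guards: the producer must not
#' be an `ends_with` member and the consumer must not be a `starts_with` or
#' fork member. The guards keep recycled entities (output of the ender fed
#' back to the starter) out of the consumed set.
#'
#' @inheritParams compute_precedes
#' @return Sorted character vector of consumed entity ids.
#' @export
infer_consumed <- function(graph, agg_id, io = authored_io(graph)) {
  row <- check_aggregated(graph, agg_id)
  starters <- unique(c(row$starts_with[[1]], row$forks[[1]]))
  enders <- row$ends_with[[1]]
  subs <- unique(c(starters, row$intermediates[[1]], enders))
  sio <- sub_io(graph, subs, io)
  consumed <- character(0)
  for (p1 in setdiff(subs, enders)) {
    for (p2 in setdiff(subs, starters)) {
      if (p1 != p2) {
        consumed <- c(consumed, intersect(sio[[p1]]$outputs, sio[[p2]]$inputs))
      }
    }
  }
  sort(unique(consumed))
}

#' Key elements of every process
#'
#' A key element is an entity appearing both as input and as output of the
#' same process — a reactant required but unmodified, typically the enzyme
#' of an enzymatic step. Aggregated processes are scanned over their
#' resolved (inferred) participant sets.
#'
#' @inheritParams compute_precedes
#' @param scope `"macromolecules_only"` (default, as in the rule's
#'   "IF m is a macromolecule") or `"all_chemicals"`.
#' @return A tibble with columns `process_id`, `entity_id`. Aggregates with
#'   unresolved I/O (when `io` lacks them) are skipped.
#' @seealso [key_element_of()] for the inverse view.
#' @export
infer_key_elements <- function(graph,
                               scope = c("macromolecules_only",
                                         "all_chemicals"),
                               io = authored_io(graph)) {
  scope <- match.arg(scope)
  kinds <- if (scope == "macromolecules_only") "macromolecule" else
    CHEMICAL_KINDS
  ekind <- stats::setNames(graph$entities$kind, graph$entities$id)
  pids <- character(0); eids <- character(0)
  for (pid in graph$processes$id) {
    pio <- io[[pid]]
    if (is.null(pio)) next
    ke <- intersect(pio$inputs, pio$outputs)
    ke <- ke[ke %in% names(ekind) & ekind[ke] %in% kinds]
    if (length(ke) > 0) {
      pids <- c(pids, rep(pid, length(ke)))
      eids <- c(eids, sort(ke))
    }
  }
  ord <- order(pids, eids, method = "radix")
  fast_tbl(process_id = pids[ord], entity_id = eids[ord])
}

#' Processes for which an entity is a key element
#'
#' @param key_elements A tibble as returned by [infer_key_elements()] or
#'   the `key_elements` component of an [saturate()] bundle.
#' @param entity_id Entity id.
#' @return Character vector of process ids.
#' @export
key_element_of <- function(key_elements, entity_id) {
  sort(unique(key_elements$process_id[key_elements$entity_id == entity_id]))
}

#' Molecular functions affecting processes
#'
#' For each key element of a process and each molecular-function label the
#' entity carries, the function affects that process and every aggregated
#' process of higher level (via the transitive `has_part` closure).
#'
#' @param graph A process graph.
#' @param bundle An [saturate()] bundle (supplies `key_elements` and
#'   `has_part`).
#' @return A tibble with columns `function_label`, `process_id`.
#' @export
infer_affects <- function(graph, bundle) {
  ke <- bundle$key_elements
  if (nrow(ke) == 0) {
    return(tibble(function_label = character(), process_id = character()))
  }
  efun <- stats::setNames(graph$entities$functions, graph$entities$id)
  hp <- bundle$has_part
  fls <- character(0); pls <- character(0)
  for (k in seq_len(nrow(ke))) {
    fns <- efun[[ke$entity_id[k]]] %||% character(0)
    if (length(fns) == 0) next
    p <- ke$process_id[k]
    targets <- c(p, hp$process_id[hp$part_id == p])
    for (f in fns) {
      fls <- c(fls, rep(f, length(targets)))
      pls <- c(pls, targets)
    }
  }
  keep_ix <- !duplicated(paste(fls, pls, sep = "\r"))
  fls <- fls[keep_ix]; pls <- pls[keep_ix]
  ord <- order(fls, pls, method = "radix")
  fast_tbl(function_label = fls[ord], process_id = pls[ord])
}

#' Saturate a process graph
#'
#' Orders the aggregated processes bottom-up along the composition DAG and
#' resolves, for each, the `precedes` pairs, effective inputs/outputs and
#' consumed intermediates; then computes the transitive `has_part` closure,
#' the key elements of every process and the `affects` map. Deterministic
#' for a fixed graph and mode.
#'
#' @param graph A validated process graph (validation errors abort;
#'   warnings are tolerated).
#' @param mode Inference mode, see [infer_io()].
#' @param scope Key-element scope, see [infer_key_elements()].
#' @param catalysts_as_io Expand each elementary catalyst into both an
#'   input and an output before inference (default `FALSE`: catalysts are
#'   stored but take no part in the rules).
#' @return An `inference_bundle`: a list of tibbles `io` (`process_id`,
#'   `direction`, `entity_id` for every aggregate), `precedes` (`agg_id`,
#'   `from`, `to`), `consumed` (`agg_id`, `entity_id`), `key_elements`,
#'   `affects`, `has_part` (`process_id`, `part_id`, transitive), plus the
#'   resolved I/O table and the modes used.
#' @examples
#' g <- worked_example_30s()
#' b <- saturate(g)
#' b$consumed
#' @export
saturate <- function(graph, mode = c("set_semantics", "strict_swrl"),
                     scope = c("macromolecules_only", "all_chemicals"),
                     catalysts_as_io = FALSE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  assert_valid(graph)

  p <- graph$processes
  subs <- subprocess_sets(graph)
  aggs <- p$id[p$kind == "aggregated"]
  io <- authored_io(graph, catalysts_as_io = catalysts_as_io)

  # bottom-up topological order over the composition DAG
  pending <- aggs
  order <- character(0)
  while (length(pending) > 0) {
    ready <- pending[map_lgl(pending, function(a) {
      !any(intersect(subs[[a]], aggs) %in% pending)
    })]
    if (length(ready) == 0) {
      pg_abort("cyclic decomposition among aggregated processes",
               "pg_error_cycle")
    }
    order <- c(order, sort(ready))
    pending <- setdiff(pending, ready)
  }

  io_agg <- character(0); io_dir <- character(0); io_ent <- character(0)
  pr_agg <- character(0); pr_from <- character(0); pr_to <- character(0)
  co_agg <- character(0); co_ent <- character(0)
  for (a in order) {
    res <- infer_io(graph, a, mode = mode, io = io)
    io[[a]] <- res
    prec <- compute_precedes(graph, a, io = io)
    cons <- infer_consumed(graph, a, io = io)
    nio <- length(res$inputs) + length(res$outputs)
    io_agg <- c(io_agg, rep(a, nio))
    io_dir <- c(io_dir, rep(c("input", "output"),
                            c(length(res$inputs), length(res$outputs))))
    io_ent <- c(io_ent, res$inputs, res$outputs)
    pr_agg <- c(pr_agg, rep(a, nrow(prec)))
    pr_from <- c(pr_from, prec$from); pr_to <- c(pr_to, prec$to)
    co_agg <- c(co_agg, rep(a, length(cons)))
    co_ent <- c(co_ent, cons)
  }

  # transitive has_part closure (has_subprocess only)
  closure <- list()
  for (a in order) {
    parts <- subs[[a]]
    parts <- unique(c(parts, unlist(closure[intersect(parts, names(closure))],
                                    use.names = FALSE)))
    closure[[a]] <- parts
  }
  hp_id <- character(0); hp_part <- character(0)
  for (a in sort(names(closure))) {
    hp_id <- c(hp_id, rep(a, length(closure[[a]])))
    hp_part <- c(hp_part, sort(closure[[a]]))
  }

  # canonical row order regardless of the saturation order
  oi <- order(io_agg, io_dir, io_ent, method = "radix")
  op <- order(pr_agg, pr_from, pr_to, method = "radix")
  oc <- order(co_agg, co_ent, method = "radix")
  bundle <- structure(list(
    io = fast_tbl(process_id = io_agg[oi], direction = io_dir[oi],
                  entity_id = io_ent[oi]),
    precedes = fast_tbl(agg_id = pr_agg[op], from = pr_from[op],
                        to = pr_to[op]),
    consumed = fast_tbl(agg_id = co_agg[oc], entity_id = co_ent[oc]),
    has_part = fast_tbl(process_id = hp_id, part_id = hp_part),
    resolved_io = io,
    mode = mode, scope = scope
  ), class = "inference_bundle")

  bundle$key_elements <- infer_key_elements(graph, scope = scope, io = io)
  bundle$affects <- infer_affects(graph, bundle)
  bundle
}

#' Resolved inputs/outputs of one process from a bundle
#'
#' @param bundle An inference bundle.
#' @param id Process id.
#' @return List with `inputs` and `outputs` character vectors.
#' @export
aggregate_io <- function(bundle, id) {
  res <- bundle$resolved_io[[id]]
  if (is.null(res)) {
    pg_abort(sprintf("no resolved I/O for '%s'", id), "pg_error_unknown_id")
  }
  res
}

#' @export
print.inference_bundle <- function(x, ...) {
  cat(sprintf(
    "<inference_bundle mode=%s> %d aggregate(s): %d precedes pair(s), %d consumed, %d key element(s), %d affects fact(s)\n",
    x$mode, length(unique(x$io$process_id)), nrow(x$precedes),
    nrow(x$consumed), nrow(x$key_elements), nrow(x$affects)))
  invisible(x)
}
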