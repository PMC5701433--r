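# Typed in-memory representation of a multi-scale process knowledge graph.
#
# Entities and processes are stored as tibbles with list-columns for the
# multi-valued fields; the class hierarchy (is_a) is an edge tibble. Abstract
# superclasses ("chemical entity", "primary transcript", ...) may appear as
# is_a parents without a full record: they carry only an id and an optional
# label in the `classes` tibble, or are implicitly declared by an is_a edge.

ENTITY_KINDS <- c("small_molecule", "macromolecule", "sequence_feature",
                  "cellular_component")
PROCESS_KINDS <- c("elementary", "aggregated")
CHEMICAL_KINDS <- c("small_molecule", "macromolecule")

chr_list <- function(x) {
  if (is.null(x)) return(list(character(0)))
  if (is.list(x)) return(lapply(x, function(v) unique(as.character(v))))
  list(unique(as.character(x)))
}

empty_entity_tbl <- function() {
  tibble(
    id = character(), label = character(), kind = character(),
    xrefs = list(), located_in = list(), binds_to = list(),
    is_motif_of = list(), has_template = list(), functions = list()
  )
}

empty_process_tbl <- function() {
  tibble(
    id = character(), label = character(), kind = character(), xrefs = list(),
    inputs = list(), outputs = list(), catalysts = list(),
    starts_with = list(), ends_with = list(), intermediates = list(),
    forks = list(), cyclication_of = list(),
    native = logical(), declared_categories = list()
  )
}

#' Create an entity record
#'
#' One row of the entity table of a process graph: a chemical entity (small
#' molecule, macromolecule or complex), a sequence feature (motif), or a
#' cellular component (compartment or template polymer).
#'
#' @param id Unique identifier string.
#' @param label Human-readable name; defaults to `id`.
#' @param kind One of `"small_molecule"`, `"macromolecule"`,
#'   `"sequence_feature"`, `"cellular_component"`.
#' @param xrefs Character vector of external database cross-references
#'   (e.g. `"K02520"`, `"SO_0000185"`).
#' @param located_in Entity ids of compartments or sequence features the
#'   entity is localized in.
#' @param binds_to Entity ids of sequence features the entity is bound to.
#'   Every `binds_to` edge also counts as a `located_in` edge during
#'   reasoning (sub-property semantics).
#' @param is_motif_of Entity ids of the larger feature or polymer carrying
#'   this motif (only meaningful for sequence features).
#' @param has_template Entity ids of sequences that recruit this entity.
#' @param functions Molecular-function labels (free text or GO-MF xrefs).
#' @return A one-row tibble suitable for [add_entity()] or [process_graph()].
#' @examples
#' entity_record("if3", "translation initiation factor IF-3",
#'               "macromolecule", xrefs = "K02520")
#' @export
entity_record <- function(id, label = id, kind, xrefs = character(),
                          located_in = character(), binds_to = character(),
                          is_motif_of = character(),
                          has_template = character(),
                          functions = character()) {
  kind <- match.arg(kind, ENTITY_KINDS)
  tibble(
    id = as.character(id), label = as.character(label), kind = kind,
    xrefs = chr_list(xrefs), located_in = chr_list(located_in),
    binds_to = chr_list(binds_to), is_motif_of = chr_list(is_motif_of),
    has_template = chr_list(has_template), functions = chr_list(functions)
  )
}

#' Create a process record
#'
#' One row of the process table. An elementary process is defined by its
#' participants (inputs/outputs); an aggregated process is defined only by
#' the composition of its sub-processes (`starts_with`, `intermediates`,
#' `ends_with`, `forks`) and its effective participants are inferred with
#' [saturate()].
#'
#' @param id,label,xrefs As in [entity_record()].
#' @param kind `"elementary"` or `"aggregated"`.
#' @param inputs,outputs,catalysts Entity ids (elementary processes only).
#' @param starts_with,ends_with,intermediates,forks,cyclication_of Process
#'   ids composing an aggregated process. `cyclication_of` marks recycling
#'   sub-processes that are excluded from inference.
#' @param native Logical flag used by polymer-production classification.
#' @param declared_categories Curator-declared category tags (e.g.
#'   `"release_process"`, which has no defining axiom).
#' @return A one-row tibble.
#' @examples
#' process_record("e1", "free 30S fixation", "elementary",
#'                inputs = c("if3", "ribosome_30S"),
#'                outputs = "complex_30S_IF3")
#' @export
process_record <- function(id, label = id, kind, xrefs = character(),
                           inputs = character(), outputs = character(),
                           catalysts = character(),
                           starts_with = character(), ends_with = character(),
                           intermediates = character(), forks = character(),
                           cyclication_of = character(), native = TRUE,
                           declared_categories = character()) {
  kind <- match.arg(kind, PROCESS_KINDS)
  tibble(
    id = as.character(id), label = as.character(label), kind = kind,
    xrefs = chr_list(xrefs),
    inputs = chr_list(inputs), outputs = chr_list(outputs),
    catalysts = chr_list(catalysts),
    starts_with = chr_list(starts_with), ends_with = chr_list(ends_with),
    intermediates = chr_list(intermediates), forks = chr_list(forks),
    cyclication_of = chr_list(cyclication_of),
    native = isTRUE(native), declared_categories = chr_list(declared_categories)
  )
}

complete_records <- function(df, template, what) {
  df <- as_tibble(df)
  extra <- setdiff(names(df), names(template))
  if (length(extra) > 0) {
    pg_abort(sprintf("unknown %s field(s): %s", what,
                     paste(extra, collapse = ", ")), "pg_error_schema")
  }
  for (col in names(template)) {
    if (!col %in% names(df)) {
      df[[col]] <- if (is.list(template[[col]])) {
        rep(list(character(0)), nrow(df))
      } else if (is.logical(template[[col]])) {
        rep(TRUE, nrow(df))
      } else {
        rep(NA_character_, nrow(df))
      }
    } else if (is.list(template[[col]]) && !is.list(df[[col]])) {
      df[[col]] <- lapply(df[[col]], function(v) {
        if (length(v) == 1 && is.na(v)) character(0) else as.character(v)
      })
    }
  }
  df[names(template)]
}

#' Construct a process knowledge graph
#'
#' @param entities Tibble of entity records (see [entity_record()]).
#' @param processes Tibble of process records (see [process_record()]).
#' @param is_a Tibble or data frame with columns `child`, `parent` giving
#'   the class hierarchy; parents may be abstract class names without a
#'   record. The relation must form a DAG (multiple parents allowed).
#' @param classes Optional tibble with columns `id`, `label` declaring
#'   abstract named classes explicitly.
#' @param meta Named list of provenance annotations (e.g. `iri_prefix`).
#' @return A `process_graph` object.
#' @seealso [add_entity()], [validate_graph()], [saturate()]
#' @export
process_graph <- function(entities = NULL, processes = NULL, is_a = NULL,
                          classes = NULL, meta = list()) {
  ent <- if (is.null(entities)) empty_entity_tbl() else
    complete_records(entities, empty_entity_tbl(), "entity")
  prc <- if (is.null(processes)) empty_process_tbl() else
    complete_records(processes, empty_process_tbl(), "process")
  isa <- if (is.null(is_a)) tibble(child = character(), parent = character())
         else as_tibble(is_a)[c("child", "parent")]
  cls <- if (is.null(classes)) tibble(id = character(), label = character())
         else as_tibble(classes)[c("id", "label")]
  dup <- unique(c(ent$id[duplicated(ent$id)], prc$id[duplicated(prc$id)],
                  intersect(ent$id, prc$id)))
  if (length(dup) > 0) {
    pg_abort(sprintf("duplicate identifier(s): %s", paste(dup, collapse = ", ")),
             "pg_error_duplicate_id")
  }
  structure(
    list(entities = ent, processes = prc, is_a = isa, classes = cls,
         meta = meta),
    class = "process_graph"
  )
}

#' @export
print.process_graph <- function(x, ...) {
  cat(sprintf(
    "<process_graph> %d entities, %d processes (%d elementary, %d aggregated), %d is_a edges\n",
    nrow(x$entities), nrow(x$processes),
    sum(x$processes$kind == "elementary"),
    sum(x$processes$kind == "aggregated"), nrow(x$is_a)))
  invisible(x)
}

graph_ids <- function(graph) {
  unique(c(graph$entities$id, graph$processes$id, graph$classes$id,
           graph$is_a$child, graph$is_a$parent))
}

#' Add records to a graph
#'
#' `add_entity()` and `add_process()` append records; referential and axiom
#' checks are deferred to [validate_graph()]. Adding an id that is already
#' present raises an identity-collision error.
#'
#' @param graph A [process_graph()].
#' @param record A one-or-more-row tibble from [entity_record()] /
#'   [process_record()] (or any data frame with a compatible subset of
#'   columns).
#' @return The updated `process_graph`.
#' @export
add_entity <- function(graph, record) {
  stopifnot(inherits(graph, "process_graph"))
  rec <- complete_records(record, empty_entity_tbl(), "entity")
  clash <- intersect(rec$id, c(graph$entities$id, graph$processes$id))
  if (length(clash) > 0 || anyDuplicated(rec$id) > 0) {
    pg_abort(sprintf("identifier already present: %s",
                     paste(unique(c(clash, rec$id[duplicated(rec$id)])),
                           collapse = ", ")),
             "pg_error_duplicate_id")
  }
  graph$entities <- bind_rows(graph$entities, rec)
  graph
}

#' @rdname add_entity
#' @export
add_process <- function(graph, record) {
  stopifnot(inherits(graph, "process_graph"))
  rec <- complete_records(record, empty_process_tbl(), "process")
  clash <- intersect(rec$id, c(graph$entities$id, graph$processes$id))
  if (length(clash) > 0 || anyDuplicated(rec$id) > 0) {
    pg_abort(sprintf("identifier already present: %s",
                     paste(unique(c(clash, rec$id[duplicated(rec$id)])),
                           collapse = ", ")),
             "pg_error_duplicate_id")
  }
  graph$processes <- bind_rows(graph$processes, rec)
  graph
}

#' Add is_a edges
#'
#' @param graph A process graph.
#' @param child,parent Character vectors (recycled) of class ids.
#' @return The updated graph.
#' @export
add_is_a <- function(graph, child, parent) {
  graph$is_a <- distinct(bind_rows(graph$is_a, tibble(child = child,
                                                      parent = parent)))
  graph
}

# parent adjacency as a named list child -> character vector of parents
isa_parents <- function(graph) {
  if (nrow(graph$is_a) == 0) return(list())
  split(graph$is_a$parent, graph$is_a$child)
}

#' Ancestors in the class hierarchy
#'
#' Reflexive-transitive closure of the `is_a` relation from `id`, used by
#' every SOME/ONLY class-membership check.
#'
#' @param graph A process graph.
#' @param id A declared identifier (record or abstract class).
#' @return Character vector of ancestor ids, including `id` itself.
#' @export
ancestors <- function(graph, id) {
  if (!id %in% graph_ids(graph)) {
    pg_abort(sprintf("unknown identifier: %s", id), "pg_error_unknown_id")
  }
  up <- isa_parents(graph)
  seen <- character(0)
  frontier <- id
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(up[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}

# named list of process composition (inference view: cyclication_of excluded)
subprocess_sets <- function(graph) {
  p <- graph$processes
  stats::setNames(
    pmap(list(p$starts_with, p$intermediates, p$ends_with, p$forks),
         function(s, i, e, f) unique(c(s, i, e, f))),
    p$id)
}

# detect a cycle in adjacency list (named list id -> children); returns
# character vector of ids on some cycle, or character(0)
find_cycle_nodes <- function(adj, nodes) {
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  bad <- character(0)
  visit <- function(v) {
    if (!v %in% nodes) return(invisible(NULL))
    if (state[[v]] == 1L) { bad <<- c(bad, v); return(invisible(NULL)) }
    if (state[[v]] == 2L) return(invisible(NULL))
    state[[v]] <<- 1L
    for (w in adj[[v]] %||% character(0)) visit(w)
    state[[v]] <<- 2L
    invisible(NULL)
  }
  for (v in nodes) visit(v)
  unique(bad)
}

violation <- function(rule, subject, severity, message) {
  tibble(rule = rule, subject = subject, severity = severity,
         message = message)
}

#' Validate a process graph
#'
#' Checks the structural axioms of the representation: unique non-empty
#' labels, resolvable edge targets, kind constraints on `binds_to` /
#' `is_motif_of` / `located_in`, the elementary-process participant axiom
#' (at least one chemical input and output; participants only chemicals or
#' sequence features), the aggregated-process composition axiom (at least
#' one starter and one ender, role lists disjoint), and acyclicity of both
#' `is_a` and the composition relation.
#'
#' Violations are returned, never thrown. A degenerate aggregate whose
#' single sub-process both starts and ends it, and an aggregate with more
#' than one `ends_with` member, are reported as warnings rather than errors.
#'
#' @param graph A process graph.
#' @return A tibble with columns `rule`, `subject`, `severity`, `message`;
#'   zero rows iff the graph is clean.
#' @export
validate_graph <- function(graph) {
  out <- list()
  ent <- graph$entities
  prc <- graph$processes
  known <- graph_ids(graph)
  ekind <- stats::setNames(ent$kind, ent$id)

  bad_label <- c(ent$id[is.na(ent$label) | ent$label == ""],
                 prc$id[is.na(prc$label) | prc$label == ""])
  for (id in bad_label) {
    out[[length(out) + 1L]] <- violation("label_nonempty", id, "error",
                                         "label is missing or empty")
  }

  check_refs <- function(id, targets, field, allowed_kinds = NULL) {
    for (t in targets) {
      if (!t %in% known) {
        out[[length(out) + 1L]] <<- violation(
          "dangling_reference", id, "error",
          sprintf("%s target '%s' is not declared", field, t))
      } else if (!is.null(allowed_kinds) && t %in% names(ekind) &&
                 !ekind[[t]] %in% allowed_kinds) {
        out[[length(out) + 1L]] <<- violation(
          "target_kind", id, "error",
          sprintf("%s target '%s' has kind %s (expected %s)", field, t,
                  ekind[[t]], paste(allowed_kinds, collapse = "/")))
      }
    }
  }

  for (i in seq_len(nrow(ent))) {
    id <- ent$id[i]
    check_refs(id, ent$located_in[[i]], "located_in",
               c("cellular_component", "sequence_feature"))
    check_refs(id, ent$binds_to[[i]], "binds_to", "sequence_feature")
    check_refs(id, ent$is_motif_of[[i]], "is_motif_of",
               c("sequence_feature", "cellular_component"))
    check_refs(id, ent$has_template[[i]], "has_template")
    if (length(ent$is_motif_of[[i]]) > 0 && ent$kind[i] != "sequence_feature") {
      out[[length(out) + 1L]] <- violation(
        "motif_kind", id, "error",
        "is_motif_of is only allowed for sequence features")
    }
  }

  proc_ids <- prc$id
  for (i in seq_len(nrow(prc))) {
    id <- prc$id[i]
    participants <- unique(c(prc$inputs[[i]], prc$outputs[[i]],
                             prc$catalysts[[i]]))
    for (t in participants) {
      if (!t %in% known) {
        out[[length(out) + 1L]] <- violation(
          "dangling_reference", id, "error",
          sprintf("participant '%s' is not declared", t))
      }
    }
    comp <- list(starts_with = prc$starts_with[[i]],
                 ends_with = prc$ends_with[[i]],
                 intermediates = prc$intermediates[[i]],
                 forks = prc$forks[[i]],
                 cyclication_of = prc$cyclication_of[[i]])
    for (field in names(comp)) {
      for (t in comp[[field]]) {
        if (!t %in% proc_ids) {
          out[[length(out) + 1L]] <- violation(
            "dangling_reference", id, "error",
            sprintf("%s member '%s' is not a declared process", field, t))
        }
      }
    }
    if (id %in% unlist(comp, use.names = FALSE)) {
      out[[length(out) + 1L]] <- violation(
        "self_composition", id, "error",
        "process appears in its own composition lists")
    }

    if (prc$kind[i] == "elementary") {
      if (any(lengths(comp[1:4]) > 0)) {
        out[[length(out) + 1L]] <- violation(
          "elementary_no_subprocess", id, "error",
          "elementary process must not have composition edges")
      }
      pk <- ekind[intersect(participants, names(ekind))]
      if (!any(ekind[intersect(prc$inputs[[i]], names(ekind))] %in%
                 CHEMICAL_KINDS)) {
        out[[length(out) + 1L]] <- violation(
          "elementary_some_chemical_input", id, "error",
          "elementary process needs at least one chemical-entity input")
      }
      if (!any(ekind[intersect(prc$outputs[[i]], names(ekind))] %in%
                 CHEMICAL_KINDS)) {
        out[[length(out) + 1L]] <- violation(
          "elementary_some_chemical_output", id, "error",
          "elementary process needs at least one chemical-entity output")
      }
      off <- names(pk)[!pk %in% c(CHEMICAL_KINDS, "sequence_feature")]
      for (t in off) {
        out[[length(out) + 1L]] <- violation(
          "elementary_only_chemical_or_feature", id, "error",
          sprintf("participant '%s' is a %s; only chemical entities and sequence features are allowed",
                  t, ekind[[t]]))
      }
    } else {  # aggregated
      if (length(prc$inputs[[i]]) + length(prc$outputs[[i]]) > 0) {
        out[[length(out) + 1L]] <- violation(
          "aggregate_authored_io", id, "error",
          "aggregated process must not author inputs/outputs (they are inferred)")
      }
      if (length(comp$starts_with) + length(comp$forks) == 0) {
        out[[length(out) + 1L]] <- violation(
          "aggregate_has_starter", id, "error",
          "aggregated process needs at least one starts_with or fork member")
      }
      if (length(comp$ends_with) == 0) {
        out[[length(out) + 1L]] <- violation(
          "aggregate_has_ender", id, "error",
          "aggregated process needs at least one ends_with member")
      }
      if (length(comp$ends_with) > 1) {
        out[[length(out) + 1L]] <- violation(
          "aggregate_single_ender", id, "warning",
          "aggregated process has more than one ends_with member")
      }
      roles <- comp[c("starts_with", "ends_with", "intermediates", "forks")]
      all_members <- unlist(roles, use.names = FALSE)
      overlap <- unique(all_members[duplicated(all_members)])
      if (length(overlap) > 0) {
        degenerate <- length(unique(all_members)) == 1 &&
          identical(sort(names(keep(roles, ~ length(.x) > 0))),
                    c("ends_with", "starts_with"))
        out[[length(out) + 1L]] <- violation(
          "subprocess_roles_disjoint", id,
          if (degenerate) "warning" else "error",
          sprintf("member(s) %s appear in several composition roles",
                  paste(overlap, collapse = ", ")))
      }
    }
  }

  cyc <- find_cycle_nodes(isa_parents(graph), unique(graph$is_a$child))
  for (id in cyc) {
    out[[length(out) + 1L]] <- violation("is_a_acyclic", id, "error",
                                         "is_a hierarchy contains a cycle")
  }
  sub_adj <- subprocess_sets(graph)
  cyc2 <- find_cycle_nodes(sub_adj, proc_ids)
  for (id in cyc2) {
    out[[length(out) + 1L]] <- violation("composition_acyclic", id, "error",
                                         "has_subprocess relation contains a cycle")
  }

  if (length(out) == 0) {
    violation(character(0), character(0), character(0), character(0))
  } else {
    arrange(bind_rows(out), .data$rule, .data$subject)
  }
}

# stop unless the graph validates without errors (warnings allowed)
assert_valid <- function(graph) {
  rep <- validate_graph(graph)
  if (any(rep$severity == "error")) {
    pg_abort(sprintf("graph fails validation (%d error(s), e.g. %s: %s)",
                     sum(rep$severity == "error"),
                     rep$rule[rep$severity == "error"][1],
                     rep$message[rep$severity == "error"][1]),
             "pg_error_invalid_graph")
  }
  invisible(graph)
}

#' Mint sequential identifiers
#'
#' @param n Number of ids.
#' @param prefix Id prefix; ids follow the pattern `<prefix>_%08d`.
#' @param start First counter value.
#' @return Character vector of ids.
#' @export
mint_ids <- function(n, prefix = "PG", start = 1L) {
  sprintf("%s_%08d", prefix, seq.int(start, length.out = n))
}

#' Effective localization targets
#'
#' `binds_to` is a sub-property of `located_in`: every binding edge counts
#' as a localization during reasoning. This accessor returns the union.
#'
#' @param graph A process graph.
#' @param id Entity id.
#' @return Character vector of localization target ids.
#' @export
located_in_targets <- function(graph, id) {
  i <- match(id, graph$entities$id)
  if (is.na(i)) pg_abort(sprintf("unknown entity: %s", id), "pg_error_unknown_id")
  unique(c(graph$entities$located_in[[i]], graph$entities$binds_to[[i]]))
}
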