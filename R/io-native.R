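# Native curation format: JSON (canonical) or YAML (accepted on input).
#
# Top-level sections: meta{}, classes[], entities[], processes[], is_a[],
# and optionally inferred{} and classification{} on output. Field names
# mirror the in-memory record types one-to-one. Dumps are canonical
# (records and set-valued fields sorted lexicographically) so re-export is
# byte-stable.

ENTITY_LIST_FIELDS <- c("xrefs", "located_in", "binds_to", "is_motif_of",
                        "has_template", "functions")
PROCESS_LIST_FIELDS <- c("xrefs", "inputs", "outputs", "catalysts",
                         "starts_with", "ends_with", "intermediates",
                         "forks", "cyclication_of", "declared_categories")

read_document <- function(x) {
  is_path <- length(x) == 1 && !grepl("\n", x) && file.exists(x)
  txt <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "\n") else
    paste(x, collapse = "\n")
  json_like <- grepl("^\\s*\\{", txt)
  doc <- tryCatch(
    if (json_like) jsonlite::fromJSON(txt, simplifyVector = FALSE)
    else yaml::yaml.load(txt),
    error = function(e) {
      pg_abort(sprintf("cannot parse document: %s", conditionMessage(e)),
               "pg_error_parse")
    })
  if (!is.list(doc)) {
    pg_abort("document root must be a mapping", "pg_error_schema")
  }
  doc
}

schema_fail <- function(problems) {
  pg_abort(paste0("document violates the native schema:\n",
                  paste(" ", problems, collapse = "\n")),
           "pg_error_schema", problems = problems)
}

str_at <- function(x, ptr, problems, default = NA_character_) {
  if (is.null(x)) return(list(value = default, problems = problems))
  if (!is.character(x) && !is.numeric(x) || length(x) != 1) {
    problems <- c(problems, sprintf("%s: expected a string", ptr))
    return(list(value = default, problems = problems))
  }
  list(value = as.character(x), problems = problems)
}

arr_at <- function(x, ptr, problems) {
  if (is.null(x)) return(list(value = character(0), problems = problems))
  v <- unlist(x, use.names = FALSE)
  if (length(v) > 0 && !is.character(v) && !is.numeric(v)) {
    problems <- c(problems, sprintf("%s: expected an array of strings", ptr))
    v <- character(0)
  }
  list(value = as.character(v %||% character(0)), problems = problems)
}

#' Load a process graph from the native format
#'
#' @param x A file path (JSON or YAML) or the document text itself.
#' @return A `process_graph`. Schema violations abort with
#'   JSON-pointer-style locations; edges referencing undeclared ids abort
#'   with a dangling-reference error.
#' @export
load_native <- function(x) {
  doc <- read_document(x)
  problems <- character(0)
  known_sections <- c("meta", "classes", "entities", "processes", "is_a",
                      "inferred", "classification")
  for (s in setdiff(names(doc), known_sections)) {
    problems <- c(problems, sprintf("/%s: unknown section", s))
  }

  ents <- list()
  for (i in seq_along(doc$entities %||% list())) {
    e <- doc$entities[[i]]
    ptr <- sprintf("/entities/%d", i - 1L)
    r <- str_at(e$id, paste0(ptr, "/id"), problems); problems <- r$problems
    id <- r$value
    if (is.na(id)) { problems <- c(problems, sprintf("%s/id: required", ptr)); next }
    r <- str_at(e$kind, paste0(ptr, "/kind"), problems); problems <- r$problems
    kind <- r$value
    if (is.na(kind) || !kind %in% ENTITY_KINDS) {
      problems <- c(problems, sprintf("%s/kind: must be one of %s", ptr,
                                      paste(ENTITY_KINDS, collapse = "/")))
      next
    }
    r <- str_at(e$label, paste0(ptr, "/label"), problems, default = id)
    problems <- r$problems
    lists <- list()
    for (f in ENTITY_LIST_FIELDS) {
      a <- arr_at(e[[f]], paste0(ptr, "/", f), problems)
      problems <- a$problems
      lists[[f]] <- a$value
    }
    for (f in setdiff(names(e), c("id", "label", "kind", ENTITY_LIST_FIELDS))) {
      problems <- c(problems, sprintf("%s/%s: unknown field", ptr, f))
    }
    ents[[length(ents) + 1L]] <- entity_record(
      id, r$value, kind, xrefs = lists$xrefs, located_in = lists$located_in,
      binds_to = lists$binds_to, is_motif_of = lists$is_motif_of,
      has_template = lists$has_template, functions = lists$functions)
  }

  prcs <- list()
  for (i in seq_along(doc$processes %||% list())) {
    p <- doc$processes[[i]]
    ptr <- sprintf("/processes/%d", i - 1L)
    r <- str_at(p$id, paste0(ptr, "/id"), problems); problems <- r$problems
    id <- r$value
    if (is.na(id)) { problems <- c(problems, sprintf("%s/id: required", ptr)); next }
    r <- str_at(p$kind, paste0(ptr, "/kind"), problems); problems <- r$problems
    kind <- r$value
    if (is.na(kind) || !kind %in% PROCESS_KINDS) {
      problems <- c(problems, sprintf("%s/kind: must be one of %s", ptr,
                                      paste(PROCESS_KINDS, collapse = "/")))
      next
    }
    rl <- str_at(p$label, paste0(ptr, "/label"), problems, default = id)
    problems <- rl$problems
    lists <- list()
    for (f in PROCESS_LIST_FIELDS) {
      a <- arr_at(p[[f]], paste0(ptr, "/", f), problems)
      problems <- a$problems
      lists[[f]] <- a$value
    }
    native <- p$native %||% TRUE
    if (!is.logical(native) || length(native) != 1) {
      problems <- c(problems, sprintf("%s/native: expected a boolean", ptr))
      native <- TRUE
    }
    for (f in setdiff(names(p),
                      c("id", "label", "kind", "native", PROCESS_LIST_FIELDS))) {
      problems <- c(problems, sprintf("%s/%s: unknown field", ptr, f))
    }
    prcs[[length(prcs) + 1L]] <- process_record(
      id, rl$value, kind, xrefs = lists$xrefs, inputs = lists$inputs,
      outputs = lists$outputs, catalysts = lists$catalysts,
      starts_with = lists$starts_with, ends_with = lists$ends_with,
      intermediates = lists$intermediates, forks = lists$forks,
      cyclication_of = lists$cyclication_of, native = native,
      declared_categories = lists$declared_categories)
  }

  isa <- list()
  for (i in seq_along(doc$is_a %||% list())) {
    e <- doc$is_a[[i]]
    ptr <- sprintf("/is_a/%d", i - 1L)
    if (!is.list(e) || is.null(e$child) || is.null(e$parent)) {
      problems <- c(problems, sprintf("%s: expected {child, parent}", ptr))
      next
    }
    isa[[length(isa) + 1L]] <- tibble(child = as.character(e$child),
                                      parent = as.character(e$parent))
  }

  cls <- list()
  for (i in seq_along(doc$classes %||% list())) {
    e <- doc$classes[[i]]
    ptr <- sprintf("/classes/%d", i - 1L)
    if (!is.list(e) || is.null(e$id)) {
      problems <- c(problems, sprintf("%s: expected {id, label}", ptr))
      next
    }
    cls[[length(cls) + 1L]] <- tibble(id = as.character(e$id),
                                      label = as.character(e$label %||% e$id))
  }

  if (length(problems) > 0) schema_fail(problems)

  graph <- process_graph(
    entities = if (length(ents)) bind_rows(ents) else NULL,
    processes = if (length(prcs)) bind_rows(prcs) else NULL,
    is_a = if (length(isa)) bind_rows(isa) else NULL,
    classes = if (length(cls)) bind_rows(cls) else NULL,
    meta = doc$meta %||% list())

  dangling <- filter(validate_graph(graph), .data$rule == "dangling_reference")
  if (nrow(dangling) > 0) {
    pg_abort(paste0("dangling reference(s):\n",
                    paste(" ", dangling$subject, "->", dangling$message,
                          collapse = "\n")),
             "pg_error_dangling_ref")
  }
  graph
}

ubox <- jsonlite::unbox

entity_to_doc <- function(row) {
  out <- list(id = ubox(row$id), label = ubox(row$label),
              kind = ubox(row$kind))
  for (f in ENTITY_LIST_FIELDS) {
    v <- sort(unique(row[[f]][[1]]))
    if (length(v) > 0) out[[f]] <- v
  }
  out
}

process_to_doc <- function(row) {
  out <- list(id = ubox(row$id), label = ubox(row$label),
              kind = ubox(row$kind))
  for (f in PROCESS_LIST_FIELDS) {
    ordered <- f %in% c("starts_with", "ends_with", "intermediates", "forks",
                        "cyclication_of")
    v <- if (ordered) unique(row[[f]][[1]]) else sort(unique(row[[f]][[1]]))
    if (length(v) > 0) out[[f]] <- v
  }
  if (!isTRUE(row$native)) out$native <- ubox(FALSE)
  out
}

bundle_to_doc <- function(bundle) {
  aggs <- sort(unique(bundle$io$process_id))
  list(
    mode = ubox(bundle$mode),
    aggregates = lapply(aggs, function(a) {
      res <- bundle$resolved_io[[a]]
      prec <- bundle$precedes[bundle$precedes$agg_id == a, ]
      list(
        id = ubox(a),
        inputs = sort(res$inputs), outputs = sort(res$outputs),
        consumed = sort(bundle$consumed$entity_id[
          bundle$consumed$agg_id == a]),
        precedes = lapply(seq_len(nrow(prec)), function(k) {
          list(from = ubox(prec$from[k]), to = ubox(prec$to[k]))
        })
      )
    }),
    key_elements = lapply(sort(unique(bundle$key_elements$process_id)),
                          function(p) list(
                            process = ubox(p),
                            entities = sort(bundle$key_elements$entity_id[
                              bundle$key_elements$process_id == p]))),
    affects = lapply(sort(unique(bundle$affects$function_label)),
                     function(f) list(
                       function_label = ubox(f),
                       processes = sort(bundle$affects$process_id[
                         bundle$affects$function_label == f])))
  )
}

classification_to_doc <- function(classification) {
  lapply(seq_len(nrow(classification)), function(i) {
    row <- classification[i, ]
    idcol <- names(classification)[1]
    tags <- names(classification)[-1][map_lgl(names(classification)[-1],
                                              ~ isTRUE(row[[.x]]))]
    out <- list(ubox(row[[idcol]]))
    names(out) <- idcol
    out$tags <- sort(tags)
    out
  })
}

#' Serialize a process graph to the native JSON format
#'
#' Output is canonical: records sorted by id, set-valued fields sorted,
#' composition lists kept in authored order. Byte-stable for a fixed
#' graph.
#'
#' @param graph A process graph.
#' @param bundle Optional [saturate()] bundle, emitted as an `inferred`
#'   section.
#' @param classification Optional [classify_processes()] and/or
#'   [classify_reactants()] tables, as a named list (e.g.
#'   `list(processes = ..., reactants = ...)`), emitted as a
#'   `classification` section.
#' @param path Optional output file; when `NULL` the JSON text is
#'   returned.
#' @return The JSON text, invisibly when written to `path`.
#' @export
dump_native <- function(graph, bundle = NULL, classification = NULL,
                        path = NULL) {
  ent <- graph$entities[order(graph$entities$id), ]
  prc <- graph$processes[order(graph$processes$id), ]
  isa <- graph$is_a[order(graph$is_a$child, graph$is_a$parent), ]
  cls <- graph$classes[order(graph$classes$id), ]

  meta <- graph$meta
  meta <- if (length(meta) > 0) lapply(meta[order(names(meta))], ubox) else
    structure(list(), names = character(0))
  doc <- list(meta = meta)
  if (nrow(cls) > 0) {
    doc$classes <- lapply(seq_len(nrow(cls)), function(i) {
      list(id = ubox(cls$id[i]), label = ubox(cls$label[i]))
    })
  }
  doc$entities <- lapply(seq_len(nrow(ent)),
                         function(i) entity_to_doc(ent[i, ]))
  doc$processes <- lapply(seq_len(nrow(prc)),
                          function(i) process_to_doc(prc[i, ]))
  doc$is_a <- lapply(seq_len(nrow(isa)), function(i) {
    list(child = ubox(isa$child[i]), parent = ubox(isa$parent[i]))
  })
  if (!is.null(bundle)) doc$inferred <- bundle_to_doc(bundle)
  if (!is.null(classification)) {
    doc$classification <- lapply(classification, classification_to_doc)
  }
  txt <- as.character(jsonlite::toJSON(doc, pretty = 2, auto_unbox = FALSE,
                                       null = "null"))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
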