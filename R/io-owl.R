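# OWL 2 functional-syntax export.
#
# Conventions preserved from the curation side: original cross-references
# are kept as oboInOwl:hasDbXref annotations, labels as rdfs:label, and
# property IRIs reuse Relation Ontology / BFO ids where they exist
# (has_participant RO_0000057, has_input RO_0002233, has_output RO_0002234,
# has_part BFO_0000051); all other properties are minted under the local
# prefix. Every leaf class is instantiated with one typical individual
# (prefix i_/s_/p_ for chemical entities, sequence features and processes)
# closed by an ObjectOneOf equivalence, which is what makes closed-world
# rule evaluation sound at the ontology level. Functional syntax is the
# canonical serialization because it is deterministic and diffable.

OWL_PROPS <- c(
  has_participant = "obo:RO_0000057", has_input = "obo:RO_0002233",
  has_output = "obo:RO_0002234", has_part = "obo:BFO_0000051",
  has_catalyst = ":has_catalyst", located_in = ":located_in",
  binds_to = ":binds_to", is_motif_of = ":is_motif_of",
  has_template = ":has_template", has_subprocess = ":has_subprocess",
  starts_with = ":starts_with", ends_with = ":ends_with",
  has_intermediate_process = ":has_intermediate_process",
  has_fork_process = ":has_fork_process", cyclication_of = ":cyclication_of",
  precedes = ":precedes", consumes = ":consumes",
  has_key_element = ":has_key_element")

KIND_TOP_CLASS <- c(small_molecule = ":chemical_entity",
                    macromolecule = ":chemical_entity",
                    sequence_feature = ":sequence_feature",
                    cellular_component = ":cellular_component")

sanitize_iri_name <- function(id) {
  out <- gsub("[^A-Za-z0-9_]", "", gsub("[ \t/,:+-]+", "_", id))
  out
}

iri_names <- function(ids) {
  nm <- sanitize_iri_name(ids)
  empty <- ids[nm == ""]
  if (length(empty) > 0) {
    pg_abort(sprintf(
      "id(s) %s cannot be minted into an IRI; suggested replacement: %s",
      paste(shQuote(empty), collapse = ", "),
      paste(sprintf("class_%d", seq_along(empty)), collapse = ", ")),
      "pg_error_naming")
  }
  clash <- unique(nm[duplicated(nm)])
  if (length(clash) > 0) {
    pg_abort(sprintf(
      "ids collide after IRI sanitization: %s; disambiguate the ids",
      paste(clash, collapse = ", ")), "pg_error_naming")
  }
  stats::setNames(paste0(":", nm), ids)
}

owl_literal <- function(x) {
  sprintf("\"%s\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)))
}

some_values <- function(prop, cls) {
  sprintf("ObjectSomeValuesFrom(%s %s)", prop, cls)
}

all_values <- function(prop, classes) {
  filler <- if (length(classes) == 1) classes else
    sprintf("ObjectUnionOf(%s)", paste(sort(classes), collapse = " "))
  sprintf("ObjectAllValuesFrom(%s %s)", prop, filler)
}

#' Export a process graph as OWL 2 functional syntax
#'
#' Emits class declarations and hierarchy, the object-property skeleton
#' (with `binds_to` as sub-property of `located_in`, transitive `has_part`
#' and `is_motif_of`, and the participant/composition sub-property trees),
#' equivalence axioms for elementary processes (SOME/ONLY over
#' inputs/outputs) and aggregated processes (composition roles plus
#' `has_subprocess ONLY` union), `rdfs:label` and `hasDbXref` annotations,
#' and one named individual per leaf class (`i_`/`s_`/`p_` prefix) closed
#' by an `ObjectOneOf` equivalence. When a bundle is given, inferred
#' relations are emitted as property assertions between individuals.
#'
#' Re-export of the same graph is byte-identical.
#'
#' @param graph A validated process graph.
#' @param bundle Optional [saturate()] bundle.
#' @param iri_prefix Ontology IRI prefix; defaults to
#'   `graph$meta$iri_prefix` or a placeholder prefix.
#' @param path Optional output file (`.ofn`).
#' @return The functional-syntax text, invisibly when written to `path`.
#' @export
export_owl <- function(graph, bundle = NULL, iri_prefix = NULL, path = NULL) {
  prefix <- iri_prefix %||% graph$meta$iri_prefix %||%
    "http://example.org/procgraph/"
  ent <- graph$entities
  prc <- graph$processes
  all_ids <- sort(unique(c(ent$id, prc$id, graph$classes$id,
                           graph$is_a$child, graph$is_a$parent)))
  iri <- iri_names(all_ids)
  labels <- c(stats::setNames(ent$label, ent$id),
              stats::setNames(prc$label, prc$id),
              stats::setNames(graph$classes$label, graph$classes$id))

  ax <- character(0)
  add <- function(...) ax <<- c(ax, sprintf(...))

  # object property skeleton
  for (p in sort(unname(OWL_PROPS))) add("Declaration(ObjectProperty(%s))", p)
  add("Declaration(AnnotationProperty(oboInOwl:hasDbXref))")
  for (p in c("has_input", "has_output", "has_catalyst")) {
    add("SubObjectPropertyOf(%s %s)", OWL_PROPS[[p]],
        OWL_PROPS[["has_participant"]])
  }
  add("SubObjectPropertyOf(%s %s)", OWL_PROPS[["binds_to"]],
      OWL_PROPS[["located_in"]])
  for (p in c("cyclication_of", "has_subprocess")) {
    add("SubObjectPropertyOf(%s %s)", OWL_PROPS[[p]], OWL_PROPS[["has_part"]])
  }
  for (p in c("starts_with", "ends_with", "has_intermediate_process",
              "has_fork_process")) {
    add("SubObjectPropertyOf(%s %s)", OWL_PROPS[[p]],
        OWL_PROPS[["has_subprocess"]])
  }
  add("DisjointObjectProperties(%s %s %s %s)", OWL_PROPS[["starts_with"]],
      OWL_PROPS[["ends_with"]], OWL_PROPS[["has_intermediate_process"]],
      OWL_PROPS[["has_fork_process"]])
  add("TransitiveObjectProperty(%s)", OWL_PROPS[["has_part"]])
  add("TransitiveObjectProperty(%s)", OWL_PROPS[["is_motif_of"]])

  # top classes
  tops <- c(":biological_process", ":chemical_entity", ":sequence_feature",
            ":cellular_component")
  for (cl in tops) add("Declaration(Class(%s))", cl)

  # declarations + hierarchy
  for (id in all_ids) add("Declaration(Class(%s))", iri[[id]])
  ekind <- stats::setNames(ent$kind, ent$id)
  for (id in sort(ent$id)) {
    add("SubClassOf(%s %s)", iri[[id]], KIND_TOP_CLASS[[ekind[[id]]]])
  }
  for (id in sort(prc$id)) add("SubClassOf(%s :biological_process)", iri[[id]])
  isa <- graph$is_a[order(graph$is_a$child, graph$is_a$parent), ]
  for (k in seq_len(nrow(isa))) {
    add("SubClassOf(%s %s)", iri[[isa$child[k]]], iri[[isa$parent[k]]])
  }

  # entity property restrictions
  eord <- order(ent$id)
  for (i in eord) {
    id <- ent$id[i]
    for (t in sort(ent$located_in[[i]])) {
      add("SubClassOf(%s %s)", iri[[id]],
          some_values(OWL_PROPS[["located_in"]], iri[[t]]))
    }
    for (t in sort(ent$binds_to[[i]])) {
      add("SubClassOf(%s %s)", iri[[id]],
          some_values(OWL_PROPS[["binds_to"]], iri[[t]]))
    }
    for (t in sort(ent$is_motif_of[[i]])) {
      add("SubClassOf(%s %s)", iri[[id]],
          some_values(OWL_PROPS[["is_motif_of"]], iri[[t]]))
    }
    for (t in sort(ent$has_template[[i]])) {
      add("SubClassOf(%s %s)", iri[[id]],
          some_values(OWL_PROPS[["has_template"]], iri[[t]]))
    }
  }

  # process equivalence axioms
  pord <- order(prc$id)
  for (i in pord) {
    id <- prc$id[i]
    conj <- character(0)
    if (prc$kind[i] == "elementary") {
      for (t in sort(prc$inputs[[i]])) {
        conj <- c(conj, some_values(OWL_PROPS[["has_input"]], iri[[t]]))
      }
      for (t in sort(prc$outputs[[i]])) {
        conj <- c(conj, some_values(OWL_PROPS[["has_output"]], iri[[t]]))
      }
      for (t in sort(prc$catalysts[[i]])) {
        conj <- c(conj, some_values(OWL_PROPS[["has_catalyst"]], iri[[t]]))
      }
      if (length(prc$inputs[[i]]) > 0) {
        conj <- c(conj, all_values(OWL_PROPS[["has_input"]],
                                   unname(iri[sort(prc$inputs[[i]])])))
      }
      if (length(prc$outputs[[i]]) > 0) {
        conj <- c(conj, all_values(OWL_PROPS[["has_output"]],
                                   unname(iri[sort(prc$outputs[[i]])])))
      }
    } else {
      role_props <- c(starts_with = "starts_with", forks = "has_fork_process",
                      intermediates = "has_intermediate_process",
                      ends_with = "ends_with")
      for (f in names(role_props)) {
        for (t in prc[[f]][[i]]) {
          conj <- c(conj, some_values(OWL_PROPS[[role_props[[f]]]], iri[[t]]))
        }
      }
      members <- unique(c(prc$starts_with[[i]], prc$forks[[i]],
                          prc$intermediates[[i]], prc$ends_with[[i]]))
      if (length(members) > 0) {
        conj <- c(conj, all_values(OWL_PROPS[["has_subprocess"]],
                                   unname(iri[sort(members)])))
      }
      for (t in sort(prc$cyclication_of[[i]])) {
        add("SubClassOf(%s %s)", iri[[id]],
            some_values(OWL_PROPS[["cyclication_of"]], iri[[t]]))
      }
    }
    if (length(conj) >= 2) {
      add("EquivalentClasses(%s ObjectIntersectionOf(%s))", iri[[id]],
          paste(conj, collapse = " "))
    } else if (length(conj) == 1) {
      add("EquivalentClasses(%s %s)", iri[[id]], conj)
    }
  }

  # annotations: labels and cross-references
  for (id in all_ids) {
    lab <- labels[id]
    if (!is.na(lab)) {
      add("AnnotationAssertion(rdfs:label %s %s)", iri[[id]],
          owl_literal(unname(lab)))
    }
  }
  xr <- c(stats::setNames(ent$xrefs, ent$id), stats::setNames(prc$xrefs, prc$id))
  for (id in sort(names(xr))) {
    for (x in sort(xr[[id]])) {
      add("AnnotationAssertion(oboInOwl:hasDbXref %s %s)", iri[[id]],
          owl_literal(x))
    }
  }

  # one typical individual per leaf class
  has_children <- unique(graph$is_a$parent)
  leaf <- function(id) !id %in% has_children
  ind_prefix <- function(id) {
    if (id %in% names(ekind)) {
      switch(ekind[[id]], sequence_feature = "s_", cellular_component = "i_",
             "i_")
    } else "p_"
  }
  indiv <- stats::setNames(
    paste0(":", map_chr(all_ids, ind_prefix), sanitize_iri_name(all_ids)),
    all_ids)
  leaves <- sort(c(ent$id[map_lgl(ent$id, leaf)], prc$id[map_lgl(prc$id, leaf)]))
  for (id in leaves) {
    add("Declaration(NamedIndividual(%s))", indiv[[id]])
    add("EquivalentClasses(%s ObjectOneOf(%s))", iri[[id]], indiv[[id]])
  }

  # inferred relations as assertions between typical individuals
  if (!is.null(bundle)) {
    assert_ok <- function(a, b) a %in% leaves && b %in% leaves
    io <- bundle$io[order(bundle$io$process_id, bundle$io$direction,
                          bundle$io$entity_id), ]
    for (k in seq_len(nrow(io))) {
      if (!assert_ok(io$process_id[k], io$entity_id[k])) next
      prop <- if (io$direction[k] == "input") "has_input" else "has_output"
      add("ObjectPropertyAssertion(%s %s %s)", OWL_PROPS[[prop]],
          indiv[[io$process_id[k]]], indiv[[io$entity_id[k]]])
    }
    cons <- bundle$consumed[order(bundle$consumed$agg_id,
                                  bundle$consumed$entity_id), ]
    for (k in seq_len(nrow(cons))) {
      if (!assert_ok(cons$agg_id[k], cons$entity_id[k])) next
      add("ObjectPropertyAssertion(%s %s %s)", OWL_PROPS[["consumes"]],
          indiv[[cons$agg_id[k]]], indiv[[cons$entity_id[k]]])
    }
    prec <- bundle$precedes[order(bundle$precedes$agg_id, bundle$precedes$from,
                                  bundle$precedes$to), ]
    for (k in seq_len(nrow(prec))) {
      if (!assert_ok(prec$from[k], prec$to[k])) next
      add("ObjectPropertyAssertion(%s %s %s)", OWL_PROPS[["precedes"]],
          indiv[[prec$from[k]]], indiv[[prec$to[k]]])
    }
    ke <- bundle$key_elements[order(bundle$key_elements$process_id,
                                    bundle$key_elements$entity_id), ]
    for (k in seq_len(nrow(ke))) {
      if (!assert_ok(ke$process_id[k], ke$entity_id[k])) next
      add("ObjectPropertyAssertion(%s %s %s)", OWL_PROPS[["has_key_element"]],
          indiv[[ke$process_id[k]]], indiv[[ke$entity_id[k]]])
    }
  }

  txt <- paste0(
    paste(c(
      sprintf("Prefix(:=<%s>)", prefix),
      "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
      "Prefix(rdf:=<http://www.w3.org/1999/02/22-rdf-syntax-ns#>)",
      "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
      "Prefix(xsd:=<http://www.w3.org/2001/XMLSchema#>)",
      "Prefix(obo:=<http://purl.obolibrary.org/obo/>)",
      "Prefix(oboInOwl:=<http://www.geneontology.org/formats/oboInOwl#>)",
      "",
      sprintf("Ontology(<%sontology>", prefix),
      ax,
      ")"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

# --- functional-syntax structure checker -------------------------------------
# A grammar validator for the OFN subset the exporter emits: tokenizes the
# document and recursively checks that every construct is a known OWL 2
# functional-syntax production with structurally valid arguments.

OFN_AXIOMS <- c("Declaration", "SubClassOf", "EquivalentClasses",
                "DisjointClasses", "SubObjectPropertyOf",
                "DisjointObjectProperties", "TransitiveObjectProperty",
                "AnnotationAssertion", "ObjectPropertyAssertion",
                "ClassAssertion")
OFN_DECLARABLE <- c("Class", "ObjectProperty", "AnnotationProperty",
                    "NamedIndividual", "Datatype", "DataProperty")
OFN_CLASS_EXPR <- c("ObjectIntersectionOf", "ObjectUnionOf", "ObjectOneOf",
                    "ObjectSomeValuesFrom", "ObjectAllValuesFrom",
                    "ObjectComplementOf")

ofn_tokenize <- function(text) {
  pattern <- paste0(
    '"(?:[^"\\\\]|\\\\.)*"',            # quoted literal
    "|<[^>]*>",                         # full IRI
    "|[A-Za-z][A-Za-z0-9_]*:=",         # prefix declaration name, e.g. rdfs:=
    "|[A-Za-z0-9_]*:[A-Za-z0-9_]+",     # prefixed name (possibly :local)
    "|:=",                              # default prefix declaration
    "|[A-Za-z][A-Za-z0-9_]*",           # keyword
    "|[()]")
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

#' Check OWL 2 functional-syntax structure
#'
#' Validates that a document consists of prefix declarations followed by a
#' single `Ontology(...)` block whose axioms all belong to the OWL 2
#' functional-syntax grammar (subset used by [export_owl()]): known axiom
#' and class-expression constructors, balanced parentheses, and IRI /
#' literal arguments where the grammar requires them.
#'
#' @param text Functional-syntax document text.
#' @return `TRUE` invisibly; aborts with a descriptive error otherwise.
#' @export
check_ofn <- function(text) {
  toks <- ofn_tokenize(text)
  pos <- 1L
  fail <- function(msg) {
    pg_abort(sprintf("functional-syntax error near token %d (%s): %s", pos,
                     if (pos <= length(toks)) toks[pos] else "<eof>", msg),
             "pg_error_ofn")
  }
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(t) if (!identical(take(), t)) fail(sprintf("expected '%s'", t))
  is_iri <- function(t) !is.na(t) &&
    (grepl("^<[^>]*>$", t) || grepl("^[A-Za-z0-9_]*:[A-Za-z0-9_]+$", t) ||
       grepl("^:[A-Za-z0-9_]+$", t))
  is_literal <- function(t) !is.na(t) && grepl('^".*"$', t)

  entity_ref <- function() {
    t <- take()
    if (!is_iri(t)) fail("expected an IRI or prefixed name")
  }
  class_expr <- function() {
    t <- peek()
    if (is_iri(t) && !t %in% OFN_CLASS_EXPR) { take(); return(invisible()) }
    t <- take()
    if (!t %in% OFN_CLASS_EXPR) fail("expected a class expression")
    expect("(")
    if (t %in% c("ObjectSomeValuesFrom", "ObjectAllValuesFrom")) {
      entity_ref()
      class_expr()
    } else if (t == "ObjectOneOf") {
      while (!identical(peek(), ")")) entity_ref()
    } else if (t == "ObjectComplementOf") {
      class_expr()
    } else {
      n <- 0L
      while (!identical(peek(), ")")) { class_expr(); n <- n + 1L }
      if (n < 2) fail(sprintf("%s needs at least two operands", t))
    }
    expect(")")
  }
  axiom <- function() {
    t <- take()
    if (!t %in% OFN_AXIOMS) fail("unknown axiom constructor")
    expect("(")
    switch(t,
      Declaration = {
        d <- take()
        if (!d %in% OFN_DECLARABLE) fail("unknown declaration type")
        expect("(")
        entity_ref()
        expect(")")
      },
      SubClassOf = { class_expr(); class_expr() },
      EquivalentClasses = ,
      DisjointClasses = {
        n <- 0L
        while (!identical(peek(), ")")) { class_expr(); n <- n + 1L }
        if (n < 2) fail("needs at least two class expressions")
      },
      SubObjectPropertyOf = { entity_ref(); entity_ref() },
      DisjointObjectProperties = {
        while (!identical(peek(), ")")) entity_ref()
      },
      TransitiveObjectProperty = entity_ref(),
      AnnotationAssertion = {
        entity_ref(); entity_ref()
        v <- take()
        if (!is_literal(v) && !is_iri(v)) fail("expected annotation value")
      },
      ObjectPropertyAssertion = { entity_ref(); entity_ref(); entity_ref() },
      ClassAssertion = { class_expr(); entity_ref() }
    )
    expect(")")
  }

  while (identical(peek(), "Prefix")) {
    take(); expect("(")
    pn <- take()
    if (!grepl("^([A-Za-z][A-Za-z0-9_]*)?:=$", pn)) fail("bad prefix name")
    t <- take()
    if (!grepl("^<[^>]*>$", t)) fail("prefix must map to a full IRI")
    expect(")")
  }
  expect("Ontology")
  expect("(")
  t <- peek()
  if (is_iri(t) && grepl("^<", t)) take()          # ontology IRI
  if (is_iri(peek()) && grepl("^<", peek())) take() # version IRI
  while (!identical(peek(), ")")) {
    if (is.na(peek())) fail("unterminated Ontology block")
    axiom()
  }
  expect(")")
  if (pos <= length(toks)) fail("trailing tokens after Ontology block")
  invisible(TRUE)
}
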