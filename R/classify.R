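# Closed-world evaluation of the bridge rules between the biological and
# the modeling views, followed by rate-law template assignment.
#
# Reactant tags (entities):
#   reactant       == participates in at least one process
#   chemical       == reactant of chemical kind (small molecule/macromolecule)
#   motif_entity   == reactant of sequence-feature kind
#   bound_chemical == chemical with at least one binds_to edge
#   free_chemical  == chemical whose effective localizations (located_in
#                     plus binds_to, sub-property semantics) are all the
#                     designated cytosol entity
#
# Universal (ONLY) restrictions are evaluated closed-world against the
# explicitly listed participants/localizations: this is the role the
# singleton instantiation plays in the ontology release, where every leaf
# class is closed to one typical individual.

PROCESS_CATEGORIES <- c(
  "elementary_process", "aggregated_process", "elementary_chemical_process",
  "sequence_binding_process", "release_process", "matrix_dependent_process",
  "polymer_production_process", "native_polymer_production_process",
  "transcription_process", "translation_process")

#' Classify entities onto reactant classes
#'
#' Evaluates the bridge-rule definitions for every entity of the graph:
#' `Reactant == participates_in SOME biological process`, `Chemical` /
#' `Motif Entity` by kind, `BoundChemical == Chemical AND binds_to SOME
#' sequence feature`, and `FreeChemical == Chemical AND located_in ONLY
#' cytosol`, the last evaluated closed-world over the effective
#' localizations (a `binds_to` edge counts as a non-cytosol localization).
#'
#' A chemical with no localization at all satisfies the universal
#' restriction vacuously; by default such entities are *not* tagged free
#' (at least one effective localization is required). Set
#' `vacuous_only_is_free = TRUE` for the literal description-logic reading.
#'
#' @param graph A process graph.
#' @param cytosol Id of the designated cytosol entity (default
#'   `"cytosol"`).
#' @param vacuous_only_is_free Tag unlocalized chemicals as free
#'   (default `FALSE`).
#' @param localization Evaluate the free/bound split (default `TRUE`);
#'   requires the cytosol entity to be declared.
#' @return A tibble with columns `entity_id`, `reactant`, `chemical`,
#'   `motif_entity`, `free_chemical`, `bound_chemical` (logicals).
#' @export
classify_reactants <- function(graph, cytosol = "cytosol",
                               vacuous_only_is_free = FALSE,
                               localization = TRUE) {
  ent <- graph$entities
  prc <- graph$processes
  if (localization && !cytosol %in% ent$id) {
    pg_abort(sprintf(
      "free/bound classification requires a declared cytosol entity ('%s' not found)",
      cytosol), "pg_error_config")
  }
  participants <- unique(unlist(c(prc$inputs, prc$outputs, prc$catalysts),
                                use.names = FALSE))
  reactant <- ent$id %in% participants
  chemical <- reactant & ent$kind %in% CHEMICAL_KINDS
  motif <- reactant & ent$kind == "sequence_feature"
  bound <- chemical & lengths(ent$binds_to) > 0
  if (localization) {
    eff_loc <- map2(ent$located_in, ent$binds_to, ~ unique(c(.x, .y)))
    only_cyt <- map_lgl(eff_loc, ~ all(.x == cytosol))
    has_loc <- lengths(eff_loc) > 0
    free <- chemical & only_cyt & (has_loc | vacuous_only_is_free)
  } else {
    free <- rep(FALSE, nrow(ent))
  }
  tibble(entity_id = ent$id, reactant = reactant, chemical = chemical,
         motif_entity = motif, free_chemical = free & !bound,
         bound_chemical = bound)
}

# helper: tag lookup over a reactant table
tag_set <- function(reactants, tag) {
  reactants$entity_id[reactants[[tag]]]
}

#' Classify processes onto modeled-process categories
#'
#' Closed-world evaluation of the modeled-process class templates against
#' each process's participant sets (authored for elementary processes,
#' inferred for aggregates):
#'
#' * `elementary_chemical_process` — elementary, all participants Chemical;
#' * `sequence_binding_process` — elementary, some motif input, some free
#'   chemical input, some bound chemical output, inputs only motifs or
#'   free chemicals, outputs only bound chemicals;
#' * `matrix_dependent_process` — aggregated with some sequence-binding
#'   part (transitive);
#' * `polymer_production_process` — matrix dependent with some release
#'   part (`release_process` is a curator-declared tag, no defining axiom
#'   exists);
#' * `native_polymer_production_process` — polymer production with the
#'   `native` flag;
#' * `transcription_process` / `translation_process` — native polymer
#'   production with some output whose ancestors include the
#'   `transcript_class` / `polypeptide_class` abstract class.
#'
#' @param graph A process graph.
#' @param reactants A [classify_reactants()] table.
#' @param bundle An [saturate()] bundle; required whenever the graph
#'   contains aggregated processes (their participants and `has_part`
#'   closure are read from it).
#' @param transcript_class,polypeptide_class Ids of the abstract output
#'   classes anchoring transcription and translation.
#' @return A tibble: `process_id` plus one logical column per category.
#' @export
classify_processes <- function(graph, reactants = classify_reactants(graph),
                               bundle = NULL,
                               transcript_class = "primary_transcript",
                               polypeptide_class = "pre_processed_polypeptide") {
  prc <- graph$processes
  n <- nrow(prc)
  if (is.null(bundle) && any(prc$kind == "aggregated")) {
    pg_abort("graph has aggregated processes: saturate() it first and pass the bundle",
             "pg_error_unresolved_io")
  }
  chem <- tag_set(reactants, "chemical")
  motif <- tag_set(reactants, "motif_entity")
  free <- tag_set(reactants, "free_chemical")
  bound <- tag_set(reactants, "bound_chemical")

  proc_io <- function(i) {
    if (prc$kind[i] == "elementary") {
      list(inputs = prc$inputs[[i]], outputs = prc$outputs[[i]])
    } else {
      aggregate_io(bundle, prc$id[i])
    }
  }

  elem <- prc$kind == "elementary"
  aggr <- !elem
  ecp <- logical(n); sbp <- logical(n)
  out_anc_transcript <- logical(n); out_anc_polypeptide <- logical(n)
  known <- graph_ids(graph)
  anc_has <- function(ids, cls) {
    if (!cls %in% known) return(FALSE)
    any(map_lgl(ids, ~ cls %in% ancestors(graph, .x)))
  }
  for (i in seq_len(n)) {
    pio <- proc_io(i)
    if (elem[i]) {
      ecp[i] <- all(pio$inputs %in% chem) && all(pio$outputs %in% chem)
      sbp[i] <- any(pio$inputs %in% motif) && any(pio$inputs %in% free) &&
        any(pio$outputs %in% bound) &&
        all(pio$inputs %in% c(motif, free)) && all(pio$outputs %in% bound)
    }
    out_anc_transcript[i] <- anc_has(pio$outputs, transcript_class)
    out_anc_polypeptide[i] <- anc_has(pio$outputs, polypeptide_class)
  }

  declared <- prc$declared_categories
  release <- map_lgl(declared, ~ "release_process" %in% .x)

  parts_of <- function(i) {
    if (!aggr[i]) return(character(0))
    bundle$has_part$part_id[bundle$has_part$process_id == prc$id[i]]
  }
  sbp_ids <- prc$id[sbp]
  rel_ids <- prc$id[release]
  mdp <- logical(n); ppp <- logical(n)
  for (i in which(aggr)) {
    parts <- parts_of(i)
    mdp[i] <- any(parts %in% sbp_ids)
    ppp[i] <- mdp[i] && any(parts %in% rel_ids)
  }
  nppp <- ppp & prc$native
  txp <- nppp & out_anc_transcript
  tlp <- nppp & out_anc_polypeptide

  tibble(
    process_id = prc$id,
    elementary_process = elem,
    aggregated_process = aggr,
    elementary_chemical_process = ecp,
    sequence_binding_process = sbp,
    release_process = release,
    matrix_dependent_process = mdp,
    polymer_production_process = ppp,
    native_polymer_production_process = nppp,
    transcription_process = txp,
    translation_process = tlp
  )
}
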