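# Deterministic fixtures: the translation-initiation worked example and
# randomized multi-scale chain/fork graphs with constructive ground truth.

#' Worked example: formation of the 30S--mRNA complex
#'
#' The prokaryotic translation-initiation chain encoded as a process graph:
#' four elementary processes (free 30S fixation, A site hiding, mRNA
#' binding / translation preinitiation, mRNA scanning for start codon
#' recognition) composed into one aggregated process. Free entities are
#' localized in the cytosol, the ribosome-binding-site and start-codon
#' motifs are carried by the mRNA, and the two scanning complexes are
#' bound to those motifs.
#'
#' @return A validated `process_graph`.
#' @examples
#' g <- worked_example_30s()
#' saturate(g)$consumed
#' @export
worked_example_30s <- function() {
  classes <- tibble(
    id = c("biological_process", "cellular_process", "chemical_entity",
           "sequence_feature_class", "cellular_component_class",
           "initiation_factor"),
    label = c("biological process", "cellular process", "chemical entity",
              "sequence feature", "cellular component", "initiation factor"))

  entities <- bind_rows(
    entity_record("cytosol", "cytosol", "cellular_component"),
    entity_record("mRNA", "mRNA", "cellular_component"),
    entity_record("if3", "prokaryote translation initiation factor IF-3",
                  "macromolecule", xrefs = "K02520", located_in = "cytosol"),
    entity_record("ribosome_30S", "30S", "macromolecule",
                  located_in = "cytosol"),
    entity_record("if1", "prokaryote translation initiation factor IF-1",
                  "macromolecule", located_in = "cytosol"),
    entity_record("complex_30S_IF3", "30S-IF3 complex", "macromolecule",
                  located_in = "cytosol"),
    entity_record("complex_30S_IF3_IF1", "30S-IF3-IF1 complex",
                  "macromolecule", located_in = "cytosol"),
    entity_record("rbs_motif", "GGAGG", "sequence_feature",
                  is_motif_of = "mRNA"),
    entity_record("start_codon_motif", "AUG", "sequence_feature",
                  is_motif_of = "mRNA"),
    entity_record("complex_preinit_RBS",
                  "30S-mRNA preinitiation complex at RBS", "macromolecule",
                  binds_to = "rbs_motif"),
    entity_record("complex_30S_initiation", "30S initiation complex",
                  "macromolecule", binds_to = "start_codon_motif")
  )

  processes <- bind_rows(
    process_record("free_30S_fixation", "free 30S fixation", "elementary",
                   inputs = c("if3", "ribosome_30S"),
                   outputs = "complex_30S_IF3"),
    process_record("a_site_hiding", "A site hiding", "elementary",
                   inputs = c("complex_30S_IF3", "if1"),
                   outputs = "complex_30S_IF3_IF1"),
    process_record("mrna_binding_preinitiation",
                   "mRNA binding, translation preinitiation", "elementary",
                   inputs = c("complex_30S_IF3_IF1", "rbs_motif"),
                   outputs = "complex_preinit_RBS"),
    process_record("mrna_scanning_start_codon",
                   "mRNA scanning for start codon recognition", "elementary",
                   inputs = c("complex_preinit_RBS", "start_codon_motif"),
                   outputs = "complex_30S_initiation"),
    process_record("formation_30S_mRNA_complex",
                   "formation of 30S-mRNA complex", "aggregated",
                   starts_with = "free_30S_fixation",
                   intermediates = c("a_site_hiding",
                                     "mrna_binding_preinitiation"),
                   ends_with = "mrna_scanning_start_codon")
  )

  is_a <- bind_rows(
    tibble(child = "cellular_process", parent = "biological_process"),
    tibble(child = processes$id, parent = "cellular_process"),
    tibble(child = "initiation_factor", parent = "chemical_entity"),
    tibble(child = c("if3", "if1"), parent = "initiation_factor"),
    tibble(child = c("ribosome_30S", "complex_30S_IF3",
                     "complex_30S_IF3_IF1", "complex_preinit_RBS",
                     "complex_30S_initiation"),
           parent = "chemical_entity"),
    tibble(child = c("rbs_motif", "start_codon_motif"),
           parent = "sequence_feature_class"),
    tibble(child = c("cytosol", "mRNA"), parent = "cellular_component_class")
  )

  process_graph(entities, processes, is_a, classes,
                meta = list(iri_prefix = "http://example.org/procgraph/",
                            version = "0.1.0"))
}

# accumulator for building record tibbles without per-row tibble() calls
new_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}
acc_add <- function(acc, row) {
  acc$rows[[length(acc$rows) + 1L]] <- row
  invisible(NULL)
}
acc_tbl <- function(acc, template) {
  cols <- names(template)
  vals <- lapply(cols, function(cn) {
    v <- lapply(acc$rows, function(r) r[[cn]])
    if (is.list(template[[cn]])) {
      lapply(v, function(x) as.character(x %||% character(0)))
    } else if (is.logical(template[[cn]])) {
      vapply(v, function(x) isTRUE(x %||% TRUE), logical(1))
    } else {
      vapply(v, as.character, character(1))
    }
  })
  names(vals) <- cols
  new_tibble(vals, nrow = length(acc$rows))
}

#' Generate a random multi-scale chain/fork graph with ground truth
#'
#' Builds an elementary chain of `chain_length` steps linked by unique
#' intermediates, optionally with fork starters converging on the second
#' step, motif-binding steps (a sequence motif plus a free chemical
#' producing a bound chemical), occasional key-element enzymes (the same
#' macromolecule as input and output of one step), and nested aggregates
#' up to `levels` tiers built by recursive bisection of the chain.
#'
#' Because the product of a motif-binding step is a bound chemical — and a
#' bound input disqualifies the consumer from the sequence-binding class —
#' two consecutive motif steps are never drawn; the realized motif
#' fraction therefore saturates below `motif_prob` on connected chains.
#' When at least one motif step is drawn, the final step is tagged as a
#' release process and the final product is declared a primary transcript,
#' so the enclosing aggregates exercise the matrix-dependent /
#' polymer-production / transcription ladder.
#'
#' Ground truth (expected aggregate I/O, consumed sets, precedes pairs,
#' process categories, reactant tags, key elements and affects facts) is
#' computed constructively during generation, independently of the
#' inference engine.
#'
#' @param levels Number of aggregation tiers (>= 1); capped by what the
#'   chain length supports (each aggregate needs two sub-units).
#' @param chain_length Number of elementary chain steps (>= 1).
#' @param forks Number of fork starter processes (requires
#'   `chain_length >= 2`).
#' @param motif_prob Probability that a step is a motif-binding step.
#' @param seed Integer seed; the same seed yields a byte-identical dump.
#' @param key_prob Probability that a non-motif step carries a key-element
#'   enzyme.
#' @return A list with components `graph` (a `process_graph`) and `truth`
#'   (a `ground_truth` object).
#' @export
random_multiscale_graph <- function(levels = 1, chain_length = 4, forks = 0,
                                    motif_prob = 0, seed, key_prob = 0.2) {
  if (!is.numeric(levels) || levels < 1 || levels != round(levels) ||
      !is.numeric(chain_length) || chain_length < 1 ||
      chain_length != round(chain_length) ||
      !is.numeric(forks) || forks < 0 || forks != round(forks) ||
      !is.numeric(motif_prob) || motif_prob < 0 || motif_prob > 1 ||
      !is.numeric(key_prob) || key_prob < 0 || key_prob > 1) {
    pg_abort("invalid generator parameters", "pg_error_parameter")
  }
  if (forks > 0 && chain_length < 2) {
    pg_abort("forks require chain_length >= 2", "pg_error_parameter")
  }
  if (missing(seed)) pg_abort("seed is required", "pg_error_parameter")
  withr::local_seed(as.integer(seed))

  n <- as.integer(chain_length)
  motif <- logical(n); key <- logical(n)
  for (i in seq_len(n)) {
    motif[i] <- stats::runif(1) < motif_prob && (i == 1 || !motif[i - 1])
    key[i] <- !motif[i] && stats::runif(1) < key_prob
  }
  any_motif <- any(motif)

  ents <- new_acc()
  side_kind <- function() sample(c("small_molecule", "macromolecule"), 1)
  add_ent <- function(id, kind, label = id, located_in = character(),
                      binds_to = character(), is_motif_of = character(),
                      functions = character()) {
    acc_add(ents, list(id = id, label = label, kind = kind,
                       xrefs = character(), located_in = located_in,
                       binds_to = binds_to, is_motif_of = is_motif_of,
                       has_template = character(), functions = functions))
  }
  add_ent("cytosol", "cellular_component")
  if (any_motif) add_ent("template_polymer", "cellular_component")

  step_in <- vector("list", n); step_out <- vector("list", n)
  cid <- function(i) sprintf("int_%03d", i)
  for (i in seq_len(n)) {
    ins <- character(0)
    if (i > 1) ins <- cid(i - 1)
    if (motif[i]) {
      m <- sprintf("motif_%03d", i)
      add_ent(m, "sequence_feature", is_motif_of = "template_polymer")
      if (i == 1) {
        f <- sprintf("chem_%03d_a", i)
        add_ent(f, side_kind(), located_in = "cytosol")
        ins <- c(ins, f)
      }
      ins <- c(ins, m)
    } else {
      s <- sprintf("chem_%03d_a", i)
      add_ent(s, side_kind(), located_in = "cytosol")
      ins <- c(ins, s)
      if (i == 1) {
        s2 <- sprintf("chem_%03d_b", i)
        add_ent(s2, side_kind(), located_in = "cytosol")
        ins <- c(ins, s2)
      }
    }
    outs <- cid(i)
    if (motif[i]) {
      add_ent(cid(i), "macromolecule", binds_to = sprintf("motif_%03d", i))
    } else {
      add_ent(cid(i), "macromolecule", located_in = "cytosol")
    }
    if (key[i]) {
      e <- sprintf("enz_%03d", i)
      add_ent(e, "macromolecule", located_in = "cytosol",
              functions = sprintf("catalytic_activity_%03d", i))
      ins <- c(ins, e)
      outs <- c(outs, e)
    }
    step_in[[i]] <- ins
    step_out[[i]] <- outs
  }

  nf <- as.integer(forks)
  fork_ids <- character(0)
  fork_in <- list(); fork_out <- list()
  for (j in seq_len(nf)) {
    u <- sprintf("fork_chem_%03d_a", j); v <- sprintf("fork_chem_%03d_b", j)
    d <- sprintf("fork_int_%03d", j)
    add_ent(u, side_kind(), located_in = "cytosol")
    add_ent(v, side_kind(), located_in = "cytosol")
    add_ent(d, "macromolecule", located_in = "cytosol")
    fork_ids <- c(fork_ids, sprintf("fork_%03d", j))
    fork_in[[j]] <- c(u, v)
    fork_out[[j]] <- d
    step_in[[2]] <- c(step_in[[2]], d)
  }

  prcs <- new_acc()
  add_prc <- function(id, kind, inputs = character(), outputs = character(),
                      starts_with = character(), ends_with = character(),
                      intermediates = character(), forks = character(),
                      declared_categories = character()) {
    acc_add(prcs, list(
      id = id, label = id, kind = kind, xrefs = character(),
      inputs = inputs, outputs = outputs, catalysts = character(),
      starts_with = starts_with, ends_with = ends_with,
      intermediates = intermediates, forks = forks,
      cyclication_of = character(), native = TRUE,
      declared_categories = declared_categories))
  }
  pid <- function(i) sprintf("proc_%03d", i)
  for (i in seq_len(n)) {
    add_prc(pid(i), "elementary", inputs = step_in[[i]],
            outputs = step_out[[i]],
            declared_categories = if (any_motif && i == n) "release_process"
                                  else character())
  }
  for (j in seq_len(nf)) {
    add_prc(fork_ids[j], "elementary", inputs = fork_in[[j]],
            outputs = fork_out[[j]])
  }

  # recursive bisection into nested aggregates; constructive ground truth
  agg_counter <- 0L
  agg_truth <- list()          # id -> list(inputs, outputs, consumed, precedes, lo, hi, has_motif)
  unit_range <- list()         # unit id -> c(lo, hi)
  all_step_inputs <- function(lo, hi, with_forks) {
    ins <- unique(unlist(step_in[lo:hi], use.names = FALSE))
    if (with_forks) ins <- unique(c(ins, unlist(fork_in, use.names = FALSE)))
    internal <- cid(seq.int(lo, length.out = max(0, hi - lo)))
    if (with_forks) internal <- c(internal, unlist(fork_out))
    setdiff(ins, internal)
  }
  unit_outputs <- function(lo, hi) {
    c(cid(hi), sprintf("enz_%03d", which(key[seq(lo, hi)]) + lo - 1L))
  }
  build <- function(lo, hi, lv) {
    width <- hi - lo + 1L
    if (lv <= 1 || width < 4L) {
      children <- pid(lo:hi)
      with_forks <- nf > 0 && lo == 1L && hi >= 2L
      agg_counter <<- agg_counter + 1L
      id <- sprintf("agg_%03d", agg_counter)
      if (length(children) == 1L) {
        add_prc(id, "aggregated", starts_with = children,
                ends_with = children)
      } else {
        add_prc(id, "aggregated", starts_with = children[1],
                ends_with = children[length(children)],
                intermediates = children[-c(1, length(children))],
                forks = if (with_forks) fork_ids else character())
      }
      pfrom <- if (length(children) > 1) children[-length(children)] else
        character(0)
      pto <- if (length(children) > 1) children[-1] else character(0)
      if (with_forks) {
        pfrom <- c(pfrom, fork_ids)
        pto <- c(pto, rep(pid(2), length(fork_ids)))
      }
      pord <- order(pfrom, pto, method = "radix")
      consumed <- cid(seq.int(lo, length.out = max(0, hi - lo)))
      if (with_forks) consumed <- c(consumed, unlist(fork_out))
      agg_truth[[id]] <<- list(
        inputs = sort(all_step_inputs(lo, hi, with_forks)),
        outputs = sort(unit_outputs(lo, hi)),
        consumed = sort(consumed),
        precedes = fast_tbl(from = pfrom[pord], to = pto[pord]),
        lo = lo, hi = hi, has_motif = any(motif[lo:hi]))
      unit_range[[id]] <<- c(lo, hi)
      return(id)
    }
    m <- lo + max(2L, width %/% 2L) - 1L
    if (hi - m < 2L) m <- hi - 2L
    left <- build(lo, m, lv - 1L)
    right <- build(m + 1L, hi, lv - 1L)
    agg_counter <<- agg_counter + 1L
    id <- sprintf("agg_%03d", agg_counter)
    add_prc(id, "aggregated", starts_with = left, ends_with = right)
    agg_truth[[id]] <<- list(
      inputs = sort(all_step_inputs(lo, hi, nf > 0 && lo == 1L)),
      outputs = sort(unit_outputs(lo, hi)),
      consumed = cid(m),
      precedes = fast_tbl(from = left, to = right),
      lo = lo, hi = hi, has_motif = any(motif[lo:hi]))
    unit_range[[id]] <<- c(lo, hi)
    id
  }
  top <- build(1L, n, as.integer(levels))

  entities <- acc_tbl(ents, empty_entity_tbl())
  processes <- acc_tbl(prcs, empty_process_tbl())
  classes <- NULL
  is_a <- NULL
  if (any_motif) {
    classes <- tibble(id = "primary_transcript", label = "primary transcript")
    is_a <- tibble(child = cid(n), parent = "primary_transcript")
  }
  graph <- process_graph(entities, processes, is_a, classes,
                         meta = list(iri_prefix = "http://example.org/procgraph/",
                                     seed = as.integer(seed)))

  # --- ground-truth tables ---------------------------------------------------
  agg_ids <- names(agg_truth)
  step_ids <- pid(seq_len(n))
  ke_p <- character(0); ke_e <- character(0)
  af_f <- character(0); af_p <- character(0)
  for (i in which(key)) {
    e <- sprintf("enz_%03d", i)
    f <- sprintf("catalytic_activity_%03d", i)
    holders <- sort(c(pid(i),
                      agg_ids[map_lgl(agg_ids, function(a) {
                        r <- unit_range[[a]]; i >= r[1] && i <= r[2]
                      })]))
    ke_p <- c(ke_p, holders); ke_e <- c(ke_e, rep(e, length(holders)))
    af_f <- c(af_f, rep(f, length(holders))); af_p <- c(af_p, holders)
  }
  kord <- order(ke_p, ke_e, method = "radix")
  key_elements <- fast_tbl(process_id = ke_p[kord], entity_id = ke_e[kord])
  aord <- order(af_f, af_p, method = "radix")
  affects <- fast_tbl(function_label = af_f[aord], process_id = af_p[aord])

  all_proc <- c(step_ids, fork_ids, agg_ids)
  cat_tbl <- tibble(
    process_id = all_proc,
    elementary_process = all_proc %in% c(step_ids, fork_ids),
    aggregated_process = all_proc %in% agg_ids,
    elementary_chemical_process =
      all_proc %in% c(pid(which(!motif)), fork_ids),
    sequence_binding_process = all_proc %in% pid(which(motif)),
    release_process = any_motif & all_proc == pid(n),
    matrix_dependent_process =
      all_proc %in% agg_ids[map_lgl(agg_ids, ~ agg_truth[[.x]]$has_motif)],
    polymer_production_process =
      all_proc %in% agg_ids[map_lgl(agg_ids, function(a) {
        agg_truth[[a]]$has_motif && agg_truth[[a]]$hi == n
      })]
  )
  cat_tbl$native_polymer_production_process <- cat_tbl$polymer_production_process
  cat_tbl$transcription_process <- cat_tbl$polymer_production_process
  cat_tbl$translation_process <- FALSE

  ent_ids <- entities$id
  participating <- unique(unlist(c(step_in, step_out, fork_in, fork_out),
                                 use.names = FALSE))
  bound_ids <- cid(which(motif))
  motif_ids <- sprintf("motif_%03d", which(motif))
  reactants <- tibble(
    entity_id = ent_ids,
    reactant = ent_ids %in% participating,
    chemical = ent_ids %in% participating &
      !ent_ids %in% c(motif_ids, "cytosol", "template_polymer"),
    motif_entity = ent_ids %in% motif_ids,
    free_chemical = ent_ids %in% setdiff(participating, c(bound_ids,
                                                          motif_ids)) &
      !ent_ids %in% c("cytosol", "template_polymer"),
    bound_chemical = ent_ids %in% bound_ids
  )

  truth <- structure(list(
    aggregates = agg_truth, top = top, key_elements = key_elements,
    affects = affects, categories = cat_tbl, reactants = reactants,
    params = list(levels = levels, chain_length = chain_length,
                  forks = forks, motif_prob = motif_prob, seed = seed,
                  key_prob = key_prob)
  ), class = "ground_truth")

  list(graph = graph, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d aggregate(s), top '%s'; %d key-element fact(s)\n",
    length(x$aggregates), x$top, nrow(x$key_elements)))
  invisible(x)
}
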