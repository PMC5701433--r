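# Independent brute-force oracles used to cross-check the inference engine
# and the classifier. These deliberately re-derive everything by naive
# per-entity quantifier scans and literal rule evaluation, sharing no code
# with the package internals.

# reflexive-transitive closure of is_a by repeated edge expansion
oracle_ancestors <- function(graph, id) {
  edges <- graph$is_a
  anc <- id
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (length(new) == 0) break
    anc <- c(anc, new)
  }
  sort(anc)
}

oracle_subs <- function(graph, agg_id) {
  i <- match(agg_id, graph$processes$id)
  p <- graph$processes[i, ]
  list(
    starters = unique(c(p$starts_with[[1]], p$forks[[1]])),
    enders = unique(p$ends_with[[1]]),
    all = unique(c(p$starts_with[[1]], p$forks[[1]], p$intermediates[[1]],
                   p$ends_with[[1]]))
  )
}

# resolve every process's I/O top-down with memoized recursion; per-entity
# quantifier scan implements "not produced by a different sub-process",
# with Step-1 seeds forced in
oracle_resolve_io <- function(graph) {
  prc <- graph$processes
  memo <- new.env(parent = emptyenv())
  get_io <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    i <- match(id, prc$id)
    if (prc$kind[i] == "elementary") {
      res <- list(inputs = sort(unique(prc$inputs[[i]])),
                  outputs = sort(unique(prc$outputs[[i]])))
    } else {
      s <- oracle_subs(graph, id)
      sio <- lapply(s$all, get_io)
      names(sio) <- s$all
      ins <- unlist(lapply(s$starters, function(p) sio[[p]]$inputs))
      outs <- unlist(lapply(s$enders, function(p) sio[[p]]$outputs))
      for (p in s$all) {
        for (e in sio[[p]]$inputs) {
          produced_elsewhere <- FALSE
          for (q in s$all) {
            if (q != p && e %in% sio[[q]]$outputs) produced_elsewhere <- TRUE
          }
          if (!produced_elsewhere) ins <- c(ins, e)
        }
        for (e in sio[[p]]$outputs) {
          consumed_elsewhere <- FALSE
          for (q in s$all) {
            if (q != p && e %in% sio[[q]]$inputs) consumed_elsewhere <- TRUE
          }
          if (!consumed_elsewhere) outs <- c(outs, e)
        }
      }
      res <- list(inputs = sort(unique(ins)), outputs = sort(unique(outs)))
    }
    memo[[id]] <- res
    res
  }
  out <- lapply(prc$id, get_io)
  names(out) <- prc$id
  out
}

# literal evaluation of the consumes rule over all ordered sub-process
# pairs and all entities
oracle_consumed <- function(graph, agg_id, io) {
  s <- oracle_subs(graph, agg_id)
  i <- match(agg_id, graph$processes$id)
  p <- graph$processes[i, ]
  consumed <- character(0)
  for (p1 in s$all) {
    for (p2 in s$all) {
      if (p1 == p2) next
      if (p1 %in% p$ends_with[[1]]) next
      if (p2 %in% c(p$starts_with[[1]], p$forks[[1]])) next
      for (m in io[[p1]]$outputs) {
        if (m %in% io[[p2]]$inputs) consumed <- c(consumed, m)
      }
    }
  }
  sort(unique(consumed))
}

oracle_precedes <- function(graph, agg_id, io) {
  s <- oracle_subs(graph, agg_id)
  out <- data.frame(from = character(0), to = character(0))
  for (p1 in s$all) {
    for (p2 in s$all) {
      if (p1 != p2 && any(io[[p1]]$outputs %in% io[[p2]]$inputs)) {
        out <- rbind(out, data.frame(from = p1, to = p2))
      }
    }
  }
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# literal per-participant evaluation of the bridge rules and the
# modeled-process definitions
oracle_classify <- function(graph, io, cytosol = "cytosol") {
  ent <- graph$entities
  prc <- graph$processes
  participant_ids <- unique(unlist(c(prc$inputs, prc$outputs, prc$catalysts)))
  tag <- function(id) {
    i <- match(id, ent$id)
    t <- character(0)
    if (id %in% participant_ids) t <- c(t, "reactant")
    if ("reactant" %in% t &&
        ent$kind[i] %in% c("small_molecule", "macromolecule")) {
      t <- c(t, "chemical")
    }
    if ("reactant" %in% t && ent$kind[i] == "sequence_feature") {
      t <- c(t, "motif_entity")
    }
    if ("chemical" %in% t && length(ent$binds_to[[i]]) > 0) {
      t <- c(t, "bound_chemical")
    }
    eff <- unique(c(ent$located_in[[i]], ent$binds_to[[i]]))
    if ("chemical" %in% t && !"bound_chemical" %in% t &&
        length(eff) > 0 && all(eff == cytosol)) {
      t <- c(t, "free_chemical")
    }
    t
  }
  etags <- lapply(ent$id, tag)
  names(etags) <- ent$id
  has_tag <- function(ids, tg) {
    any(vapply(ids, function(e) tg %in% etags[[e]], logical(1)))
  }
  all_tag <- function(ids, tgs) {
    all(vapply(ids, function(e) any(tgs %in% etags[[e]]), logical(1)))
  }
  # naive transitive has_part closure by repeated expansion
  direct <- lapply(seq_len(nrow(prc)), function(i) {
    unique(c(prc$starts_with[[i]], prc$forks[[i]], prc$intermediates[[i]],
             prc$ends_with[[i]]))
  })
  names(direct) <- prc$id
  closure <- direct
  repeat {
    grew <- FALSE
    for (id in prc$id) {
      add <- unique(unlist(closure[intersect(closure[[id]], prc$id)]))
      new <- setdiff(add, closure[[id]])
      if (length(new) > 0) { closure[[id]] <- c(closure[[id]], new); grew <- TRUE }
    }
    if (!grew) break
  }
  ptags <- lapply(seq_len(nrow(prc)), function(i) {
    id <- prc$id[i]
    ins <- io[[id]]$inputs; outs <- io[[id]]$outputs
    t <- if (prc$kind[i] == "elementary") "elementary_process" else
      "aggregated_process"
    if (prc$kind[i] == "elementary") {
      if (all_tag(ins, "chemical") && all_tag(outs, "chemical")) {
        t <- c(t, "elementary_chemical_process")
      }
      if (has_tag(ins, "motif_entity") && has_tag(ins, "free_chemical") &&
          has_tag(outs, "bound_chemical") &&
          all_tag(ins, c("motif_entity", "free_chemical")) &&
          all_tag(outs, "bound_chemical")) {
        t <- c(t, "sequence_binding_process")
      }
    }
    if ("release_process" %in% prc$declared_categories[[i]]) {
      t <- c(t, "release_process")
    }
    t
  })
  names(ptags) <- prc$id
  # aggregated ladder needs sequence-binding/release tags of parts
  for (i in seq_len(nrow(prc))) {
    id <- prc$id[i]
    if (prc$kind[i] != "aggregated") next
    parts <- closure[[id]]
    if (any(vapply(parts, function(p)
      "sequence_binding_process" %in% ptags[[p]], logical(1)))) {
      ptags[[id]] <- c(ptags[[id]], "matrix_dependent_process")
      if (any(vapply(parts, function(p)
        "release_process" %in% ptags[[p]], logical(1)))) {
        ptags[[id]] <- c(ptags[[id]], "polymer_production_process")
        if (isTRUE(prc$native[i])) {
          ptags[[id]] <- c(ptags[[id]], "native_polymer_production_process")
          outs <- io[[id]]$outputs
          if (any(vapply(outs, function(e)
            "primary_transcript" %in% oracle_ancestors(graph, e),
            logical(1)))) {
            ptags[[id]] <- c(ptags[[id]], "transcription_process")
          }
          if (any(vapply(outs, function(e)
            "pre_processed_polypeptide" %in% oracle_ancestors(graph, e),
            logical(1)))) {
            ptags[[id]] <- c(ptags[[id]], "translation_process")
          }
        }
      }
    }
  }
  list(entities = etags, processes = ptags)
}

# convert a classify_processes() row into a sorted tag vector
category_tags <- function(categories, id) {
  row <- categories[categories$process_id == id, ]
  sort(names(categories)[-1][vapply(names(categories)[-1],
                                    function(cn) isTRUE(row[[cn]]),
                                    logical(1))])
}

reactant_tags <- function(reactants, id) {
  row <- reactants[reactants$entity_id == id, ]
  sort(names(reactants)[-1][vapply(names(reactants)[-1],
                                   function(cn) isTRUE(row[[cn]]),
                                   logical(1))])
}

# random parameter draw for sweep tests (seeded by the caller)
draw_sim <- function(seed) {
  withr::with_seed(seed, {
    list(levels = sample(1:3, 1), chain_length = sample(2:7, 1),
         forks = sample(0:2, 1), motif_prob = stats::runif(1, 0, 0.6),
         key_prob = 0.3)
  })
}

sim_for_seed <- function(seed) {
  p <- draw_sim(seed)
  random_multiscale_graph(levels = p$levels, chain_length = p$chain_length,
                          forks = p$forks, motif_prob = p$motif_prob,
                          seed = seed, key_prob = p$key_prob)
}

# bare elementary chain (no aggregates): used for level-collapse tests
chain_parts <- function(n, seed, motif_prob = 0, key_prob = 0.3) {
  sim <- random_multiscale_graph(levels = 1, chain_length = n,
                                 motif_prob = motif_prob, seed = seed,
                                 key_prob = key_prob)
  g <- sim$graph
  steps <- g$processes$id[g$processes$kind == "elementary"]
  g$processes <- g$processes[g$processes$kind == "elementary", ]
  list(graph = g, steps = steps, truth = sim$truth)
}

agg_record <- function(id, children) {
  if (length(children) == 1) {
    process_record(id, kind = "aggregated", starts_with = children,
                   ends_with = children)
  } else {
    process_record(id, kind = "aggregated", starts_with = children[1],
                   ends_with = children[length(children)],
                   intermediates = children[-c(1, length(children))])
  }
}
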