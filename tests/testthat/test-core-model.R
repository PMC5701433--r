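test_that("entity and process records are stored verbatim, ids must be unique", {
  g <- process_graph()
  g <- add_entity(g, entity_record("if3",
                                   "prokaryote translation initiation factor IF-3",
                                   "macromolecule", xrefs = "K02520"))
  expect_equal(nrow(g$entities), 1)
  expect_equal(g$entities$xrefs[[1]], "K02520")
  expect_error(add_entity(g, entity_record("if3", kind = "macromolecule")),
               class = "pg_error_duplicate_id")

  g <- add_entity(g, entity_record("mRNA", kind = "cellular_component"))
  g <- add_entity(g, entity_record("ggagg", "GGAGG", "sequence_feature",
                                   is_motif_of = "mRNA"))
  expect_equal(g$entities$is_motif_of[[3]], "mRNA")

  g <- add_entity(g, entity_record("s30", "30S", "macromolecule"))
  g <- add_entity(g, entity_record("cx", "30S-IF3 complex", "macromolecule"))
  g <- add_process(g, process_record("fix", "free 30S fixation", "elementary",
                                     inputs = c("if3", "s30"),
                                     outputs = "cx"))
  expect_equal(g$processes$inputs[[1]], c("if3", "s30"))
  expect_error(add_process(g, process_record("fix", kind = "elementary")),
               class = "pg_error_duplicate_id")
  # entity/process id namespaces are shared
  expect_error(add_process(g, process_record("if3", kind = "elementary")),
               class = "pg_error_duplicate_id")

  # aggregated process with empty composition is accepted here...
  g <- add_process(g, process_record("agg", kind = "aggregated"))
  expect_equal(nrow(g$processes), 2)
  # ...and rejected by validate_graph
  rep <- validate_graph(g)
  expect_true("aggregate_has_starter" %in% rep$rule)
  expect_true("aggregate_has_ender" %in% rep$rule)
})

test_that("ancestors computes the reflexive-transitive is_a closure", {
  g <- process_graph(
    entities = entity_record("if3", kind = "macromolecule"),
    is_a = tibble::tibble(child = "if3", parent = "chemical entity"))
  expect_setequal(ancestors(g, "if3"), c("if3", "chemical entity"))

  # diamond hierarchy, cross-checked against a brute-force edge expansion
  d <- process_graph(is_a = tibble::tibble(
    child = c("x", "x", "a", "b"), parent = c("a", "b", "r", "r")))
  expect_setequal(ancestors(d, "x"), oracle_ancestors(d, "x"))
  expect_setequal(ancestors(d, "x"), c("x", "a", "b", "r"))
  expect_setequal(ancestors(d, "r"), "r")

  expect_error(ancestors(g, "unknown"), class = "pg_error_unknown_id")
})

test_that("ancestors is monotone under is_a additions", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      nodes <- paste0("n", 1:8)
      g <- process_graph(is_a = tibble::tibble(
        child = nodes[2:8],
        parent = vapply(2:8, function(i) nodes[sample(i - 1, 1)],
                        character(1))))
      before <- lapply(nodes, function(n) ancestors(g, n))
      i <- sample(3:8, 1)
      g2 <- add_is_a(g, nodes[i], nodes[sample(i - 1, 1)])
      after <- lapply(nodes, function(n) ancestors(g2, n))
      for (k in seq_along(nodes)) {
        expect_true(all(before[[k]] %in% after[[k]]))
      }
    })
  }
})

test_that("validate_graph enforces the participant and composition axioms", {
  expect_equal(nrow(validate_graph(worked_example_30s())), 0)

  # an elementary process with only sequence-feature inputs violates the
  # "at least one chemical input" part of the axiom
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("m", kind = "sequence_feature"),
      entity_record("p", kind = "macromolecule")),
    processes = process_record("e", kind = "elementary", inputs = "m",
                               outputs = "p"))
  expect_true("elementary_some_chemical_input" %in% validate_graph(g)$rule)

  # cellular components may not participate at all
  g2 <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("cyt", kind = "cellular_component"),
      entity_record("a", kind = "macromolecule"),
      entity_record("b", kind = "macromolecule")),
    processes = process_record("e", kind = "elementary",
                               inputs = c("a", "cyt"), outputs = "b"))
  expect_true("elementary_only_chemical_or_feature" %in%
                validate_graph(g2)$rule)

  # smallest has_subprocess cycle
  g3 <- process_graph(processes = dplyr::bind_rows(
    process_record("a", kind = "aggregated", starts_with = "b",
                   ends_with = "b"),
    process_record("b", kind = "aggregated", starts_with = "a",
                   ends_with = "a")))
  expect_true("composition_acyclic" %in% validate_graph(g3)$rule)

  # is_a cycle
  g4 <- process_graph(is_a = tibble::tibble(child = c("a", "b"),
                                            parent = c("b", "a")))
  expect_true("is_a_acyclic" %in% validate_graph(g4)$rule)

  # binds_to must target sequence features
  g5 <- process_graph(entities = dplyr::bind_rows(
    entity_record("a", kind = "macromolecule", binds_to = "b"),
    entity_record("b", kind = "macromolecule")))
  expect_true("target_kind" %in% validate_graph(g5)$rule)

  # is_motif_of only on sequence features
  g6 <- process_graph(entities = dplyr::bind_rows(
    entity_record("a", kind = "macromolecule", is_motif_of = "m"),
    entity_record("m", kind = "sequence_feature")))
  expect_true("motif_kind" %in% validate_graph(g6)$rule)

  # dangling participant
  g7 <- process_graph(
    entities = entity_record("a", kind = "macromolecule"),
    processes = process_record("e", kind = "elementary", inputs = "a",
                               outputs = "ghost"))
  expect_true("dangling_reference" %in% validate_graph(g7)$rule)
})

test_that("branched endings and degenerate single-step aggregates are warnings", {
  base <- chain_parts(3, seed = 11)
  g <- add_process(base$graph,
                   process_record("agg", kind = "aggregated",
                                  starts_with = base$steps[1],
                                  ends_with = base$steps[2:3]))
  rep <- validate_graph(g)
  expect_true("aggregate_single_ender" %in% rep$rule)
  expect_equal(rep$severity[rep$rule == "aggregate_single_ender"], "warning")

  g2 <- add_process(chain_parts(1, seed = 12)$graph,
                    agg_record("solo", "proc_001"))
  rep2 <- validate_graph(g2)
  expect_equal(rep2$rule, "subprocess_roles_disjoint")
  expect_equal(rep2$severity, "warning")

  # overlap between other roles stays an error
  g3 <- add_process(base$graph,
                    process_record("agg", kind = "aggregated",
                                   starts_with = base$steps[1],
                                   intermediates = base$steps[1:2],
                                   ends_with = base$steps[3]))
  rep3 <- validate_graph(g3)
  expect_equal(rep3$severity[rep3$rule == "subprocess_roles_disjoint"],
               "error")
})

test_that("validation is deterministic, idempotent and dump/load stable", {
  g <- worked_example_30s()
  expect_identical(validate_graph(g), validate_graph(g))
  g2 <- load_native(dump_native(g))
  expect_equal(nrow(validate_graph(g2)), 0)

  bad <- process_graph(entities = entity_record("a", "", "macromolecule"))
  expect_identical(validate_graph(bad), validate_graph(bad))
  expect_true("label_nonempty" %in% validate_graph(bad)$rule)
})

test_that("binds_to edges are visible as located_in (sub-property semantics)", {
  g <- worked_example_30s()
  for (i in seq_len(nrow(g$entities))) {
    id <- g$entities$id[i]
    expect_true(all(g$entities$binds_to[[i]] %in% located_in_targets(g, id)))
  }
  expect_setequal(located_in_targets(g, "complex_preinit_RBS"), "rbs_motif")
})

test_that("minted identifiers follow the zero-padded pattern", {
  expect_equal(mint_ids(2), c("PG_00000001", "PG_00000002"))
  expect_equal(mint_ids(1, prefix = "KB", start = 42), "KB_00000042")
})
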