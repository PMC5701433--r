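worked <- worked_example_30s()
worked_agg <- "formation_30S_mRNA_complex"

test_that("precedes follows the shared intermediates of the worked example", {
  prec <- compute_precedes(worked, worked_agg)
  expect_equal(
    prec[order(match(prec$from, worked$processes$id)), ],
    tibble::tibble(
      from = c("free_30S_fixation", "a_site_hiding",
               "mrna_binding_preinitiation"),
      to = c("a_site_hiding", "mrna_binding_preinitiation",
             "mrna_scanning_start_codon")),
    ignore_attr = TRUE)
  expect_error(compute_precedes(worked, "free_30S_fixation"),
               class = "pg_error_wrong_kind")
})

test_that("sub-processes sharing no entity are unordered", {
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("a", kind = "macromolecule"),
      entity_record("b", kind = "macromolecule"),
      entity_record("c", kind = "macromolecule"),
      entity_record("d", kind = "macromolecule")),
    processes = dplyr::bind_rows(
      process_record("e1", kind = "elementary", inputs = "a", outputs = "b"),
      process_record("e2", kind = "elementary", inputs = "c", outputs = "d"),
      process_record("agg", kind = "aggregated", starts_with = "e1",
                     ends_with = "e2")))
  expect_equal(nrow(compute_precedes(g, "agg")), 0)
})

test_that("chains of length n yield exactly n-1 precedes pairs matching adjacency", {
  for (seed in c(3, 9, 27)) {
    n <- 4 + seed %% 4
    sim <- random_multiscale_graph(levels = 1, chain_length = n, seed = seed)
    top <- sim$truth$top
    prec <- compute_precedes(sim$graph, top)
    expect_equal(nrow(prec), n - 1)
    expect_equal(as.data.frame(prec),
                 as.data.frame(sim$truth$aggregates[[top]]$precedes))
    b <- saturate(sim$graph)
    expect_false(any(b$precedes$from == b$precedes$to))
  }
})

test_that("worked-example aggregate I/O matches the set-difference expectation", {
  io <- infer_io(worked, worked_agg)
  # Step-1 seeds: inputs of the starter
  expect_true(all(c("if3", "ribosome_30S") %in% io$inputs))
  expect_equal(io$inputs, sort(c("if3", "ribosome_30S", "if1", "rbs_motif",
                                 "start_codon_motif")))
  expect_equal(io$outputs, "complex_30S_initiation")
  # literal pairwise SWRL mode agrees on this chain
  expect_identical(infer_io(worked, worked_agg, mode = "strict_swrl"), io)
})

test_that("degenerate single-sub-process aggregates pass through the step I/O", {
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("a", kind = "macromolecule"),
      entity_record("b", kind = "macromolecule")),
    processes = dplyr::bind_rows(
      process_record("e", kind = "elementary", inputs = "a", outputs = "b"),
      agg_record("agg", "e")))
  for (mode in c("set_semantics", "strict_swrl")) {
    io <- infer_io(g, "agg", mode = mode)
    expect_equal(io$inputs, "a")
    expect_equal(io$outputs, "b")
  }
  expect_equal(infer_consumed(g, "agg"), character(0))
})

test_that("the worked example consumes exactly the three intermediate complexes", {
  expect_equal(infer_consumed(worked, worked_agg),
               sort(c("complex_30S_IF3", "complex_30S_IF3_IF1",
                      "complex_preinit_RBS")))
})

test_that("recycled entities are kept out of the consumed set by the guards", {
  # r is produced by the ending step and fed back to the starting step:
  # the p_ends/p_starts guards must exclude it
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("x", kind = "macromolecule"),
      entity_record("a", kind = "macromolecule"),
      entity_record("y", kind = "macromolecule"),
      entity_record("r", kind = "macromolecule")),
    processes = dplyr::bind_rows(
      process_record("e1", kind = "elementary", inputs = c("x", "r"),
                     outputs = "a"),
      process_record("e2", kind = "elementary", inputs = "a",
                     outputs = c("y", "r")),
      process_record("agg", kind = "aggregated", starts_with = "e1",
                     ends_with = "e2")))
  cons <- infer_consumed(g, "agg")
  expect_equal(cons, "a")
  expect_false("r" %in% cons)
  # cross-check with the literal brute-force rule evaluation
  expect_equal(cons, oracle_consumed(g, "agg", oracle_resolve_io(g)))
})

test_that("key elements are unmodified required reactants", {
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("S", kind = "small_molecule"),
      entity_record("P", kind = "small_molecule"),
      entity_record("E", kind = "macromolecule")),
    processes = process_record("rxn", kind = "elementary",
                               inputs = c("S", "E"), outputs = c("P", "E")))
  ke <- infer_key_elements(g)
  expect_equal(ke, tibble::tibble(process_id = "rxn", entity_id = "E"),
               ignore_attr = TRUE)
  # a small molecule in both sides only counts under the wider scope
  g2 <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("S", kind = "small_molecule"),
      entity_record("P", kind = "small_molecule"),
      entity_record("ion", kind = "small_molecule")),
    processes = process_record("rxn", kind = "elementary",
                               inputs = c("S", "ion"),
                               outputs = c("P", "ion")))
  expect_equal(nrow(infer_key_elements(g2)), 0)
  expect_equal(infer_key_elements(g2, scope = "all_chemicals")$entity_id,
               "ion")

  # no participant repeats within any worked-example step
  expect_equal(nrow(saturate(worked)$key_elements), 0)
})

test_that("a release-factor-like entity is key element of two distinct processes", {
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("rf", "class I translation release factor",
                    "macromolecule"),
      entity_record("a", kind = "macromolecule"),
      entity_record("b", kind = "macromolecule"),
      entity_record("c", kind = "macromolecule"),
      entity_record("d", kind = "macromolecule")),
    processes = dplyr::bind_rows(
      process_record("rescue", kind = "elementary", inputs = c("a", "rf"),
                     outputs = c("b", "rf")),
      process_record("termination", kind = "elementary",
                     inputs = c("c", "rf"), outputs = c("d", "rf"))))
  ke <- saturate(g)$key_elements
  expect_equal(key_element_of(ke, "rf"), c("rescue", "termination"))
})

test_that("functions of key elements affect the process and all higher levels", {
  base <- chain_parts(4, seed = 5, key_prob = 0)
  g <- base$graph
  g <- add_entity(g, entity_record("E", kind = "macromolecule",
                                   located_in = "cytosol",
                                   functions = "catalytic activity"))
  # attach E to the second step
  i <- match(base$steps[2], g$processes$id)
  g$processes$inputs[[i]] <- c(g$processes$inputs[[i]], "E")
  g$processes$outputs[[i]] <- c(g$processes$outputs[[i]], "E")
  g <- add_process(g, agg_record("B2", base$steps[1:2]))
  g <- add_process(g, agg_record("B2b", base$steps[3:4]))
  g <- add_process(g, agg_record("B1", c("B2", "B2b")))
  b <- saturate(g)
  aff <- b$affects
  expect_setequal(aff$process_id[aff$function_label == "catalytic activity"],
                  c(base$steps[2], "B2", "B1"))

  # an entity with no function contributes nothing
  g2 <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("S", kind = "small_molecule"),
      entity_record("P", kind = "small_molecule"),
      entity_record("E", kind = "macromolecule")),
    processes = process_record("rxn", kind = "elementary",
                               inputs = c("S", "E"), outputs = c("P", "E")))
  expect_equal(nrow(saturate(g2)$affects), 0)
})

test_that("saturate resolves nested aggregates bottom-up and is deterministic", {
  b <- saturate(worked)
  expect_equal(nrow(b$consumed), 3)
  expect_identical(tidy(b), tidy(saturate(worked)))

  sim <- sim_for_seed(77)
  b1 <- saturate(sim$graph)
  b2 <- saturate(sim$graph)
  expect_identical(tidy(b1), tidy(b2))

  # zero aggregates: only key elements (and affects) are populated
  g0 <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("S", kind = "small_molecule"),
      entity_record("P", kind = "small_molecule"),
      entity_record("E", kind = "macromolecule",
                    functions = "catalytic activity")),
    processes = process_record("rxn", kind = "elementary",
                               inputs = c("S", "E"), outputs = c("P", "E")))
  b0 <- saturate(g0)
  expect_equal(nrow(b0$io), 0)
  expect_equal(b0$key_elements$entity_id, "E")
  expect_equal(b0$affects$process_id, "rxn")

  # standalone operations on a nested aggregate need resolved sub-I/O
  g <- sim_for_seed(101)$graph
  nested <- g$processes$id[g$processes$kind == "aggregated"]
  top <- nested[vapply(nested, function(a) {
    any(nested %in% unlist(g$processes[match(a, g$processes$id),
                                       c("starts_with", "ends_with",
                                         "intermediates", "forks")]))
  }, logical(1))]
  if (length(top) > 0) {
    expect_error(infer_io(g, top[1]), class = "pg_error_unresolved_io")
  }
  expect_error(saturate(process_graph(
    processes = process_record("agg", kind = "aggregated"))),
    class = "pg_error_invalid_graph")
})

test_that("catalysts join inference only when catalysts_as_io is set", {
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("S", kind = "small_molecule", located_in = "cyt"),
      entity_record("P", kind = "small_molecule", located_in = "cyt"),
      entity_record("E", kind = "macromolecule", located_in = "cyt"),
      entity_record("cyt", kind = "cellular_component")),
    processes = process_record("rxn", kind = "elementary", inputs = "S",
                               outputs = "P", catalysts = "E"))
  expect_equal(nrow(saturate(g)$key_elements), 0)
  b <- saturate(g, catalysts_as_io = TRUE)
  expect_equal(b$key_elements$entity_id, "E")
})
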