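worked <- worked_example_30s()
worked_bundle <- saturate(worked)
worked_reactants <- classify_reactants(worked)

test_that("bridge rules tag reactants, chemicals, motifs and free/bound state", {
  r <- worked_reactants
  expect_setequal(reactant_tags(r, "if3"),
                  c("reactant", "chemical", "free_chemical"))
  # bound complexes inherit the motif localization via binds_to, hence are
  # not free even though no explicit located_in contradicts the cytosol
  expect_setequal(reactant_tags(r, "complex_preinit_RBS"),
                  c("reactant", "chemical", "bound_chemical"))
  expect_setequal(reactant_tags(r, "rbs_motif"),
                  c("reactant", "motif_entity"))
  # the mRNA and the cytosol participate in no process
  expect_equal(reactant_tags(r, "mRNA"), character(0))
  expect_equal(reactant_tags(r, "cytosol"), character(0))
})

test_that("free classification is closed-world and needs a cytosol entity", {
  g <- process_graph(
    entities = dplyr::bind_rows(
      entity_record("a", kind = "macromolecule"),
      entity_record("b", kind = "macromolecule")),
    processes = process_record("e", kind = "elementary", inputs = "a",
                               outputs = "b"))
  expect_error(classify_reactants(g), class = "pg_error_config")
  r <- classify_reactants(g, localization = FALSE)
  expect_false(any(r$free_chemical))

  # unlocalized chemicals satisfy "located_in ONLY cytosol" vacuously; the
  # default still refuses to call them free
  g2 <- add_entity(g, entity_record("cytosol", kind = "cellular_component"))
  r2 <- classify_reactants(g2)
  expect_false(any(r2$free_chemical))
  r3 <- classify_reactants(g2, vacuous_only_is_free = TRUE)
  expect_true(all(r3$free_chemical[r3$entity_id %in% c("a", "b")]))
})

test_that("adding a binds_to edge can only move an entity free -> bound", {
  for (seed in 1:10) {
    sim <- sim_for_seed(seed)
    g <- sim$graph
    r <- classify_reactants(g)
    free_ids <- r$entity_id[r$free_chemical]
    if (length(free_ids) == 0) next
    motifs <- g$entities$id[g$entities$kind == "sequence_feature"]
    if (length(motifs) == 0) {
      g <- add_entity(g, entity_record("m_extra", kind = "sequence_feature"))
      motifs <- "m_extra"
    }
    pick <- free_ids[1]
    i <- match(pick, g$entities$id)
    g$entities$binds_to[[i]] <- c(g$entities$binds_to[[i]], motifs[1])
    r2 <- classify_reactants(g)
    expect_true(r2$bound_chemical[r2$entity_id == pick])
    expect_false(r2$free_chemical[r2$entity_id == pick])
    # nothing previously bound became free
    expect_true(all(r$entity_id[r$bound_chemical] %in%
                      r2$entity_id[r2$bound_chemical]))
  }
})

test_that("modeled-process templates classify the worked example", {
  cats <- classify_processes(worked, worked_reactants, worked_bundle)
  expect_setequal(category_tags(cats, "free_30S_fixation"),
                  c("elementary_process", "elementary_chemical_process"))
  expect_setequal(category_tags(cats, "mrna_binding_preinitiation"),
                  c("elementary_process", "sequence_binding_process"))
  # the scanning step consumes a bound chemical: neither all-chemical nor
  # sequence-binding
  expect_setequal(category_tags(cats, "mrna_scanning_start_codon"),
                  "elementary_process")
  expect_setequal(category_tags(cats, "formation_30S_mRNA_complex"),
                  c("aggregated_process", "matrix_dependent_process"))
  # aggregated graphs need the bundle
  expect_error(classify_processes(worked, worked_reactants),
               class = "pg_error_unresolved_io")
})

test_that("the polymer-production ladder reaches transcription", {
  sim <- random_multiscale_graph(levels = 2, chain_length = 6,
                                 motif_prob = 1, seed = 13)
  b <- saturate(sim$graph)
  cats <- classify_processes(sim$graph, classify_reactants(sim$graph), b)
  top <- sim$truth$top
  tags <- category_tags(cats, top)
  expect_true(all(c("aggregated_process", "matrix_dependent_process",
                    "polymer_production_process",
                    "native_polymer_production_process",
                    "transcription_process") %in% tags))
  # hierarchy soundness on every process of every fixture
  for (seed in 1:15) {
    s2 <- sim_for_seed(seed)
    b2 <- saturate(s2$graph)
    c2 <- classify_processes(s2$graph, classify_reactants(s2$graph), b2)
    expect_true(all(!c2$transcription_process |
                      c2$native_polymer_production_process))
    expect_true(all(!c2$native_polymer_production_process |
                      c2$polymer_production_process))
    expect_true(all(!c2$polymer_production_process |
                      c2$matrix_dependent_process))
    expect_true(all(!c2$matrix_dependent_process | c2$aggregated_process))
  }
})

test_that("disjointness holds on random fixtures", {
  for (seed in 1:15) {
    sim <- sim_for_seed(seed)
    r <- classify_reactants(sim$graph)
    expect_false(any(r$free_chemical & r$bound_chemical))
    expect_false(any(r$chemical & r$motif_entity))
    b <- saturate(sim$graph)
    cats <- classify_processes(sim$graph, r, b)
    expect_false(any(cats$elementary_chemical_process &
                       cats$sequence_binding_process))
  }
})

test_that("classification agrees with the literal brute-force evaluator", {
  for (seed in c(2, 8, 21, 34)) {
    sim <- sim_for_seed(seed)
    g <- sim$graph
    io <- oracle_resolve_io(g)
    oc <- oracle_classify(g, io)
    b <- saturate(g)
    r <- classify_reactants(g)
    cats <- classify_processes(g, r, b)
    for (id in g$entities$id) {
      expect_setequal(reactant_tags(r, id), oc$entities[[id]])
    }
    for (id in g$processes$id) {
      expect_setequal(category_tags(cats, id), oc$processes[[id]])
    }
  }
})

test_that("rate-law templates are assigned from the registry", {
  cats <- classify_processes(worked, worked_reactants, worked_bundle)
  m <- assign_models(cats)
  a <- tidy(m)
  expect_equal(a$template[a$process_id == "free_30S_fixation"],
               "chemical reaction rate law")
  expect_equal(a$template[a$process_id == "mrna_binding_preinitiation"],
               "sequence binding rate law")
  expect_true(all(c("mrna_scanning_start_codon",
                    "formation_30S_mRNA_complex") %in% m$unmodeled))
  expect_equal(a$parameters[a$process_id == "free_30S_fixation"][[1]],
               c("forward rate constant", "backward rate constant"))

  bad <- tibble::tibble(category = "no_such_category", template = "x",
                        sbo_xref = NA_character_, parameters = list("k"))
  expect_error(assign_models(cats, bad), class = "pg_error_config")
})

test_that("a registry round-trips through YAML and JSON", {
  reg <- list(
    elementary_chemical_process = list(
      template_name = "chemical reaction rate law",
      parameters = list("forward rate constant")),
    sequence_binding_process = list(
      template_name = "sequence binding rate law",
      sbo_xref = "SBO:0000064",
      parameters = list("binding rate constant")))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(reg, yml)
  ry <- read_model_registry(yml)
  expect_equal(ry$template,
               c("chemical reaction rate law", "sequence binding rate law"))
  expect_equal(ry$sbo_xref[2], "SBO:0000064")
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(reg, jsn, auto_unbox = TRUE)
  expect_equal(read_model_registry(jsn)$parameters[[2]],
               "binding rate constant")
})
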