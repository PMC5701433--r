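# procgraph

Cellular processes — transcription, translation, complex assembly — are
naturally described as *interlocked systems*: an elementary reaction step
is a box defined by its inputs and outputs, and a higher-level process is
defined only by the composition of its sub-processes, down through as many
granularity levels as the curator needs. `procgraph` makes that systemic
description executable in R. It is aimed at systems biologists and
bio-ontology curators who want to author processes at the elementary level
and let the machine derive everything the composition implies.

Given a typed process knowledge graph (entities, elementary processes,
composition edges, an `is_a` hierarchy), the package saturates a small set
of forward-chaining rules:

* **precedes** — for sub-processes `p1`, `p2` of an aggregate:
  `out(p1) ∩ in(p2) ≠ ∅  ⇒  p1 precedes p2`.
* **aggregated I/O** — Step 1 seeds the aggregate with the inputs of its
  starting (and fork) sub-processes and the outputs of its ending
  sub-process; Step 2 adds every participant not produced (resp. not
  consumed) by a *different* sub-process of the same aggregate. The
  literal pairwise SWRL-style rule is available as mode `strict_swrl`.
* **consumes** — an entity output by one sub-process and input to another
  (producer not an ender, consumer not a starter) is a consumed
  intermediate and is excluded from the aggregate's own participants.
* **has_key_element** — a macromolecule that is both input and output of
  the same process (an enzyme, a release factor) is a key element.
* **affects** — molecular functions of key elements propagate to the
  process and to every aggregate of higher level.

A closed-world evaluator then maps processes onto rate-law templates via
description-logic class definitions, e.g.

```
elementary chemical process ≡ elementary process
                              AND has_input ONLY Chemical
                              AND has_output ONLY Chemical
sequence binding process    ≡ elementary process
                              AND has_input SOME Motif entity
                              AND has_input SOME FreeChemical
                              AND has_output SOME BoundChemical
                              AND has_input ONLY (Motif entity OR FreeChemical)
                              AND has_output ONLY BoundChemical
FreeChemical                ≡ Chemical AND located_in ONLY cytosol
BoundChemical               ≡ Chemical AND binds_to SOME Sequence feature
```

with the aggregated ladder `matrix dependent ⊐ polymer production ⊐
native polymer production ⊐ transcription / translation` evaluated over
the transitive `has_part` closure. Graphs round-trip through a native
JSON/YAML curation format and export to OWL 2 functional syntax with
OBO-style `hasDbXref` annotations and one typical individual per leaf
class.

## Worked example

The bundled fixture encodes the formation of the 30S–mRNA translation
initiation complex as a chain of four elementary steps (free 30S
fixation → A site hiding → mRNA binding, translation preinitiation →
mRNA scanning for start codon recognition) inside one aggregate:

```r
library(procgraph)
g <- worked_example_30s()
b <- saturate(g)
b$consumed
#> # A tibble: 3 × 2
#>   agg_id                     entity_id
#>   <chr>                      <chr>
#> 1 formation_30S_mRNA_complex complex_30S_IF3
#> 2 formation_30S_mRNA_complex complex_30S_IF3_IF1
#> 3 formation_30S_mRNA_complex complex_preinit_RBS

aggregate_io(b, "formation_30S_mRNA_complex")
#> $inputs
#> [1] "if1"               "if3"               "rbs_motif"
#> [4] "ribosome_30S"      "start_codon_motif"
#> $outputs
#> [1] "complex_30S_initiation"
```

The three complexes built and immediately consumed along the chain are
flagged `consumes` and disappear from the aggregate's own participants;
what remains is exactly what the overall process needs (two initiation
factors, the small ribosomal subunit, and the two mRNA sequence motifs)
and what it delivers (the initiation complex). Classification then
attaches rate-law templates:

```r
m <- assign_models(classify_processes(g, bundle = b))
tidy(m)[, c("process_id", "category", "template")]
#> # A tibble: 3 × 3
#>   process_id                 category                    template
#> 1 a_site_hiding              elementary_chemical_process chemical reaction rate law
#> 2 free_30S_fixation          elementary_chemical_process chemical reaction rate law
#> 3 mrna_binding_preinitiation sequence_binding_process    sequence binding rate law
m
#> <model_assignment> 3 process(es) modeled, 2 unmodeled
```

The scanning step consumes a bound chemical, so it matches neither
template and is reported unmodeled together with the aggregate — the
honest closed-world answer.

A command-line interface wraps the same workflows
(`validate` / `infer` / `classify` / `export-owl` / `demo` / `simulate`);
see `exec/procgraph`.

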