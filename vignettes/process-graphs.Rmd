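---
title: "Multi-scale process graphs: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale process graphs: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procgraph)
```

## The model

`procgraph` encodes the systemic view of cellular processes used in
whole-cell modeling. The knowledge base is a typed graph with four entity
kinds — small molecules, macromolecules (including complexes and
polymers), sequence features (motifs such as a ribosome binding site or a
start codon), and cellular components (compartments and the template
polymers that carry motifs) — and two process kinds:

* an **elementary process** is defined entirely by its participants: it
  must have at least one chemical input and one chemical output, and all
  participants must be chemical entities or sequence features;
* an **aggregated process** is defined only by the composition of its
  sub-processes through the roles `starts_with`, `has_intermediate_process`,
  `ends_with` and `has_fork_process` (several sub-processes may start an
  aggregate); its own participants are never authored — they are inferred.

Classes are organized in an `is_a` DAG with multiple inheritance;
abstract superclasses ("chemical entity", "primary transcript") may
appear as parents without a full record. `binds_to` is a sub-property of
`located_in`: a chemical bound to a motif is localized wherever the motif
is, and every inference and classification step treats a binding edge as
a localization edge. `cyclication_of` marks recycling arrows; they are
retained for export but excluded from all inference, including the
transitive `has_part` closure — recycling is bookkeeping about reuse, not
part of the productive decomposition.

Two spots in the representation are deliberately permissive and reported
as warnings rather than errors by `validate_graph()`: an aggregate with
more than one `ends_with` member (branched endings are unusual but not
contradictory), and the degenerate single-sub-process aggregate encoded
as `starts_with = ends_with = [p]`. The role lists are otherwise required
to be disjoint; the degenerate case is the one place where the
disjointness requirement and the requirement to have both a starter and
an ender cannot be met simultaneously, so it is tolerated with a warning
and the inference returns the step's own I/O.

## The inference rules

`saturate()` orders aggregates bottom-up along the composition DAG and
resolves each one from its direct children; a nested aggregate
contributes its *inferred* I/O to its parent, never its children's raw
participants. For one aggregate:

1. **Step 1 (seeds).** Inputs of every `starts_with` and fork sub-process
   become aggregate inputs; outputs of every `ends_with` sub-process
   become aggregate outputs. Seeds are unconditional: if a starter
   consumes something that another sub-process happens to produce, the
   seed still stands.
2. **precedes.** `p1` precedes `p2` when some entity is an output of `p1`
   and an input of `p2` (`p1 ≠ p2`).
3. **Step 2.** In the default `set_semantics` mode, an input of any
   sub-process joins the aggregate inputs iff no *different* sub-process
   of the same aggregate produces it; symmetrically for outputs. The
   "different" qualifier matters: an enzyme that is both input and output
   of the *same* step must surface at every level, and it does. The
   `strict_swrl` mode instead applies the literal pairwise rule over
   `precedes` pairs (any input of the successor differing from some shared
   intermediate). On linear chains with unique intermediates the two modes
   provably coincide; on convergent topologies (forks) the literal rule
   over-asserts — an intermediate covered by a non-adjacent producer is
   claimed as an aggregate input — which is why `set_semantics` is the
   normative default and `strict_swrl` a fidelity mode. The output side of
   Step 2 is implemented symmetrically to the input side.
4. **consumes.** An entity output by `p1` and input to `p2 ≠ p1` is a
   consumed intermediate, guarded by: `p1` is not *any* `ends_with`
   member, and `p2` is not *any* `starts_with` or fork member (forks
   start the aggregate, so they get the starter guard). The guards keep
   recycled cofactors — produced by the ender, fed back to the starter —
   out of the consumed set. Consumed intermediates of an inner aggregate
   stay attached to the level where they are consumed; they are not
   re-surfaced in outer levels, whose own consumed sets contain exactly
   the boundary intermediates between their direct children.
5. **Key elements and affects.** A key element is an entity appearing on
   both sides of the same process; the default scope restricts this to
   macromolecules (the catalytic reading), `all_chemicals` widens it to
   small molecules. Every molecular-function label carried by a key
   element affects the process and every aggregate whose `has_part`
   closure contains it.

Catalysts (`has_catalyst`) are stored but take no part in any rule by
default, because the rules are defined over inputs and outputs only. The
`catalysts_as_io` flag of `saturate()` expands each catalyst into both an
input and an output before inference, which makes catalysts behave as key
elements — a pragmatic extension, off by default.

## Closed-world classification

The bridge between the biological and the modeling view is evaluated
closed-world: universal (ONLY) restrictions are checked against the
explicitly listed participants and localizations. This is the semantics
that singleton instantiation gives an OWL reasoner — each leaf class
closed to one typical individual — and it is what makes `FreeChemical`
(`located_in ONLY cytosol`) decidable without closure axioms.

Two decisions here were genuinely open:

* A chemical with *no* localization satisfies `located_in ONLY cytosol`
  vacuously. Tagging unlocalized entities as free felt wrong for curation
  (most unlocalized entities are simply under-annotated), so at least one
  effective localization is required by default; the literal DL reading
  is available via `vacuous_only_is_free = TRUE`.
* `release_process` has no defining axiom, so it is a curator-declared
  tag on process records, and `native` (of "native polymer production")
  is a boolean flag defaulting to `TRUE`. Both are stopgaps and are
  flagged as such here.
* Aggregated processes are classified over their *inferred* I/O (the
  authored sets are empty by construction), and transcription/translation
  anchor on outputs whose `is_a` ancestors include the abstract classes
  `primary_transcript` / `pre_processed_polypeptide`.

Rate-law templates are symbolic stubs: the default registry maps
`elementary_chemical_process` to a "chemical reaction rate law" (forward
and backward rate constants) and `sequence_binding_process` to a
"sequence binding rate law" (binding rate constant). The registry is
configuration-driven (YAML/JSON); no kinetics are instantiated.

## The synthetic-data generator

`random_multiscale_graph()` emulates the structure the curation workflow
produces: an elementary chain with unique intermediates, optional fork
starters converging on the second step, motif-binding steps (motif +
free chemical → bound chemical), occasional enzymes (same macromolecule
on both sides of one step, carrying a molecular-function label), and
nested aggregates built by recursive bisection of the chain. Defaults —
chains of a handful of steps, one to three tiers, moderate motif and
enzyme probabilities — mirror the scale at which real curated processes
are decomposed (a translation-initiation chain has four steps).

Ground truth is computed constructively during generation, independently
of the inference engine: external inputs are the union of step inputs
minus internally produced intermediates, outputs are the final product
plus enzymes, consumed sets are the boundary intermediates between a
node's direct children, and categories follow from how each step was
built. One structural constraint is worth stating: under the
sequence-binding axiom, the product of a motif-binding step is a bound
chemical, and a bound input disqualifies the consumer from the
sequence-binding class — so two *consecutive* motif steps cannot both be
sequence-binding on a connected chain. The generator therefore never
draws consecutive motif steps, and with `motif_prob = 1` motif steps
occupy alternating positions. When any motif step is drawn, the final
step is tagged as a release process and the final product declared a
primary transcript, so generated graphs exercise the full
matrix-dependent → polymer-production → transcription ladder.

What the generator does *not* emulate: shared participants across
unrelated processes (ubiquitous metabolites like ATP or water appearing
in dozens of reactions), cyclic recycling arrows, branched endings, and
curation noise (dangling references, inconsistent kinds). Passing the
property suite therefore shows that the engine is correct on the
topologies the rules were designed for; it does not show robustness to
messy real-world curation beyond what `validate_graph()` rejects.

## Numerical and serialization choices

Everything is exact set computation; there are no tolerances. Ties and
ordering are resolved by canonical lexicographic sorting: bundles,
native JSON dumps and OWL exports are sorted by identifier so that
re-export is byte-identical and diffs are meaningful. The native format
is JSON on output (YAML accepted on input); OWL export uses functional
syntax precisely because it is deterministic and diffable, with property
IRIs reused from the Relation Ontology / BFO where they exist
(`RO_0000057`, `RO_0002233`, `RO_0002234`, `BFO_0000051`) and minted
locally otherwise. Identifier minting follows a zero-padded
`<prefix>_%08d` pattern. Individual names are sanitized label-style ids
prefixed `i_` / `s_` / `p_` for chemical entities, sequence features and
processes. A small grammar validator for the emitted functional-syntax
subset (`check_ofn()`) backs the serialization tests.

The test and acceptance sweeps use on the order of 1000 random graphs
for oracle equivalence, 200 chains for mode agreement, every cut point
of 25 chains for level-collapse invariance, and 100–120 seeds for
ground-truth recovery — sizes chosen so that each property is exercised
across all generator regimes (levels 1–3, chains of 2–7 steps, 0–2
forks, motif probabilities up to 0.6) while the whole suite stays
interactive.

## Known limitations

* No general rule language: the five rule families are built in.
* No tableau reasoning or consistency proof; validation is structural.
* OWL is export-only; ingesting arbitrary OWL releases would require an
  external conversion step to the native format.
* `has_template` is stored and exported but drives no inference — no
  rule in the implemented set mentions it.
* Whether an aggregate may mix elementary and aggregated sub-processes
  at one level is left open by the axioms; the engine allows it.
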