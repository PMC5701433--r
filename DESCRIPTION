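Package: procgraph
Title: Multi-Scale Process Knowledge Graphs with Rule-Based Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate and reason over multi-scale descriptions of
    cellular processes. Processes are encoded as typed knowledge graphs in
    which elementary reaction steps carry explicit inputs and outputs and
    aggregated processes are defined only by the composition of their
    sub-processes. Forward-chaining rules then derive the ordering of
    sub-processes, the effective inputs and outputs of every aggregate, the
    intermediates consumed along the way, the key (catalytic) participants,
    and the molecular functions affecting each level of the hierarchy.
    Closed-world evaluation of description-logic style class templates
    assigns processes to rate-law model templates with named parameter
    slots. Includes a native JSON/YAML curation format, an OWL 2 functional
    syntax exporter, deterministic fixture generators with constructive
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
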