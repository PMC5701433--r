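# Rate-law template registry: category -> symbolic mathematical-expression
# template with named parameter slots. Templates are symbolic stubs (no
# kinetics are instantiated); the registry is configuration-driven and can
# be loaded from YAML or JSON.

#' Default rate-law template registry
#'
#' Maps `elementary_chemical_process` to the "chemical reaction rate law"
#' and `sequence_binding_process` to the "sequence binding rate law", each
#' with conventional parameter slots. Extend or replace via
#' [read_model_registry()].
#'
#' @return A tibble with columns `category`, `template`, `sbo_xref`,
#'   `parameters` (list of character vectors).
#' @export
default_model_registry <- function() {
  tibble(
    category = c("elementary_chemical_process", "sequence_binding_process"),
    template = c("chemical reaction rate law", "sequence binding rate law"),
    sbo_xref = c(NA_character_, NA_character_),
    parameters = list(
      c("forward rate constant", "backward rate constant"),
      c("binding rate constant")
    )
  )
}

#' Read a template registry from YAML or JSON
#'
#' The document maps category names to objects with fields
#' `template_name`, optional `sbo_xref`, and `parameters` (list of slot
#' names).
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A registry tibble as in [default_model_registry()].
#' @export
read_model_registry <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (length(doc) == 0) {
    return(default_model_registry()[0, ])
  }
  tibble(
    category = names(doc),
    template = unname(map_chr(doc, ~ .x$template_name %||%
                                pg_abort("registry entry lacks template_name",
                                         "pg_error_config"))),
    sbo_xref = unname(map_chr(doc, ~ .x$sbo_xref %||% NA_character_)),
    parameters = unname(map(doc, ~ as.character(unlist(.x$parameters %||%
                                                         character(0)))))
  )
}

#' Assign rate-law templates to classified processes
#'
#' Every process carrying a registry-mapped category receives the
#' template(s) and their parameter slots; processes with no mapped
#' category are reported as unmodeled.
#'
#' @param categories A [classify_processes()] table.
#' @param registry A registry tibble (see [default_model_registry()]).
#' @return A `model_assignment` object: list with `assigned` (tibble
#'   `process_id`, `category`, `template`, `sbo_xref`, `parameters`) and
#'   `unmodeled` (character vector of process ids).
#' @export
assign_models <- function(categories, registry = default_model_registry()) {
  bad <- setdiff(registry$category, PROCESS_CATEGORIES)
  if (length(bad) > 0) {
    pg_abort(sprintf("registry references unknown categor%s: %s",
                     if (length(bad) > 1) "ies" else "y",
                     paste(bad, collapse = ", ")), "pg_error_config")
  }
  long <- tidyr::pivot_longer(categories, -"process_id",
                              names_to = "category", values_to = "holds")
  long <- filter(long, .data$holds)
  assigned <- dplyr::inner_join(long[c("process_id", "category")], registry,
                                by = "category")
  assigned <- arrange(assigned, .data$process_id, .data$category)
  structure(list(
    assigned = assigned,
    unmodeled = sort(setdiff(categories$process_id, assigned$process_id))
  ), class = "model_assignment")
}

#' @export
print.model_assignment <- function(x, ...) {
  cat(sprintf("<model_assignment> %d process(es) modeled, %d unmodeled\n",
              length(unique(x$assigned$process_id)), length(x$unmodeled)))
  invisible(x)
}
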