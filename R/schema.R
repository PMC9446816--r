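#' The eight-type semantic relation schema
#'
#' Builds the canonical label schema used throughout the package: eight
#' relation labels organised in a three-level hierarchy (causality,
#' direction of causality, explicit expressions of quantity), the set of
#' labels treated as negative examples, and the twelve biomedical entity
#' types.
#'
#' The hierarchy is a forest of depth three. \code{directed_link} splits by
#' causal polarity into \code{positive_cause} and \code{negative_cause};
#' each of those splits again when the sentence states an explicit quantity
#' change in the object entity: \code{positive_cause} into
#' \code{positive_increase} / \code{negative_decrease}, and
#' \code{negative_cause} into \code{positive_decrease} /
#' \code{negative_increase}. \code{undirected_link} (correlation without
#' causality) is a root with no children and is the schema's negative class.
#'
#' @return An object of class \code{relation_schema}: a list with elements
#'   \code{relation_labels} (character, length 8, canonical snake_case,
#'   fixed order), \code{parent_of} (named character; \code{NA} for roots),
#'   \code{negative_labels} (character), and \code{entity_types}
#'   (character, length 12).
#' @examples
#' sch <- relation_schema()
#' sch$parent_of[["positive_increase"]]
#' @export
relation_schema <- function() {
  labels <- c(
    "undirected_link", "directed_link",
    "positive_cause", "negative_cause",
    "positive_increase", "negative_decrease",
    "positive_decrease", "negative_increase"
  )
  parent <- c(
    undirected_link   = NA_character_,
    directed_link     = NA_character_,
    positive_cause    = "directed_link",
    negative_cause    = "directed_link",
    positive_increase = "positive_cause",
    negative_decrease = "positive_cause",
    positive_decrease = "negative_cause",
    negative_increase = "negative_cause"
  )
  types <- c(
    "biological_process", "cell", "compound", "dna", "enzyme", "gene",
    "hormone", "molecular_function", "phenotype", "protein", "rna", "virus"
  )
  structure(
    list(
      relation_labels = labels,
      parent_of = parent,
      negative_labels = "undirected_link",
      entity_types = types
    ),
    class = "relation_schema"
  )
}

#' @export
print.relation_schema <- function(x, ...) {
  cat("Semantic relation schema: 8 relation labels, 12 entity types\n")
  roots <- names(x$parent_of)[is.na(x$parent_of)]
  for (r in roots) {
    cat("  ", r, "\n", sep = "")
    kids <- names(x$parent_of)[!is.na(x$parent_of) & x$parent_of == r]
    for (k in kids) {
      cat("    ", k, "\n", sep = "")
      gk <- names(x$parent_of)[!is.na(x$parent_of) & x$parent_of == k]
      if (length(gk)) cat("      ", paste(gk, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Normalize a relation label or entity type to its canonical form
#'
#' Display forms such as \code{"Positive Cause"} or \code{"BIOLOGICAL
#' PROCESS"} are lower-cased and their separators collapsed to underscores.
#'
#' @param x character vector of label or type names in any display form.
#' @return character vector of canonical snake_case names (not validated
#'   against the schema; see \code{\link{validate_instance}}).
#' @export
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ \\-]+", "_", x)
  x
}

#' Parent of a relation label in the three-level hierarchy
#'
#' @param label a relation label (canonical or display form).
#' @param schema a \code{\link{relation_schema}}.
#' @return The parent label, or \code{NA} for the two root labels
#'   (\code{undirected_link}, \code{directed_link}).
#' @examples
#' label_parent("positive_increase")  # "positive_cause"
#' @export
label_parent <- function(label, schema = relation_schema()) {
  label <- normalize_label(label)
  if (!label %in% schema$relation_labels) {
    stop("unknown relation label: '", label, "'", call. = FALSE)
  }
  unname(schema$parent_of[[label]])
}

#' Collapse an eight-type label to the binary positive/negative scheme
#'
#' \code{undirected_link} — correlation with no causality revealed — is the
#' negative class; the seven causal labels are positive.
#'
#' @inheritParams label_parent
#' @return \code{"positive"} or \code{"negative"}.
#' @examples
#' collapse_to_binary("undirected_link")   # "negative"
#' collapse_to_binary("Positive Cause")    # "positive"
#' @export
collapse_to_binary <- function(label, schema = relation_schema()) {
  label <- normalize_label(label)
  if (!label %in% schema$relation_labels) {
    stop("unknown relation label: '", label, "'", call. = FALSE)
  }
  if (label %in% schema$negative_labels) "negative" else "positive"
}
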