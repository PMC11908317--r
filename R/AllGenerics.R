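#' Ancestors of a term
#'
#' Transitive closure over is-a edges, child to parent. Excludes the term
#' itself unless `includeSelf = TRUE`.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a term id present in the graph.
#' @param includeSelf include the query term itself?
#' @return character vector of term ids.
#' @export
setGeneric("termAncestors", function(graph, term, includeSelf = FALSE)
  standardGeneric("termAncestors"))

#' Descendants of a term
#'
#' @inheritParams termAncestors
#' @return character vector of term ids.
#' @export
setGeneric("termDescendants", function(graph, term, includeSelf = FALSE)
  standardGeneric("termDescendants"))

#' Evaluate a variant predicate on a variant record
#'
#' @param pred a [VariantPredicate-class].
#' @param variant a [VariantRecord-class].
#' @return `TRUE` or `FALSE`.
#' @export
setGeneric("evaluatePredicate", function(pred, variant)
  standardGeneric("evaluatePredicate"))

#' Assign an individual to a genotype class
#'
#' @param classifier a [GenotypeClassifier-class].
#' @param individual an [Individual-class].
#' @return the class label, or `NA_character_` if the individual is omitted.
#' @export
setGeneric("assignClass", function(classifier, individual)
  standardGeneric("assignClass"))

#' @rdname individuals
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname gpcResults
#' @export
setGeneric("gpcResults", function(x) standardGeneric("gpcResults"))

#' @rdname gpcResults
#' @export
setGeneric("filterDecisions", function(x) standardGeneric("filterDecisions"))
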