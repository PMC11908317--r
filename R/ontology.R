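#' Construct an ontology graph from terms and is-a edges
#'
#' Low-level constructor used by [loadOntology()] and [makeToyOntology()].
#'
#' @param terms character vector of term ids.
#' @param labels character vector of labels, parallel to `terms`.
#' @param edges two-column matrix or data.frame of (child, parent) term ids.
#' @param root the phenotypic-abnormality subroot term id.
#' @return an [OntologyGraph-class].
#' @export
ontologyGraph <- function(terms, labels = terms, edges, root) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L && length(edges) != 0L)
    stop("edges must have two columns (child, parent)")
  storage.mode(edges) <- "character"
  unknown <- setdiff(as.vector(edges), terms)
  if (length(unknown))
    stop("edge endpoint(s) not declared as terms: ",
         paste(unique(unknown), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    fas <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, fas[1])
    stop("cycle detected in is-a edges, involving edge ",
         ends[1], " -> ", ends[2])
  }
  names(labels) <- terms
  new("OntologyGraph", graph = g, labels = labels, root = root)
}

#' Load an ontology from a JSON document
#'
#' Two dialects are recognized. The toy dialect is
#' `{"root": id, "terms": [{"id", "label"}], "edges": [[child, parent], ...]}`.
#' The OBO-graph dialect (as used by `hp.json`) is `graphs[0].nodes` /
#' `graphs[0].edges` with predicate `is_a`; node IRIs are converted to CURIEs,
#' deprecated nodes are dropped and alternative ids are resolved to primary
#' ids when the document provides the mapping.
#'
#' @param x path to a JSON file, or an already-parsed list.
#' @param root optional root term id, overriding the document's declaration
#'   (required for OBO-graph documents, where the phenotypic-abnormality
#'   subroot is conventionally `HP:0000118`).
#' @return an [OntologyGraph-class].
#' @export
loadOntology <- function(x, root = NULL) {
  doc <- if (is.character(x)) {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else {
    x
  }
  if (!is.null(doc$graphs)) {
    loadOboGraph(doc, root %||% "HP:0000118")
  } else if (!is.null(doc$terms)) {
    loadToyOntology(doc, root)
  } else {
    stop("unrecognized ontology document: expected toy dialect or OBO-graph JSON")
  }
}

loadToyOntology <- function(doc, root = NULL) {
  terms <- vapply(doc$terms, function(t) t$id, character(1))
  labels <- vapply(doc$terms, function(t) t$label %||% t$id, character(1))
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) c(e[[1]], e[[2]])))
  } else {
    matrix(character(), ncol = 2)
  }
  root <- root %||% doc$root
  if (is.null(root)) stop("ontology document declares no root")
  if (!(root %in% terms)) stop("declared root ", root, " is not a member term")
  ontologyGraph(terms, labels, edges, root)
}

iriToCurie <- function(x) {
  sub("^.*[/#]([A-Za-z]+)_([0-9]+)$", "\\1:\\2", x)
}

loadOboGraph <- function(doc, root) {
  gr <- doc$graphs[[1]]
  keep <- vapply(gr$nodes, function(n) {
    is.null(n$meta$deprecated) || !isTRUE(n$meta$deprecated)
  }, logical(1))
  nodes <- gr$nodes[keep]
  ids <- vapply(nodes, function(n) iriToCurie(n$id), character(1))
  labels <- vapply(nodes, function(n) n$lbl %||% iriToCurie(n$id), character(1))
  # alternative-id mapping, when provided in node metadata
  altMap <- character()
  for (i in seq_along(nodes)) {
    bpv <- nodes[[i]]$meta$basicPropertyValues
    for (p in bpv) {
      if (grepl("hasAlternativeId", p$pred %||% ""))
        altMap[iriToCurie(p$val)] <- ids[i]
    }
  }
  isA <- Filter(function(e) (e$pred %||% "") %in% c("is_a", "subClassOf"),
                gr$edges)
  resolve <- function(x) {
    x <- iriToCurie(x)
    ifelse(x %in% names(altMap), unname(altMap[x]), x)
  }
  edges <- do.call(rbind, lapply(isA, function(e) c(resolve(e$sub),
                                                    resolve(e$obj))))
  inSet <- edges[, 1] %in% ids & edges[, 2] %in% ids
  ontologyGraph(ids, labels, edges[inSet, , drop = FALSE], root)
}

#' @describeIn termAncestors reachability over child-to-parent edges.
setMethod("termAncestors", "OntologyGraph", function(graph, term, includeSelf = FALSE) {
  reachable(graph, term, mode = "out", includeSelf = includeSelf)
})

#' @describeIn termDescendants reachability over parent-to-child edges.
setMethod("termDescendants", "OntologyGraph", function(graph, term, includeSelf = FALSE) {
  reachable(graph, term, mode = "in", includeSelf = includeSelf)
})

reachable <- function(graph, term, mode, includeSelf) {
  checkTerms(graph, term)
  out <- igraph::subcomponent(graph@graph, term, mode = mode)$name
  if (!includeSelf) out <- setdiff(out, term)
  out
}

checkTerms <- function(graph, terms) {
  missing <- setdiff(terms, igraph::V(graph@graph)$name)
  if (length(missing))
    stop("term(s) not in ontology: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Term ids of an ontology
#' @param graph an [OntologyGraph-class].
#' @return character vector of all term ids.
#' @export
ontologyTerms <- function(graph) igraph::V(graph@graph)$name

#' Phenotypic-abnormality subroot of an ontology
#' @param graph an [OntologyGraph-class].
#' @export
ontologyRoot <- function(graph) graph@root

#' Labels for term ids
#' @param graph an [OntologyGraph-class].
#' @param terms term ids.
#' @return character vector of labels (id itself when no label is known).
#' @export
termLabel <- function(graph, terms) {
  out <- graph@labels[terms]
  out[is.na(out)] <- terms[is.na(out)]
  unname(out)
}

termChildren <- function(graph, term) {
  checkTerms(graph, term)
  nb <- igraph::neighbors(graph@graph, term, mode = "in")
  nb$name
}

#' Propagate observed and excluded annotations (true path rule)
#'
#' Every observed annotation implies observation of all ancestor terms; every
#' excluded annotation implies exclusion of all descendant terms (excluding a
#' general term excludes all its specializations). A term reached by both
#' closures -- necessarily from distinct source annotations -- is flagged
#' `"conflict"` and should be dropped from that individual's analyzable set.
#'
#' @param graph an [OntologyGraph-class].
#' @param phenotypes data.frame with columns `term` and `status`
#'   (`"observed"`/`"excluded"`), e.g. the `phenotypes` slot of an
#'   [Individual-class].
#' @return data.frame with columns `term` and `status`
#'   (`"observed"`, `"excluded"` or `"conflict"`).
#' @export
propagateAnnotations <- function(graph, phenotypes) {
  checkTerms(graph, phenotypes$term)
  obsSrc <- phenotypes$term[phenotypes$status == "observed"]
  excSrc <- phenotypes$term[phenotypes$status == "excluded"]
  obs <- unique(unlist(lapply(obsSrc, function(t)
    termAncestors(graph, t, includeSelf = TRUE))))
  exc <- unique(unlist(lapply(excSrc, function(t)
    termDescendants(graph, t, includeSelf = TRUE))))
  obs <- as.character(obs %||% character())
  exc <- as.character(exc %||% character())
  both <- intersect(obs, exc)
  status <- c(
    stats::setNames(rep("observed", length(setdiff(obs, both))), setdiff(obs, both)),
    stats::setNames(rep("excluded", length(setdiff(exc, both))), setdiff(exc, both)),
    stats::setNames(rep("conflict", length(both)), both)
  )
  if (!length(status)) {
    return(data.frame(term = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(term = names(status), status = unname(status),
                    stringsAsFactors = FALSE)
  out <- out[order(out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", length(ontologyTerms(object)), "terms,",
      igraph::ecount(object@graph), "is-a edges\n")
  cat("  root:", object@root, "(", termLabel(object, object@root), ")\n")
})
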