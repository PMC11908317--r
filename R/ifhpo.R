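#' Per-term, per-class observed/excluded counts
#'
#' Assigns each individual to a genotype class, propagates its annotations
#' by the true path rule, and tallies per HPO term and class how many
#' individuals observed vs excluded the term. Conflicting statuses are
#' dropped from the individual's analyzable set; terms are restricted to the
#' phenotypic-abnormality subroot and its descendants; terms never annotated
#' in the cohort do not appear at all.
#'
#' @param cohort a [Cohort-class].
#' @param graph an [OntologyGraph-class].
#' @param classifier a [GenotypeClassifier-class].
#' @return list with `counts` (data.frame `term`, `class`, `nObserved`,
#'   `nExcluded`, complete over annotated terms x classes), `classes`
#'   (labels in classifier order), `nClassified` (individuals in a class)
#'   and `assignment` (the [classifyCohort()] table).
#' @export
phenotypeCounts <- function(cohort, graph, classifier) {
  assignment <- classifyCohort(cohort, classifier)
  labs <- classLabels(classifier)
  scope <- c(graph@root, termDescendants(graph, graph@root))
  tally <- new.env(parent = emptyenv())
  for (i in seq_along(cohort@individuals)) {
    cls <- assignment$class[i]
    if (cls == "OMITTED") next
    prop <- propagateAnnotations(graph, cohort@individuals[[i]]@phenotypes)
    prop <- prop[prop$term %in% scope & prop$status != "conflict", , drop = FALSE]
    for (j in seq_len(nrow(prop))) {
      key <- paste0(prop$term[j], "\r", cls, "\r", prop$status[j])
      tally[[key]] <- (tally[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(tally)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    long <- data.frame(term = parts[, 1], class = parts[, 2],
                       status = parts[, 3],
                       n = vapply(keys, function(k) tally[[k]], integer(1)),
                       stringsAsFactors = FALSE)
    terms <- sort(unique(long$term))
    grid <- expand.grid(term = terms, class = labs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pick <- function(status) {
      sub <- long[long$status == status, , drop = FALSE]
      idx <- match(paste0(grid$term, "\r", grid$class),
                   paste0(sub$term, "\r", sub$class))
      ifelse(is.na(idx), 0L, sub$n[idx])
    }
    counts <- data.frame(grid, nObserved = pick("observed"),
                         nExcluded = pick("excluded"),
                         stringsAsFactors = FALSE)
  } else {
    counts <- data.frame(term = character(), class = character(),
                         nObserved = integer(), nExcluded = integer())
  }
  list(counts = counts, classes = labs,
       nClassified = sum(assignment$class != "OMITTED"),
       assignment = assignment)
}

#' Configuration of the independent-filtering heuristic
#'
#' Thresholds of the rule-based pre-test filter (IF-HPO). Defaults: a term
#' must be assayed (observed or excluded, after propagation) in at least 40%
#' of the cohort; a 2x2 contingency table needs at least 7 assayed
#' individuals in total and a 3x2 table at least 6, below which no table can
#' reach nominal significance.
#'
#' @param minCoverage minimum assayed fraction of the cohort, in (0, 1].
#' @param minTotal2x2 minimum total assayed count for two genotype classes.
#' @param minTotal3x2 minimum total assayed count for three genotype classes.
#' @param generalLevelDepth how many levels below the phenotypic-abnormality
#'   subroot count as "general" and are skipped (1 = the root and its direct
#'   children).
#' @param coverageObservedOnly count only observed (not excluded)
#'   annotations toward coverage.
#' @return a list of class `IfHpoConfig`.
#' @export
ifHpoConfig <- function(minCoverage = 0.4, minTotal2x2 = 7L, minTotal3x2 = 6L,
                        generalLevelDepth = 1L, coverageObservedOnly = FALSE) {
  stopifnot(minCoverage > 0, minCoverage <= 1,
            minTotal2x2 >= 1L, minTotal3x2 >= 1L, generalLevelDepth >= 0L)
  structure(list(minCoverage = minCoverage,
                 minTotal2x2 = as.integer(minTotal2x2),
                 minTotal3x2 = as.integer(minTotal3x2),
                 generalLevelDepth = as.integer(generalLevelDepth),
                 coverageObservedOnly = coverageObservedOnly),
            class = "IfHpoConfig")
}

#' Decide per HPO term whether a categorical test is performed
#'
#' The independent-filtering heuristic: five rules applied in a fixed order,
#' each skip attributed to the first matching rule, all decided from counts
#' and graph structure alone -- no p-value is ever consulted, which is what
#' keeps the filter independent of the test statistic under the null.
#'
#' 1. `GENERAL_LEVEL`: the phenotypic-abnormality subroot and its direct
#'    children (depth configurable) carry little specific information.
#' 2. `SAME_AS_CHILD`: a parent whose per-class observed/excluded counts are
#'    identical to one of its annotated children would give the identical
#'    test result; the more specific child is kept.
#' 3. `LOW_COVERAGE`: assayed in less than `minCoverage` of the cohort.
#' 4. `UNDERPOWERED_TOTAL`: total assayed count below 7 (two classes) or
#'    6 (three classes) can never reach significance.
#' 5. `EMPTY_GENOTYPE_CLASS`: a genotype class with neither observed nor
#'    excluded annotations for the term.
#'
#' @param counts the `counts` data.frame from [phenotypeCounts()] (or any
#'   data.frame with columns `term`, `class`, `nObserved`, `nExcluded`).
#' @param graph an [OntologyGraph-class].
#' @param cohortSize denominator for the coverage rule (typically the number
#'   of genotype-classified individuals).
#' @param config an [ifHpoConfig()].
#' @return data.frame with columns `term`, `tested` (logical) and `reason`
#'   (`TESTED` or the skip-rule code), one row per annotated term, ordered
#'   by term id.
#' @export
selectTestableTerms <- function(counts, graph, cohortSize,
                                config = ifHpoConfig()) {
  terms <- sort(unique(counts$term))
  checkTerms(graph, terms)
  classes <- unique(counts$class)
  nClasses <- length(classes)
  minTotal <- if (nClasses <= 2L) config$minTotal2x2 else config$minTotal3x2

  general <- igraph::ego(graph@graph, order = config$generalLevelDepth,
                         nodes = graph@root, mode = "in")[[1]]$name

  countVec <- function(term) {
    sub <- counts[counts$term == term, , drop = FALSE]
    sub <- sub[match(classes, sub$class), , drop = FALSE]
    c(rbind(sub$nObserved, sub$nExcluded))
  }
  vecs <- lapply(terms, countVec)
  names(vecs) <- terms

  decide <- function(term) {
    v <- vecs[[term]]
    if (term %in% general) return("GENERAL_LEVEL")
    kids <- intersect(termChildren(graph, term), terms)
    for (k in kids) if (identical(v, vecs[[k]])) return("SAME_AS_CHILD")
    assayed <- if (config$coverageObservedOnly)
      sum(v[seq(1, length(v), by = 2)]) else sum(v)
    if (assayed / cohortSize < config$minCoverage) return("LOW_COVERAGE")
    if (sum(v) < minTotal) return("UNDERPOWERED_TOTAL")
    perClass <- v[seq(1, length(v), by = 2)] + v[seq(2, length(v), by = 2)]
    if (any(perClass == 0L)) return("EMPTY_GENOTYPE_CLASS")
    "TESTED"
  }

  reason <- vapply(terms, decide, character(1))
  data.frame(term = terms, tested = reason == "TESTED", reason = unname(reason),
             stringsAsFactors = FALSE)
}

#' Write the independent-filtering ledger as TSV
#'
#' The "MTC filter report": per term the verdict, skip reason and per-class
#' observed/assayed counts.
#'
#' @param decisions output of [selectTestableTerms()].
#' @param counts the matching `counts` data.frame from [phenotypeCounts()].
#' @param graph an [OntologyGraph-class] (for labels).
#' @param path output TSV path.
#' @export
writeFilterReport <- function(decisions, counts, graph, path) {
  out <- decisions
  out$label <- termLabel(graph, out$term)
  for (cls in unique(counts$class)) {
    sub <- counts[counts$class == cls, , drop = FALSE]
    idx <- match(out$term, sub$term)
    out[[paste0("observed_", cls)]] <- sub$nObserved[idx]
    out[[paste0("assayed_", cls)]] <- sub$nObserved[idx] + sub$nExcluded[idx]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
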