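#' Categorical genotype-phenotype association analysis
#'
#' The full categorical workflow: assign genotype classes, propagate
#' annotations, select the hypotheses to test (by the independent-filtering
#' heuristic, a user-supplied term list, or all annotated terms), run a
#' Fisher exact test per term on the k x 2 observed/excluded table, and
#' adjust across exactly the tests performed. Results are sorted by
#' adjusted p-value.
#'
#' @param cohort a [Cohort-class].
#' @param graph an [OntologyGraph-class].
#' @param classifier a [GenotypeClassifier-class] yielding 2 or 3 classes.
#' @param config an [ifHpoConfig()] (used in `"ifhpo"` mode).
#' @param mtcMethod multiple-testing method, see [adjustPvalues()].
#' @param alpha significance threshold on the adjusted p-value.
#' @param mode `"ifhpo"` (default), `"specified"` (test exactly `terms`) or
#'   `"all"` (every annotated term).
#' @param terms term ids for `"specified"` mode.
#' @return a [GpcResultSet-class] of kind `"categorical"`: `results` one row
#'   per performed test, `decisions` the complete filter ledger, `meta` the
#'   class assignment and configuration echo.
#' @export
runCategorical <- function(cohort, graph, classifier,
                           config = ifHpoConfig(), mtcMethod = "BH",
                           alpha = 0.05, mode = c("ifhpo", "specified", "all"),
                           terms = NULL) {
  mode <- match.arg(mode)
  pc <- phenotypeCounts(cohort, graph, classifier)
  counts <- pc$counts
  annotated <- sort(unique(counts$term))

  decisions <- switch(mode,
    ifhpo = selectTestableTerms(counts, graph, pc$nClassified, config),
    specified = {
      if (is.null(terms)) stop("mode 'specified' requires terms")
      checkTerms(graph, terms)
      data.frame(term = sort(unique(terms)),
                 tested = sort(unique(terms)) %in% annotated,
                 reason = ifelse(sort(unique(terms)) %in% annotated,
                                 "TESTED", "EMPTY_GENOTYPE_CLASS"),
                 stringsAsFactors = FALSE)
    },
    all = data.frame(term = annotated, tested = TRUE, reason = "TESTED",
                     stringsAsFactors = FALSE)
  )

  labs <- pc$classes
  testTerm <- function(term) {
    sub <- counts[counts$term == term, , drop = FALSE]
    sub <- sub[match(labs, sub$class), , drop = FALSE]
    tab <- cbind(observed = sub$nObserved, excluded = sub$nExcluded)
    fisherExactTest(tab)
  }

  tested <- decisions$term[decisions$tested]
  meta <- list(assignment = pc$assignment, classes = labs,
               nClassified = pc$nClassified, mode = mode,
               mtcMethod = mtcMethod, alpha = alpha, config = config)
  if (!length(tested)) {
    results <- data.frame(term = character(), label = character(),
                          p_raw = numeric(), p_adjusted = numeric(),
                          significant = logical())
    return(new("GpcResultSet", kind = "categorical", results = results,
               decisions = decisions, meta = meta))
  }

  pRaw <- vapply(tested, testTerm, numeric(1))
  pAdj <- adjustPvalues(pRaw, mtcMethod, alpha = alpha)
  results <- data.frame(term = tested, label = termLabel(graph, tested),
                        p_raw = unname(pRaw), p_adjusted = unname(pAdj),
                        significant = unname(pAdj) < alpha,
                        stringsAsFactors = FALSE)
  for (cls in labs) {
    sub <- counts[counts$class == cls, , drop = FALSE]
    idx <- match(results$term, sub$term)
    results[[paste0("observed_", cls)]] <- sub$nObserved[idx]
    results[[paste0("assayed_", cls)]] <- sub$nObserved[idx] + sub$nExcluded[idx]
  }
  results <- results[order(results$p_adjusted, results$p_raw, results$term), ,
                     drop = FALSE]
  rownames(results) <- NULL
  new("GpcResultSet", kind = "categorical", results = results,
      decisions = decisions, meta = meta)
}

#' Compare a numeric measurement between two genotype classes
#'
#' Collects the values of one coded assay (e.g. a LOINC code) across the
#' cohort and compares class means with an unpaired two-sided t-test.
#' Individuals without the measurement, or omitted by the classifier, are
#' counted in the exclusion tally; missing data are never imputed. No
#' multiple-testing correction is applied (each measurement is a distinct
#' hypothesis).
#'
#' @param cohort a [Cohort-class].
#' @param classifier a two-class [GenotypeClassifier-class].
#' @param assay measurement code to test.
#' @param welch use the Welch unequal-variance form.
#' @param alpha significance threshold.
#' @return a [GpcResultSet-class] of kind `"measurement"`.
#' @export
runContinuous <- function(cohort, classifier, assay, welch = FALSE,
                          alpha = 0.05) {
  assignment <- classifyCohort(cohort, classifier)
  labs <- classLabels(classifier)
  value <- vapply(cohort@individuals, function(ind) {
    idx <- match(assay, ind@measurements$assay)
    if (is.na(idx)) NA_real_ else ind@measurements$value[idx]
  }, numeric(1))
  usable <- assignment$class != "OMITTED" & !is.na(value)
  byClass <- split(value[usable], factor(assignment$class[usable], levels = labs))
  n <- vapply(byClass, length, integer(1))
  meta <- list(assignment = assignment, assay = assay,
               nExcluded = sum(!usable), nPerClass = n)
  if (any(n < 2L)) {
    results <- data.frame(hypothesis = assay, performed = FALSE,
                          reason = "fewer than two values in a class",
                          stringsAsFactors = FALSE)
    return(new("GpcResultSet", kind = "measurement", results = results,
               decisions = data.frame(), meta = meta))
  }
  tt <- studentTTest(byClass[[1]], byClass[[2]], welch = welch)
  results <- data.frame(hypothesis = assay, performed = TRUE, reason = "TESTED",
                        statistic = tt$t, df = tt$df, p_raw = tt$p,
                        significant = tt$p < alpha, stringsAsFactors = FALSE)
  results[[paste0("mean_", labs[1])]] <- mean(byClass[[1]])
  results[[paste0("mean_", labs[2])]] <- mean(byClass[[2]])
  results[[paste0("n_", labs[1])]] <- n[[1]]
  results[[paste0("n_", labs[2])]] <- n[[2]]
  new("GpcResultSet", kind = "measurement", results = results,
      decisions = data.frame(), meta = meta)
}

#' Genotype-specific survival analysis
#'
#' Derives a right-censored observation per individual for the endpoint
#' (see [endpointObservation()]), compares the two class survival curves
#' with the logrank test and reports per-class Kaplan-Meier tables. The
#' missing tally counts individuals without usable timing plus those the
#' classifier omits.
#'
#' @param cohort a [Cohort-class].
#' @param graph an [OntologyGraph-class].
#' @param classifier a two-class [GenotypeClassifier-class].
#' @param endpoint a survival endpoint, see [survival-endpoints].
#' @param alpha significance threshold.
#' @return a [GpcResultSet-class] of kind `"survival"`; `meta$km` holds the
#'   per-class Kaplan-Meier tables.
#' @export
runSurvival <- function(cohort, graph, classifier, endpoint, alpha = 0.05) {
  assignment <- classifyCohort(cohort, classifier)
  labs <- classLabels(classifier)
  rows <- list(); rowClass <- character()
  nMissing <- 0L
  for (i in seq_along(cohort@individuals)) {
    cls <- assignment$class[i]
    if (cls == "OMITTED") { nMissing <- nMissing + 1L; next }
    obs <- endpointObservation(cohort@individuals[[i]], graph, endpoint)
    if (is.null(obs)) { nMissing <- nMissing + 1L; next }
    rows[[length(rows) + 1L]] <- obs
    rowClass <- c(rowClass, cls)
  }
  hypothesis <- paste0(endpoint$kind,
                       if (!is.na(endpoint$id)) paste0(" ", endpoint$id) else "")
  meta <- list(assignment = assignment, endpoint = endpoint, nMissing = nMissing)
  notPerformed <- function(reason) {
    results <- data.frame(hypothesis = hypothesis, performed = FALSE,
                          reason = reason, stringsAsFactors = FALSE)
    new("GpcResultSet", kind = "survival", results = results,
        decisions = data.frame(), meta = meta)
  }
  if (!length(rows)) return(notPerformed("no usable survival data"))
  data <- do.call(rbind, rows)
  byClass <- split(data, factor(rowClass, levels = labs))
  n <- vapply(byClass, nrow, integer(1))
  meta$nPerClass <- n
  if (any(n < 1L)) return(notPerformed("a class has no usable survival data"))
  if (!any(data$event)) return(notPerformed("no events in either group"))
  lr <- logrankTest(byClass[[1]], byClass[[2]])
  meta$km <- lapply(byClass, kaplanMeierTable)
  results <- data.frame(hypothesis = hypothesis, performed = TRUE,
                        reason = "TESTED", statistic = lr$chi2, p_raw = lr$p,
                        significant = lr$p < alpha, stringsAsFactors = FALSE)
  results[[paste0("n_", labs[1])]] <- n[[1]]
  results[[paste0("n_", labs[2])]] <- n[[2]]
  results$nEvents <- sum(data$event)
  new("GpcResultSet", kind = "survival", results = results,
      decisions = data.frame(), meta = meta)
}

#' @describeIn gpcResults the results table of a result set.
setMethod("gpcResults", "GpcResultSet", function(x) x@results)

#' Accessors for analysis result sets
#'
#' `gpcResults` returns the per-hypothesis results table; `filterDecisions`
#' the independent-filtering ledger (categorical analyses).
#'
#' @param x a [GpcResultSet-class].
#' @name gpcResults
NULL

#' @describeIn gpcResults the filter-decision ledger.
setMethod("filterDecisions", "GpcResultSet", function(x) x@decisions)

setMethod("show", "GpcResultSet", function(object) {
  cat("GpcResultSet (", object@kind, "): ", nrow(object@results),
      " hypothesis/es tested", sep = "")
  if (nrow(object@decisions))
    cat(";", sum(!object@decisions$tested), "term(s) filtered out")
  cat("\n")
  if (nrow(object@results)) {
    print(utils::head(object@results, 5))
    if (nrow(object@results) > 5) cat("...\n")
  }
})

#' Write an analysis report to disk
#'
#' One TSV per table (results, filter ledger, Kaplan-Meier tables) plus a
#' JSON manifest with the configuration echo and tallies; a fixed cohort
#' and configuration yield byte-identical output.
#'
#' @param resultSet a [GpcResultSet-class].
#' @param dir output directory (created if needed).
#' @param graph optional [OntologyGraph-class] for labels in the filter ledger.
#' @param counts optional counts table for the filter ledger.
#' @export
writeGpcReport <- function(resultSet, dir, graph = NULL, counts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(resultSet@results, paste0(resultSet@kind, "_results.tsv"))
  if (nrow(resultSet@decisions)) {
    if (!is.null(graph) && !is.null(counts)) {
      writeFilterReport(resultSet@decisions, counts, graph,
                        file.path(dir, "filter_ledger.tsv"))
    } else {
      tsv(resultSet@decisions, "filter_ledger.tsv")
    }
  }
  for (nm in names(resultSet@meta$km %||% list())) {
    tsv(resultSet@meta$km[[nm]], paste0("km_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv"))
  }
  manifest <- list(
    kind = resultSet@kind,
    nTested = sum(resultSet@results$performed %||% rep(TRUE, nrow(resultSet@results))),
    nDecisions = nrow(resultSet@decisions),
    alpha = resultSet@meta$alpha %||% 0.05,
    mtcMethod = resultSet@meta$mtcMethod %||% NA,
    version = as.character(utils::packageVersion("PhenoGPC"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
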