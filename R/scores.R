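#' Ontology-aware counting severity score
#'
#' For each target term, one point is awarded if the individual has at least
#' one observed annotation at the term or any of its descendants; each
#' target contributes at most one point regardless of how many descendant
#' annotations exist. The score ranges from 0 to the number of target terms.
#'
#' @param individual an [Individual-class].
#' @param graph an [OntologyGraph-class].
#' @param targetTerms character vector of term ids defining the score.
#' @return integer score in `[0, length(targetTerms)]`.
#' @export
countingScore <- function(individual, graph, targetTerms) {
  checkTerms(graph, targetTerms)
  prop <- propagateAnnotations(graph, individual@phenotypes)
  observed <- prop$term[prop$status == "observed"]
  sum(targetTerms %in% observed)
}

#' @rdname countingScore
#' @return `countingScorer`: a scorer function `function(individual)`
#'   suitable for [applyScorer()].
#' @export
countingScorer <- function(graph, targetTerms) {
  checkTerms(graph, targetTerms)
  function(individual) countingScore(individual, graph, targetTerms)
}

#' Default rubric for the modified de Vries score
#'
#' An operationalization of the de Vries phenotypic severity score for
#' intellectual-disability syndromes, expressed over HPO terms so that
#' category membership is decided by descendant rollup. Categories and
#' points (total in \[0, 10\]):
#'
#' * intellectual disability: severe (`HP:0010864`) or profound
#'   (`HP:0002187`) 2 points; mild (`HP:0001256`) or moderate
#'   (`HP:0002342`) 1 point (the maximum applies).
#' * prenatal growth abnormality (intrauterine growth retardation
#'   `HP:0001511`, small for gestational age `HP:0001518`): 2 points.
#' * postnatal growth items (short stature `HP:0004322`, tall stature
#'   `HP:0000098`, microcephaly `HP:0000252`, macrocephaly `HP:0000256`):
#'   1 point each, capped at 2.
#' * facial dysmorphism (distinct annotated terms under abnormal facial
#'   shape `HP:0001999`): 2 points when at least 2 distinct features.
#' * non-facial dysmorphisms and congenital anomalies (abnormal hand
#'   morphology `HP:0005922`, abnormal heart morphology `HP:0001627`,
#'   genital-system abnormality `HP:0000078`): 1 point each, capped at 2.
#'
#' Every term id can be remapped (e.g. onto a toy ontology) by passing a
#' modified copy of this list to [deVriesScore()].
#'
#' @return a rubric list with components `idSeverity`, `prenatalGrowth`,
#'   `postnatalGrowth`, `facialDysmorphism`, `otherAnomalies`.
#' @export
defaultDeVriesRubric <- function() {
  list(
    idSeverity = list(twoPoints = c("HP:0010864", "HP:0002187"),
                      onePoint = c("HP:0001256", "HP:0002342")),
    prenatalGrowth = list(terms = c("HP:0001511", "HP:0001518"), points = 2L),
    postnatalGrowth = list(terms = c("HP:0004322", "HP:0000098",
                                     "HP:0000252", "HP:0000256"), cap = 2L),
    facialDysmorphism = list(category = "HP:0001999", threshold = 2L,
                             points = 2L),
    otherAnomalies = list(terms = c("HP:0005922", "HP:0001627", "HP:0000078"),
                          cap = 2L)
  )
}

rubricTerms <- function(rubric) {
  unique(c(rubric$idSeverity$twoPoints, rubric$idSeverity$onePoint,
           rubric$prenatalGrowth$terms, rubric$postnatalGrowth$terms,
           rubric$facialDysmorphism$category, rubric$otherAnomalies$terms))
}

#' Modified de Vries severity score
#'
#' Applies the rubric of [defaultDeVriesRubric()] with descendant rollup:
#' annotating a specialization (e.g. disproportionate short stature) counts
#' for the rubric item (short stature). Excluded annotations never subtract
#' points. An individual with no assayed term (neither observed nor
#' excluded after propagation) in any rubric category is returned as `NaN`,
#' marking exclusion from score-based testing.
#'
#' @param individual an [Individual-class].
#' @param graph an [OntologyGraph-class].
#' @param rubric a rubric list; see [defaultDeVriesRubric()].
#' @return numeric score in \[0, 10\], or `NaN`.
#' @export
deVriesScore <- function(individual, graph,
                         rubric = defaultDeVriesRubric()) {
  allTerms <- rubricTerms(rubric)
  missing <- setdiff(allTerms, ontologyTerms(graph))
  if (length(missing))
    stop("rubric term(s) absent from ontology: ", paste(missing, collapse = ", "))
  prop <- propagateAnnotations(graph, individual@phenotypes)
  status <- stats::setNames(prop$status, prop$term)
  observedAt <- function(terms) any(status[terms] == "observed", na.rm = TRUE)
  assayedAt <- function(terms) any(terms %in% prop$term[prop$status != "conflict"])

  if (!assayedAt(allTerms)) return(NaN)

  idPts <- if (observedAt(rubric$idSeverity$twoPoints)) 2L
           else if (observedAt(rubric$idSeverity$onePoint)) 1L else 0L
  prePts <- if (observedAt(rubric$prenatalGrowth$terms))
    rubric$prenatalGrowth$points else 0L
  postPts <- min(sum(vapply(rubric$postnatalGrowth$terms, function(t)
    observedAt(t), logical(1))), rubric$postnatalGrowth$cap)

  # facial features: count distinct *source* annotations under the category
  # (propagated statuses would inflate the count along the ancestor chain)
  facialSet <- termDescendants(graph, rubric$facialDysmorphism$category,
                               includeSelf = TRUE)
  srcObserved <- individual@phenotypes$term[individual@phenotypes$status == "observed"]
  nFacial <- length(intersect(unique(srcObserved), facialSet))
  facialPts <- if (nFacial >= rubric$facialDysmorphism$threshold)
    rubric$facialDysmorphism$points else 0L

  otherPts <- min(sum(vapply(rubric$otherAnomalies$terms, function(t)
    observedAt(t), logical(1))), rubric$otherAnomalies$cap)

  as.numeric(idPts + prePts + postPts + facialPts + otherPts)
}

#' @rdname deVriesScore
#' @return `deVriesScorer`: a scorer function for [applyScorer()].
#' @export
deVriesScorer <- function(graph, rubric = defaultDeVriesRubric()) {
  function(individual) deVriesScore(individual, graph, rubric)
}

#' Score a cohort and compare genotype classes by Mann-Whitney U
#'
#' Applies a scorer to every individual, drops those the classifier omits
#' and those scored `NaN` (the scorer's exclusion contract), and compares
#' the two class score distributions with [mannWhitneyU()]. Class medians
#' and the exclusion tally are reported; no multiple-testing correction is
#' applied to score tests.
#'
#' @param cohort a [Cohort-class].
#' @param classifier a two-class [GenotypeClassifier-class].
#' @param scorer `function(individual) -> numeric` (possibly `NaN`), e.g.
#'   from [countingScorer()] or [deVriesScorer()]; user-defined scorers
#'   follow the same contract.
#' @param alpha significance threshold.
#' @return a [GpcResultSet-class] of kind `"score"`; `meta$scores` holds the
#'   per-individual scores.
#' @export
applyScorer <- function(cohort, classifier, scorer, alpha = 0.05) {
  assignment <- classifyCohort(cohort, classifier)
  score <- vapply(cohort@individuals, scorer, numeric(1))
  scores <- data.frame(assignment, score = score, stringsAsFactors = FALSE)
  usable <- scores$class != "OMITTED" & !is.nan(scores$score)
  labs <- classLabels(classifier)
  byClass <- split(scores$score[usable], factor(scores$class[usable], levels = labs))
  nPerClass <- vapply(byClass, length, integer(1))
  meta <- list(scores = scores, nExcluded = sum(!usable),
               nPerClass = nPerClass)
  if (sum(nPerClass > 0L) < 2L) {
    results <- data.frame(hypothesis = "phenotype score", performed = FALSE,
                          reason = "fewer than two non-empty score classes",
                          stringsAsFactors = FALSE)
    return(new("GpcResultSet", kind = "score", results = results,
               decisions = data.frame(), meta = meta))
  }
  mwu <- mannWhitneyU(byClass[[1]], byClass[[2]])
  results <- data.frame(
    hypothesis = "phenotype score", performed = TRUE, reason = "TESTED",
    statistic = mwu$U, p_raw = mwu$p, significant = mwu$p < alpha,
    stringsAsFactors = FALSE)
  results[[paste0("median_", labs[1])]] <- stats::median(byClass[[1]])
  results[[paste0("median_", labs[2])]] <- stats::median(byClass[[2]])
  results[[paste0("n_", labs[1])]] <- nPerClass[[1]]
  results[[paste0("n_", labs[2])]] <- nPerClass[[2]]
  new("GpcResultSet", kind = "score", results = results,
      decisions = data.frame(), meta = meta)
}
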