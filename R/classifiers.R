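#' Genotype classifier constructors
#'
#' Each classifier assigns every cohort member to one genotype class or omits
#' them ([assignClass()] returns `NA` for omitted individuals).
#'
#' * `monoallelicClassifier(a, b = predNot(a))` -- individuals carrying
#'   exactly one allele matching `a` form class A, exactly one matching `b`
#'   class B; anything else (no match, homozygous or compound-heterozygous
#'   matches, or an allele matching both of non-exclusive predicates) is
#'   omitted. Hemizygous variants count as one allele, so under an X-linked
#'   analysis hemizygous males and heterozygous females land in the same class.
#' * `biallelicClassifier(a, mode)` -- for recessive disease: count alleles
#'   matching `a` among the two causal alleles (the complementary alleles
#'   must match `b`); `mode` is `"three_way"` (AA / AB / BB), `"aab_vs_bb"`
#'   (AA+AB vs BB) or `"aa_vs_abb"` (AA vs AB+BB). Individuals with an allele
#'   matching neither predicate, or matching both, are omitted.
#' * `alleleCountClassifier(target)` -- one vs two alleles matching `target`.
#' * `sexClassifier()` -- MALE vs FEMALE; unknown sex is omitted.
#' * `diagnosisClassifier(diseaseA, diseaseB)` -- class by which of the two
#'   disease ids is diagnosed; individuals with both or neither are omitted.
#'
#' @param a,b,target [VariantPredicate-class] objects.
#' @param labels length-2 (or length-3 for three-way biallelic) class labels.
#' @param mode biallelic partition mode, see above.
#' @param diseaseA,diseaseB disease ids (e.g. OMIM CURIEs).
#' @return a [GenotypeClassifier-class].
#' @name genotype-classifiers
NULL

#' @rdname genotype-classifiers
#' @export
monoallelicClassifier <- function(a, b = predNot(a), labels = c("A", "B")) {
  stopifnot(is(a, "VariantPredicate"), is(b, "VariantPredicate"),
            length(labels) == 2L)
  new("GenotypeClassifier", kind = "MONOALLELIC",
      payload = list(a = a, b = b), labels = labels)
}

#' @rdname genotype-classifiers
#' @export
biallelicClassifier <- function(a, b = predNot(a),
                                mode = c("three_way", "aab_vs_bb", "aa_vs_abb"),
                                labels = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(a, "VariantPredicate"), is(b, "VariantPredicate"))
  if (is.null(labels)) {
    labels <- switch(mode,
                     three_way = c("AA", "AB", "BB"),
                     aab_vs_bb = c("AA+AB", "BB"),
                     aa_vs_abb = c("AA", "AB+BB"))
  }
  stopifnot(length(labels) == if (mode == "three_way") 3L else 2L)
  new("GenotypeClassifier", kind = "BIALLELIC",
      payload = list(a = a, b = b, mode = mode), labels = labels)
}

#' @rdname genotype-classifiers
#' @export
alleleCountClassifier <- function(target, labels = c("monoallelic", "biallelic")) {
  stopifnot(is(target, "VariantPredicate"), length(labels) == 2L)
  new("GenotypeClassifier", kind = "ALLELE_COUNT",
      payload = list(target = target), labels = labels)
}

#' @rdname genotype-classifiers
#' @export
sexClassifier <- function() {
  new("GenotypeClassifier", kind = "SEX", payload = list(),
      labels = c("MALE", "FEMALE"))
}

#' @rdname genotype-classifiers
#' @export
diagnosisClassifier <- function(diseaseA, diseaseB, labels = c(diseaseA, diseaseB)) {
  stopifnot(is.character(diseaseA), is.character(diseaseB),
            diseaseA != diseaseB, length(labels) == 2L)
  new("GenotypeClassifier", kind = "DIAGNOSIS",
      payload = list(diseaseA = diseaseA, diseaseB = diseaseB), labels = labels)
}

#' Class labels of a classifier
#' @param classifier a [GenotypeClassifier-class].
#' @return character vector of ordered class labels.
#' @export
classLabels <- function(classifier) classifier@labels

# Count alleles matching predicates a and b across an individual's variants;
# returns c(nA, nB, overlap), where overlap flags an allele matching both.
countMatchingAlleles <- function(individual, a, b) {
  nA <- 0L; nB <- 0L; overlap <- FALSE
  for (v in individual@variants) {
    inA <- evaluatePredicate(a, v)
    inB <- evaluatePredicate(b, v)
    if (inA && inB) overlap <- TRUE
    if (inA) nA <- nA + v@alleleCount
    if (inB) nB <- nB + v@alleleCount
  }
  list(nA = nA, nB = nB, overlap = overlap)
}

#' @describeIn assignClass dispatch on the classifier kind; see
#'   [genotype-classifiers] for the per-kind rules.
setMethod("assignClass", signature("GenotypeClassifier", "Individual"),
  function(classifier, individual) {
    lab <- classifier@labels
    p <- classifier@payload
    switch(classifier@kind,
      MONOALLELIC = {
        m <- countMatchingAlleles(individual, p$a, p$b)
        if (m$overlap) {
          warning("individual ", individual@id,
                  ": an allele matches both monoallelic predicates; omitted")
          return(NA_character_)
        }
        if (m$nA == 1L && m$nB == 0L) lab[1]
        else if (m$nB == 1L && m$nA == 0L) lab[2]
        else NA_character_
      },
      BIALLELIC = {
        m <- countMatchingAlleles(individual, p$a, p$b)
        if (m$overlap) {
          warning("individual ", individual@id,
                  ": an allele matches both biallelic predicates; omitted")
          return(NA_character_)
        }
        if (m$nA + m$nB != 2L) return(NA_character_)
        idx3 <- 3L - m$nA  # nA=2 -> AA, 1 -> AB, 0 -> BB
        switch(p$mode,
               three_way = lab[idx3],
               aab_vs_bb = if (m$nA >= 1L) lab[1] else lab[2],
               aa_vs_abb = if (m$nA == 2L) lab[1] else lab[2])
      },
      ALLELE_COUNT = {
        n <- 0L
        for (v in individual@variants)
          if (evaluatePredicate(p$target, v)) n <- n + v@alleleCount
        if (n == 1L) lab[1] else if (n == 2L) lab[2] else NA_character_
      },
      SEX = {
        if (individual@sex == "MALE") lab[1]
        else if (individual@sex == "FEMALE") lab[2]
        else NA_character_
      },
      DIAGNOSIS = {
        ids <- individual@diseases$id
        hasA <- p$diseaseA %in% ids
        hasB <- p$diseaseB %in% ids
        if (hasA && !hasB) lab[1]
        else if (hasB && !hasA) lab[2]
        else NA_character_
      },
      stop("unknown classifier kind: ", classifier@kind)
    )
  })

#' Assign every cohort member to a genotype class
#'
#' @param cohort a [Cohort-class].
#' @param classifier a [GenotypeClassifier-class].
#' @return data.frame with columns `id` and `class` (`"OMITTED"` for
#'   individuals the classifier omits); together the classes and OMITTED
#'   partition the cohort.
#' @export
classifyCohort <- function(cohort, classifier) {
  cls <- vapply(cohort@individuals, function(ind)
    assignClass(classifier, ind), character(1))
  data.frame(id = cohortIds(cohort),
             class = ifelse(is.na(cls), "OMITTED", cls),
             stringsAsFactors = FALSE)
}

setMethod("show", "GenotypeClassifier", function(object) {
  cat("GenotypeClassifier:", object@kind,
      "-> classes", paste(object@labels, collapse = " / "), "\n")
})
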