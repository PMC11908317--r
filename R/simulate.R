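#' Generate a toy phenotype ontology
#'
#' A rooted is-a tree of the given depth and branching factor under a
#' synthetic phenotypic-abnormality root, with sequential `TOY:` term ids
#' assigned level by level. Optionally a fraction of the deeper terms
#' receive a second parent, creating diamond motifs like those of the real
#' HPO. Deterministic for a fixed seed.
#'
#' @param depth number of levels including the root (>= 2).
#' @param branching children per internal node (>= 1).
#' @param seed RNG seed; required when `diamondFraction > 0`.
#' @param diamondFraction fraction of depth >= 3 terms given an extra parent.
#' @return an [OntologyGraph-class].
#' @export
makeToyOntology <- function(depth, branching, seed = NULL,
                            diamondFraction = 0) {
  stopifnot(depth >= 2L, branching >= 1L,
            diamondFraction >= 0, diamondFraction <= 1)
  if (diamondFraction > 0 && is.null(seed))
    stop("diamond edges require a seed")
  nPerLevel <- branching^(0:(depth - 1L))
  total <- sum(nPerLevel)
  ids <- sprintf("TOY:%07d", seq_len(total))
  labels <- c("Phenotypic abnormality (toy)",
              paste("Toy term", seq_len(total - 1L) + 1L))
  levelStart <- cumsum(c(1L, nPerLevel))
  edges <- NULL
  for (lvl in 2:depth) {
    childIdx <- levelStart[lvl]:(levelStart[lvl + 1L] - 1L)
    parentIdx <- levelStart[lvl - 1L] +
      (seq_along(childIdx) - 1L) %/% branching
    edges <- rbind(edges, cbind(ids[childIdx], ids[parentIdx]))
  }
  if (diamondFraction > 0 && depth >= 3L) {
    edges <- withSeed(seed, {
      extra <- NULL
      for (lvl in 3:depth) {
        childIdx <- levelStart[lvl]:(levelStart[lvl + 1L] - 1L)
        parents <- levelStart[lvl - 1L]:(levelStart[lvl] - 1L)
        for (ci in childIdx) {
          if (stats::runif(1) < diamondFraction && length(parents) > 1L) {
            own <- levelStart[lvl - 1L] + (ci - levelStart[lvl]) %/% branching
            pool <- setdiff(parents, own)
            extra <- rbind(extra, c(ids[ci], ids[sample(pool, 1L)]))
          }
        }
      }
      rbind(edges, extra)
    })
  }
  ontologyGraph(ids, labels, edges, root = ids[1])
}

#' Leaf terms of an ontology
#' @param graph an [OntologyGraph-class].
#' @return term ids with no children.
#' @export
ontologyLeaves <- function(graph) {
  deg <- igraph::degree(graph@graph, mode = "in")
  names(deg)[deg == 0L]
}

#' Parameters for cohort simulation
#'
#' Defines the synthetic study conditions: two genotype classes (class A
#' carries a heterozygous missense variant, class B a heterozygous
#' stop-gained variant), per-term planted observation frequencies with an
#' assay-coverage probability, optional exponential onset models with right
#' censoring, and an optional normal measurement model. The default class
#' sizes of 50/50 match the cohort scale at which the package's power and
#' calibration properties are characterized.
#'
#' @param seed mandatory RNG seed; every individual draws from a stream
#'   derived from `(seed, index)` so cohorts are reproducible.
#' @param nPerClass named integer vector `c(A = ..., B = ...)`.
#' @param effects `NULL` or data.frame with columns `term`, `freqA`,
#'   `freqB` (per-class observation probability given assayed) and
#'   `coverage` (probability the term is assayed at all; unassayed terms
#'   are absent from the phenopacket, not excluded).
#' @param onset `NULL` or `list(term, rateA, rateB, censoringFraction)`:
#'   exponential onset ages (rates per day) with the given fraction of
#'   individuals right-censored before onset.
#' @param measurement `NULL` or `list(assay, unit, meanA, meanB, sd)`.
#' @param diseaseIds `NULL` or `c(A = id, B = id)` to attach per-class
#'   disease diagnoses.
#' @return a `SimulationParams` list.
#' @export
simulationParams <- function(seed, nPerClass = c(A = 50L, B = 50L),
                             effects = NULL, onset = NULL,
                             measurement = NULL, diseaseIds = NULL) {
  stopifnot(!missing(seed), length(nPerClass) == 2L, all(nPerClass >= 1L))
  if (!is.null(effects)) {
    stopifnot(all(c("term", "freqA", "freqB", "coverage") %in% names(effects)),
              all(effects$freqA >= 0 & effects$freqA <= 1),
              all(effects$freqB >= 0 & effects$freqB <= 1),
              all(effects$coverage >= 0 & effects$coverage <= 1))
  }
  if (!is.null(onset))
    stopifnot(onset$rateA > 0, onset$rateB > 0,
              onset$censoringFraction >= 0, onset$censoringFraction < 1)
  structure(list(seed = as.integer(seed), nPerClass = nPerClass,
                 effects = effects, onset = onset,
                 measurement = measurement, diseaseIds = diseaseIds),
            class = "SimulationParams")
}

#' Simulate a cohort with planted genotype-phenotype correlations
#'
#' Generates one individual per index from its own RNG stream: a
#' class-templated variant record, Bernoulli observed/excluded annotations
#' at the specified (typically leaf) terms -- internal-node counts then
#' arise only through true-path-rule propagation -- exponential onset ages
#' with right censoring, and normal measurements. The returned ground-truth
#' ledger records the class assignment and the planted effect sizes.
#'
#' @param graph an [OntologyGraph-class]; planted terms must be members.
#' @param params a [simulationParams()] object.
#' @return list with `cohort` (a [Cohort-class]) and `truth` (ground-truth
#'   ledger: `classes` data.frame and the parameter echo).
#' @export
simulateCohort <- function(graph, params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!is.null(params$effects)) checkTerms(graph, params$effects$term)
  if (!is.null(params$onset)) checkTerms(graph, params$onset$term)
  labs <- names(params$nPerClass) %||% c("A", "B")
  nTotal <- sum(params$nPerClass)
  classOf <- rep(labs, params$nPerClass)

  makeVariant <- function(cls) {
    if (cls == labs[1]) {
      VariantRecord(key = "var-missense", contig = "1", pos = 1000L,
                    ref = "A", alt = "G", effects = "missense_variant",
                    proteinStart = 100L, proteinEnd = 100L, exons = 2L,
                    alleleCount = 1L)
    } else {
      VariantRecord(key = "var-stop", contig = "1", pos = 2000L,
                    ref = "C", alt = "T", effects = "stop_gained",
                    proteinStart = 200L, proteinEnd = 200L, exons = 3L,
                    alleleCount = 1L)
    }
  }

  inds <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    cls <- classOf[i]
    inds[[i]] <- withSeed(childSeed(params$seed, i), {
      phRows <- list()
      if (!is.null(params$effects)) {
        ef <- params$effects
        for (j in seq_len(nrow(ef))) {
          if (stats::runif(1) < ef$coverage[j]) {
            freq <- if (cls == labs[1]) ef$freqA[j] else ef$freqB[j]
            observed <- stats::runif(1) < freq
            phRows[[length(phRows) + 1L]] <- data.frame(
              term = ef$term[j],
              status = if (observed) "observed" else "excluded",
              onsetDays = NA_real_, stringsAsFactors = FALSE)
          }
        }
      }
      lastEnc <- 30 * DAYS_PER_YEAR
      if (!is.null(params$onset)) {
        on <- params$onset
        rate <- if (cls == labs[1]) on$rateA else on$rateB
        trueOnset <- stats::rexp(1, rate)
        if (stats::runif(1) < on$censoringFraction) {
          lastEnc <- max(1, trueOnset * stats::runif(1))
        } else {
          phRows[[length(phRows) + 1L]] <- data.frame(
            term = on$term, status = "observed",
            onsetDays = trueOnset, stringsAsFactors = FALSE)
          lastEnc <- trueOnset * (1 + stats::runif(1))
        }
      }
      measurements <- emptyMeasurements()
      if (!is.null(params$measurement)) {
        ms <- params$measurement
        m <- if (cls == labs[1]) ms$meanA else ms$meanB
        measurements <- data.frame(assay = ms$assay,
                                   value = stats::rnorm(1, m, ms$sd),
                                   unit = ms$unit %||% "1",
                                   stringsAsFactors = FALSE)
      }
      diseases <- emptyDiseases()
      if (!is.null(params$diseaseIds)) {
        did <- params$diseaseIds[[cls]]
        diseases <- data.frame(id = did, label = did, onsetDays = NA_real_,
                               stringsAsFactors = FALSE)
      }
      Individual(
        id = sprintf("SIM-%04d", i),
        sex = if (stats::runif(1) < 0.5) "MALE" else "FEMALE",
        ageLastEncounterDays = lastEnc,
        vitalStatus = "ALIVE",
        diseases = diseases,
        phenotypes = if (length(phRows)) do.call(rbind, phRows)
                     else emptyPhenotypes(),
        variants = list(makeVariant(cls)),
        measurements = measurements)
    })
  }
  cohort <- buildCohort(inds)
  truth <- list(classes = data.frame(id = cohortIds(cohort), class = classOf,
                                     stringsAsFactors = FALSE),
                params = params)
  list(cohort = cohort, truth = truth)
}

#' Genotype classifier matching the simulation's variant templates
#'
#' Monoallelic missense (class A) vs stop-gained (class B), the partition
#' [simulateCohort()] plants its effects on.
#'
#' @export
simulationClassifier <- function() {
  monoallelicClassifier(effectPredicate("missense_variant"),
                        effectPredicate("stop_gained"),
                        labels = c("A", "B"))
}
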