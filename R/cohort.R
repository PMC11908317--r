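#' Build a validated cohort from individuals
#'
#' @param individuals non-empty list of [Individual-class] objects; ids must
#'   be unique (duplicates raise an error naming the offending ids).
#' @return a [Cohort-class].
#' @export
buildCohort <- function(individuals) {
  if (!length(individuals)) stop("cohort must contain at least one individual")
  new("Cohort", individuals = individuals)
}

#' Individuals of a cohort
#' @param x a [Cohort-class].
#' @return list of [Individual-class] objects.
#' @export
setMethod("individuals", "Cohort", function(x) x@individuals)

#' Individual ids of a cohort
#' @param cohort a [Cohort-class].
#' @export
cohortIds <- function(cohort) {
  vapply(cohort@individuals, function(x) x@id, character(1))
}

#' Number of individuals
#' @param x a [Cohort-class].
#' @export
setMethod("length", "Cohort", function(x) length(x@individuals))

setMethod("show", "Cohort", function(object) {
  cat("Cohort of", length(object@individuals), "individuals\n")
  sexes <- table(vapply(object@individuals, function(x) x@sex, character(1)))
  cat("  sex:", paste(names(sexes), unname(sexes), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Individual", function(object) {
  cat("Individual", object@id, "|", object@sex, "|", object@vitalStatus, "\n")
  cat("  phenotypes:", nrow(object@phenotypes),
      "| variants:", length(object@variants),
      "| measurements:", nrow(object@measurements), "\n")
})

#' Read a directory of phenopacket JSON files into a cohort
#'
#' @param dir directory containing one `.json` phenopacket per individual.
#' @return a [Cohort-class].
#' @export
readCohortDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("no .json phenopackets found in ", dir)
  buildCohort(lapply(files, readPhenopacket))
}

#' Write a cohort as a directory of phenopacket JSON files
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed); one file per individual,
#'   named `<id>.json`.
#' @export
writeCohortDir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ind in cohort@individuals) {
    writePhenopacket(ind, file.path(dir, paste0(ind@id, ".json")))
  }
  invisible(dir)
}

#' Descriptive summary of a cohort
#'
#' Tables a curator inspects before formulating hypotheses: cohort size, sex
#' distribution, the most commonly observed HPO terms (after true-path-rule
#' propagation), disease diagnoses, the distribution of variant functional
#' effects (per allele) and per-variant allele counts within the cohort.
#'
#' @param cohort a [Cohort-class].
#' @param graph an [OntologyGraph-class] used for propagation.
#' @param topK number of top terms to report.
#' @return list of data.frames: `n`, `sex`, `topTerms`, `diseases`,
#'   `effects`, `alleles`.
#' @export
cohortSummary <- function(cohort, graph, topK = 10L) {
  inds <- cohort@individuals
  sexes <- vapply(inds, function(x) x@sex, character(1))
  sexTab <- as.data.frame(table(sex = factor(sexes,
    levels = c("MALE", "FEMALE", "UNKNOWN"))), responseName = "n")

  termCount <- new.env(parent = emptyenv())
  for (ind in inds) {
    prop <- propagateAnnotations(graph, ind@phenotypes)
    for (t in prop$term[prop$status == "observed"]) {
      termCount[[t]] <- (termCount[[t]] %||% 0L) + 1L
    }
  }
  terms <- ls(termCount)
  topTerms <- if (length(terms)) {
    counts <- vapply(terms, function(t) termCount[[t]], integer(1))
    ord <- order(-counts, terms)
    data.frame(term = terms[ord], label = termLabel(graph, terms[ord]),
               nObserved = unname(counts[ord]),
               stringsAsFactors = FALSE)[seq_len(min(topK, length(terms))), ]
  } else {
    data.frame(term = character(), label = character(), nObserved = integer())
  }

  disAll <- do.call(rbind, c(lapply(inds, function(x) x@diseases[, c("id", "label")]),
                             list(data.frame(id = character(), label = character()))))
  diseases <- if (nrow(disAll)) {
    agg <- stats::aggregate(list(n = disAll$id), by = list(id = disAll$id), FUN = length)
    agg$label <- disAll$label[match(agg$id, disAll$id)]
    agg[order(-agg$n, agg$id), c("id", "label", "n")]
  } else data.frame(id = character(), label = character(), n = integer())

  effRows <- list(); alleleRows <- list()
  for (ind in inds) {
    for (v in ind@variants) {
      effs <- if (length(v@effects)) v@effects else
        if (!is.na(v@structuralType)) "structural" else "unspecified"
      effRows[[length(effRows) + 1L]] <-
        data.frame(effect = effs, n = v@alleleCount, stringsAsFactors = FALSE)
      alleleRows[[length(alleleRows) + 1L]] <-
        data.frame(key = v@key, n = v@alleleCount, stringsAsFactors = FALSE)
    }
  }
  sumBy <- function(rows, var) {
    if (!length(rows))
      return(data.frame(x = character(), nAlleles = integer())[, 0])
    df <- do.call(rbind, rows)
    agg <- stats::aggregate(list(nAlleles = df$n), by = df[var], FUN = sum)
    agg[order(-agg$nAlleles, agg[[var]]), ]
  }
  effects <- sumBy(effRows, "effect")
  alleles <- sumBy(alleleRows, "key")
  if (nrow(alleles))
    alleles$frequency <- alleles$nAlleles / (2L * length(inds))

  list(n = length(inds), sex = sexTab, topTerms = topTerms,
       diseases = diseases, effects = effects, alleles = alleles)
}
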