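#' Survival endpoints
#'
#' An endpoint defines the event whose age is compared between genotype
#' classes: death, onset of a diagnosed disease, or onset of a phenotypic
#' feature (HPO term, with descendant rollup).
#'
#' @param term HPO term id of the feature of interest.
#' @param diseaseId disease id (e.g. an OMIM CURIE).
#' @return an endpoint object for [endpointObservation()] / [runSurvival()].
#' @name survival-endpoints
NULL

#' @rdname survival-endpoints
#' @export
endpointTermOnset <- function(term) {
  structure(list(kind = "TERM_ONSET", id = term), class = "GpcEndpoint")
}

#' @rdname survival-endpoints
#' @export
endpointDeath <- function() {
  structure(list(kind = "DEATH", id = NA_character_), class = "GpcEndpoint")
}

#' @rdname survival-endpoints
#' @export
endpointDiseaseOnset <- function(diseaseId) {
  structure(list(kind = "DISEASE_ONSET", id = diseaseId), class = "GpcEndpoint")
}

# durations of exactly zero days (congenital onset) are floored to half a
# day so that the survival machinery, which needs strictly positive times,
# keeps the event rather than dropping the individual
floorDuration <- function(days) max(days, 0.5)

#' Derive one right-censored observation for an endpoint
#'
#' For a term-onset endpoint the onsets of the endpoint term and all its
#' observed descendants are pooled and the youngest taken as the event age.
#' An individual observed for the term but with no recorded onset age is
#' `MISSING` (ages are never imputed); one with no observation is censored
#' at the age of last encounter when that is known. Death and disease-onset
#' endpoints follow the same pattern on vital status and disease records.
#'
#' @param individual an [Individual-class].
#' @param graph an [OntologyGraph-class].
#' @param endpoint from [endpointTermOnset()], [endpointDeath()] or
#'   [endpointDiseaseOnset()].
#' @return one-row data.frame `duration` (days), `event` (logical), or
#'   `NULL` when no usable timing exists (the individual is excluded from
#'   the logrank test and counted in the missing tally).
#' @export
endpointObservation <- function(individual, graph, endpoint) {
  datum <- function(duration, event)
    data.frame(duration = floorDuration(duration), event = event)
  censorAtLastEncounter <- function() {
    if (!is.na(individual@ageLastEncounterDays))
      datum(individual@ageLastEncounterDays, FALSE)
    else NULL
  }
  switch(endpoint$kind,
    TERM_ONSET = {
      scope <- termDescendants(graph, endpoint$id, includeSelf = TRUE)
      ph <- individual@phenotypes
      hit <- ph$status == "observed" & ph$term %in% scope
      if (any(hit)) {
        onsets <- ph$onsetDays[hit]
        if (all(is.na(onsets))) NULL else datum(min(onsets, na.rm = TRUE), TRUE)
      } else censorAtLastEncounter()
    },
    DEATH = {
      if (individual@vitalStatus == "DECEASED") {
        if (!is.na(individual@ageAtDeathDays))
          datum(individual@ageAtDeathDays, TRUE)
        else NULL
      } else censorAtLastEncounter()
    },
    DISEASE_ONSET = {
      idx <- match(endpoint$id, individual@diseases$id)
      if (!is.na(idx)) {
        onset <- individual@diseases$onsetDays[idx]
        if (is.na(onset)) NULL else datum(onset, TRUE)
      } else censorAtLastEncounter()
    },
    stop("unknown endpoint kind: ", endpoint$kind)
  )
}
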