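#' @import methods
NULL

#' Ontology graph of phenotype terms
#'
#' A directed acyclic is-a graph over phenotype term identifiers (CURIEs such
#' as `HP:0001250`, or `TOY:0000001` for synthetic ontologies) with a
#' designated phenotypic-abnormality subroot. Edges point from child to
#' parent. Annotation at a term implies all ancestor terms (the true path
#' rule); see [propagateAnnotations()].
#'
#' @slot graph an `igraph` object; vertices are term ids, edges child -> parent.
#' @slot labels named character vector of human-readable term labels.
#' @slot root the phenotypic-abnormality subroot term id.
#'
#' @seealso [loadOntology()], [makeToyOntology()], [termAncestors()]
#' @export
setClass("OntologyGraph",
  representation(graph = "ANY", labels = "character", root = "character")
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  terms <- igraph::V(object@graph)$name
  if (length(object@root) != 1L || !(object@root %in% terms))
    msgs <- c(msgs, "root term must be a single member term of the graph")
  if (!igraph::is_dag(object@graph))
    msgs <- c(msgs, "is-a edges must form a DAG")
  if (!all(names(object@labels) %in% terms))
    msgs <- c(msgs, "labels must be named by member terms")
  if (length(msgs)) msgs else TRUE
})

#' A single variant call carried by an individual
#'
#' Coordinates follow VCF convention (1-based, explicit ref/alt); protein
#' residues and exon numbers are 1-based, protein intervals inclusive.
#' Symbolic/structural variants may omit coordinates and carry a
#' `structuralType` instead. `effects` holds functional-annotation categories
#' on the transcript of interest (e.g. `missense_variant`, `stop_gained`,
#' `frameshift_variant`); the package performs no transcript annotation
#' itself, effects come from the input record or a user-supplied annotator.
#'
#' @slot key stable string identifier of the allele.
#' @slot contig,pos,ref,alt VCF-style coordinates; may be `NA` for symbolic variants.
#' @slot structuralType one of `DEL`, `DUP`, `INV`, `TRANSLOCATION`,
#'   `CHROMOSOMAL_DELETION`, ... or `NA` for sequence variants.
#' @slot effects character vector of functional-effect categories.
#' @slot proteinStart,proteinEnd 1-based inclusive affected residue interval, or `NA`.
#' @slot exons integer vector of 1-based exon numbers overlapped by the variant.
#' @slot changeLength signed length difference `nchar(alt) - nchar(ref)`
#'   (negative for deletions); for structural variants may be supplied directly.
#' @slot alleleCount number of alleles of this variant in the individual (1 or 2).
#' @export
setClass("VariantRecord",
  representation(
    key = "character", contig = "character", pos = "integer",
    ref = "character", alt = "character", structuralType = "character",
    effects = "character", proteinStart = "integer", proteinEnd = "integer",
    exons = "integer", changeLength = "integer", alleleCount = "integer"
  ),
  prototype(
    contig = NA_character_, pos = NA_integer_, ref = NA_character_,
    alt = NA_character_, structuralType = NA_character_,
    effects = character(), proteinStart = NA_integer_,
    proteinEnd = NA_integer_, exons = integer(),
    changeLength = NA_integer_, alleleCount = 1L
  )
)

setValidity("VariantRecord", function(object) {
  msgs <- character()
  if (length(object@key) != 1L || is.na(object@key) || !nzchar(object@key))
    msgs <- c(msgs, "key must be a non-empty string")
  if (!(object@alleleCount %in% c(1L, 2L)))
    msgs <- c(msgs, "alleleCount must be 1 or 2")
  if (!is.na(object@pos)) {
    if (object@pos < 1L) msgs <- c(msgs, "pos must be >= 1 (VCF convention)")
    if (is.na(object@ref) || is.na(object@alt) ||
        !nzchar(object@ref) || !nzchar(object@alt))
      msgs <- c(msgs, "sequence variants need non-empty ref and alt")
  }
  if (!is.na(object@ref) && !is.na(object@alt) && !is.na(object@changeLength) &&
      object@changeLength != nchar(object@alt) - nchar(object@ref))
    msgs <- c(msgs, "changeLength inconsistent with ref/alt lengths")
  if (!is.na(object@proteinStart) && !is.na(object@proteinEnd) &&
      (object@proteinStart < 1L || object@proteinStart > object@proteinEnd))
    msgs <- c(msgs, "protein interval must satisfy 1 <= start <= end")
  if (length(msgs)) msgs else TRUE
})

#' One individual's clinical trajectory
#'
#' The phenopacket-derived record used throughout the analysis: phenotype
#' observations (observed/excluded, with optional onset age), disease
#' diagnoses, causal variants with genotype, numeric measurements, sex and
#' vital status. Ages are stored internally in days (1 year = 365.25 d,
#' 1 month = 30.44 d). Absence of a phenotype term means "not assayed",
#' never excluded.
#'
#' @slot id unique identifier within a cohort.
#' @slot sex `MALE`, `FEMALE` or `UNKNOWN`.
#' @slot ageLastEncounterDays age at last clinical encounter in days (`NA` if unknown).
#' @slot vitalStatus `ALIVE`, `DECEASED` or `UNKNOWN`.
#' @slot ageAtDeathDays age at death in days; requires `vitalStatus == "DECEASED"`.
#' @slot diseases data.frame with columns `id`, `label`, `onsetDays`.
#' @slot phenotypes data.frame with columns `term`, `status`
#'   (`"observed"`/`"excluded"`), `onsetDays` (onset only for observed terms).
#' @slot variants list of [VariantRecord-class] objects (total allele count <= 2).
#' @slot measurements data.frame with columns `assay` (coded concept, e.g. a
#'   LOINC code), `value` (finite real), `unit` (UCUM string).
#' @export
setClass("Individual",
  representation(
    id = "character", sex = "character", ageLastEncounterDays = "numeric",
    vitalStatus = "character", ageAtDeathDays = "numeric",
    diseases = "data.frame", phenotypes = "data.frame",
    variants = "list", measurements = "data.frame"
  )
)

setValidity("Individual", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msgs <- c(msgs, "id must be a non-empty string")
  if (!(object@sex %in% c("MALE", "FEMALE", "UNKNOWN")))
    msgs <- c(msgs, "sex must be MALE, FEMALE or UNKNOWN")
  if (!(object@vitalStatus %in% c("ALIVE", "DECEASED", "UNKNOWN")))
    msgs <- c(msgs, "vitalStatus must be ALIVE, DECEASED or UNKNOWN")
  if (!is.na(object@ageAtDeathDays) && object@vitalStatus != "DECEASED")
    msgs <- c(msgs, "ageAtDeathDays requires vitalStatus DECEASED")
  ph <- object@phenotypes
  if (!all(c("term", "status", "onsetDays") %in% names(ph))) {
    msgs <- c(msgs, "phenotypes needs columns term, status, onsetDays")
  } else {
    if (!all(ph$status %in% c("observed", "excluded")))
      msgs <- c(msgs, "phenotype status must be 'observed' or 'excluded'")
    if (any(ph$status == "excluded" & !is.na(ph$onsetDays)))
      msgs <- c(msgs, "onset is only permitted for observed phenotypes")
  }
  if (!all(vapply(object@variants, is, logical(1), "VariantRecord"))) {
    msgs <- c(msgs, "variants must be VariantRecord objects")
  } else if (length(object@variants)) {
    ac <- sum(vapply(object@variants, function(v) v@alleleCount, integer(1)))
    if (ac > 2L)
      msgs <- c(msgs, "total allele count over causal variants must be <= 2")
  }
  ms <- object@measurements
  if (!all(c("assay", "value", "unit") %in% names(ms))) {
    msgs <- c(msgs, "measurements needs columns assay, value, unit")
  } else if (nrow(ms)) {
    if (!all(is.finite(ms$value))) msgs <- c(msgs, "measurement values must be finite")
    if (!all(nzchar(ms$unit))) msgs <- c(msgs, "measurement units must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' A cohort of individuals
#'
#' @slot individuals non-empty list of [Individual-class] objects with unique ids.
#' @seealso [buildCohort()], [readCohortDir()], [simulateCohort()]
#' @export
setClass("Cohort", representation(individuals = "list"))

setValidity("Cohort", function(object) {
  msgs <- character()
  if (!length(object@individuals)) msgs <- c(msgs, "cohort must be non-empty")
  if (!all(vapply(object@individuals, is, logical(1), "Individual")))
    msgs <- c(msgs, "individuals must be Individual objects")
  else {
    ids <- vapply(object@individuals, function(x) x@id, character(1))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      msgs <- c(msgs, paste0("duplicate individual id(s): ",
                             paste(dup, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Boolean predicate over variant attributes
#'
#' A finite tree whose leaves test a single variant attribute (functional
#' effect, exon overlap, protein-region overlap, variant key, structural
#' type, change length, reference length, structural deletion) and whose
#' internal nodes combine children with AND / OR / NOT. A leaf whose
#' attribute is missing on the variant under test evaluates to `FALSE`,
#' never an error, so predicates run over mixed SNV/SV cohorts. Malformed
#' trees are rejected at construction time.
#'
#' Combine predicates with `&`, `|` and `!` or [predAnd()], [predOr()],
#' [predNot()].
#'
#' @slot kind leaf or operator kind.
#' @slot payload leaf argument list (validated by the constructors).
#' @slot children list of child predicates (operators only).
#' @slot description human-readable rendering.
#' @seealso [effectPredicate()], [evaluatePredicate()]
#' @export
setClass("VariantPredicate",
  representation(kind = "character", payload = "list",
                 children = "list", description = "character")
)

#' Rule that partitions a cohort into genotype classes
#'
#' One of five classifier kinds: `MONOALLELIC` (exactly one allele matching
#' predicate A vs exactly one matching B), `BIALLELIC` (count of alleles
#' matching A among the two causal alleles, three-way AA/AB/BB or one of the
#' two two-way coarsenings), `ALLELE_COUNT` (one vs two alleles matching a
#' target predicate), `SEX` (male vs female; unknown omitted) and
#' `DIAGNOSIS` (which of two disease ids is present). Individuals that fit
#' no class are omitted from analysis.
#'
#' @slot kind classifier kind.
#' @slot payload kind-specific parameters.
#' @slot labels ordered unique class labels.
#' @seealso [monoallelicClassifier()], [assignClass()]
#' @export
setClass("GenotypeClassifier",
  representation(kind = "character", payload = "list", labels = "character")
)

setValidity("GenotypeClassifier", function(object) {
  if (anyDuplicated(object@labels)) "class labels must be unique" else TRUE
})

#' Result container for one genotype-phenotype analysis
#'
#' @slot kind `"categorical"`, `"score"`, `"measurement"` or `"survival"`.
#' @slot results data.frame of tested hypotheses (statistic, raw p, adjusted
#'   p for categorical tests, per-class summaries, significance at alpha).
#' @slot decisions per-term independent-filtering ledger (categorical only).
#' @slot meta list: class assignment, tallies of omitted/missing individuals,
#'   Kaplan-Meier tables for survival analyses, configuration echo.
#' @seealso [runCategorical()], [gpcResults()]
#' @export
setClass("GpcResultSet",
  representation(kind = "character", results = "data.frame",
                 decisions = "data.frame", meta = "list")
)
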