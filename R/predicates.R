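newPredicate <- function(kind, payload = list(), children = list(),
                         description = kind) {
  new("VariantPredicate", kind = kind, payload = payload,
      children = children, description = description)
}

checkCmp <- function(op) {
  if (!(op %in% c("==", "!=", "<", "<=", ">", ">=")))
    stop("comparison operator must be one of ==, !=, <, <=, >, >=")
  op
}

applyCmp <- function(x, op, value) {
  switch(op,
         "==" = x == value, "!=" = x != value,
         "<" = x < value, "<=" = x <= value,
         ">" = x > value, ">=" = x >= value)
}

#' Variant predicate constructors
#'
#' Leaf predicates over a single variant attribute. Each leaf evaluates to
#' `FALSE` when its attribute is absent on the variant (e.g. a protein-region
#' test on a variant without a protein range), so predicates can run over
#' mixed SNV/SV cohorts. Interval overlaps are closed-interval intersections.
#'
#' * `effectPredicate(effect)` -- any of the variant's functional effects equals `effect`.
#' * `exonPredicate(exon)` -- the variant overlaps the given 1-based exon.
#' * `proteinRegionPredicate(start, end)` -- the affected residue interval
#'   intersects `[start, end]` (1-based inclusive).
#' * `keyPredicate(key)` -- the variant key equals `key`.
#' * `structuralTypePredicate(type)` -- the structural type equals `type`.
#' * `changeLengthPredicate(op, value)` -- comparison on the signed change length.
#' * `refLengthPredicate(op, value)` -- comparison on `nchar(ref)`.
#' * `structuralDeletionPredicate(minLength = 50)` -- an imprecise chromosomal
#'   deletion (structural type contains "deletion"/"DEL") or a sequence
#'   deletion losing at least `minLength` bases (`changeLength <= -minLength`).
#'
#' @param effect,exon,start,end,key,type,op,value,minLength leaf arguments;
#'   validated at construction time (malformed leaves never fail at
#'   evaluation).
#' @return a [VariantPredicate-class].
#' @name variant-predicates
NULL

#' @rdname variant-predicates
#' @export
effectPredicate <- function(effect) {
  stopifnot(is.character(effect), length(effect) == 1L)
  newPredicate("EFFECT_IS", list(effect = effect),
               description = paste0("effect is ", effect))
}

#' @rdname variant-predicates
#' @export
exonPredicate <- function(exon) {
  exon <- as.integer(exon)
  stopifnot(length(exon) == 1L, !is.na(exon), exon >= 1L)
  newPredicate("EXON_OVERLAPS", list(exon = exon),
               description = paste0("overlaps exon ", exon))
}

#' @rdname variant-predicates
#' @export
proteinRegionPredicate <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(!is.na(start), !is.na(end), start >= 1L, start <= end)
  newPredicate("PROTEIN_REGION_OVERLAPS", list(start = start, end = end),
               description = paste0("overlaps protein region ", start, "-", end))
}

#' @rdname variant-predicates
#' @export
keyPredicate <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  newPredicate("KEY_EQUALS", list(key = key),
               description = paste0("variant is ", key))
}

#' @rdname variant-predicates
#' @export
structuralTypePredicate <- function(type) {
  stopifnot(is.character(type), length(type) == 1L)
  newPredicate("STRUCTURAL_TYPE_IS", list(type = type),
               description = paste0("structural type is ", type))
}

#' @rdname variant-predicates
#' @export
changeLengthPredicate <- function(op, value) {
  newPredicate("CHANGE_LENGTH_CMP",
               list(op = checkCmp(op), value = as.integer(value)),
               description = paste0("change length ", op, " ", value))
}

#' @rdname variant-predicates
#' @export
refLengthPredicate <- function(op, value) {
  newPredicate("REF_LENGTH_CMP",
               list(op = checkCmp(op), value = as.integer(value)),
               description = paste0("ref length ", op, " ", value))
}

#' @rdname variant-predicates
#' @export
structuralDeletionPredicate <- function(minLength = 50L) {
  minLength <- as.integer(minLength)
  stopifnot(!is.na(minLength), minLength >= 1L)
  newPredicate("IS_STRUCTURAL_DELETION", list(minLength = minLength),
               description = paste0("structural deletion >= ", minLength, " bp"))
}

#' Predicate combinators
#'
#' Standard Boolean semantics; also available as `&`, `|` and `!` operators.
#'
#' @param ... child predicates (`predAnd`/`predOr` take two or more).
#' @param p a predicate to negate.
#' @return a [VariantPredicate-class].
#' @export
predAnd <- function(...) {
  kids <- list(...)
  stopifnot(length(kids) >= 2L,
            all(vapply(kids, is, logical(1), "VariantPredicate")))
  newPredicate("AND", children = kids,
               description = paste0("(", paste(vapply(kids, function(k) k@description,
                 character(1)), collapse = " AND "), ")"))
}

#' @rdname predAnd
#' @export
predOr <- function(...) {
  kids <- list(...)
  stopifnot(length(kids) >= 2L,
            all(vapply(kids, is, logical(1), "VariantPredicate")))
  newPredicate("OR", children = kids,
               description = paste0("(", paste(vapply(kids, function(k) k@description,
                 character(1)), collapse = " OR "), ")"))
}

#' @rdname predAnd
#' @export
predNot <- function(p) {
  stopifnot(is(p, "VariantPredicate"))
  newPredicate("NOT", children = list(p),
               description = paste0("NOT ", p@description))
}

#' @export
setMethod("&", signature("VariantPredicate", "VariantPredicate"),
          function(e1, e2) predAnd(e1, e2))

#' @export
setMethod("|", signature("VariantPredicate", "VariantPredicate"),
          function(e1, e2) predOr(e1, e2))

#' @export
setMethod("!", "VariantPredicate", function(x) predNot(x))

isStructuralDeletionType <- function(type) {
  !is.na(type) && grepl("del", type, ignore.case = TRUE)
}

#' @describeIn evaluatePredicate Boolean semantics over leaf truth values;
#'   missing attributes make a leaf `FALSE`.
setMethod("evaluatePredicate", signature("VariantPredicate", "VariantRecord"),
  function(pred, variant) {
    v <- variant
    switch(pred@kind,
      AND = all(vapply(pred@children, evaluatePredicate, logical(1), variant = v)),
      OR = any(vapply(pred@children, evaluatePredicate, logical(1), variant = v)),
      NOT = !evaluatePredicate(pred@children[[1]], v),
      EFFECT_IS = pred@payload$effect %in% v@effects,
      EXON_OVERLAPS = pred@payload$exon %in% v@exons,
      PROTEIN_REGION_OVERLAPS =
        !is.na(v@proteinStart) && !is.na(v@proteinEnd) &&
        v@proteinStart <= pred@payload$end && v@proteinEnd >= pred@payload$start,
      KEY_EQUALS = identical(v@key, pred@payload$key),
      STRUCTURAL_TYPE_IS = identical(v@structuralType, pred@payload$type),
      CHANGE_LENGTH_CMP =
        !is.na(v@changeLength) &&
        applyCmp(v@changeLength, pred@payload$op, pred@payload$value),
      REF_LENGTH_CMP =
        !is.na(v@ref) && applyCmp(nchar(v@ref), pred@payload$op, pred@payload$value),
      IS_STRUCTURAL_DELETION =
        isStructuralDeletionType(v@structuralType) ||
        (!is.na(v@changeLength) && v@changeLength <= -pred@payload$minLength),
      stop("unknown predicate kind: ", pred@kind)
    )
  })

setMethod("show", "VariantPredicate", function(object) {
  cat("VariantPredicate:", object@description, "\n")
})

#' Serialize / deserialize a predicate as a JSON-ready tree
#'
#' Used by the analysis-configuration file format: a predicate is a list
#' with `kind`, leaf `payload` fields, and `children` for operators.
#'
#' @param pred a [VariantPredicate-class].
#' @param spec a list as produced by `predicateToSpec` (e.g. parsed from
#'   JSON or YAML).
#' @return `predicateToSpec`: a plain list; `predicateFromSpec`: a predicate.
#' @export
predicateToSpec <- function(pred) {
  out <- list(kind = pred@kind)
  if (length(pred@payload)) out <- c(out, pred@payload)
  if (length(pred@children))
    out$children <- lapply(pred@children, predicateToSpec)
  out
}

#' @rdname predicateToSpec
#' @export
predicateFromSpec <- function(spec) {
  kids <- lapply(spec$children %||% list(), predicateFromSpec)
  switch(spec$kind,
    AND = do.call(predAnd, kids),
    OR = do.call(predOr, kids),
    NOT = predNot(kids[[1]]),
    EFFECT_IS = effectPredicate(spec$effect),
    EXON_OVERLAPS = exonPredicate(spec$exon),
    PROTEIN_REGION_OVERLAPS = proteinRegionPredicate(spec$start, spec$end),
    KEY_EQUALS = keyPredicate(spec$key),
    STRUCTURAL_TYPE_IS = structuralTypePredicate(spec$type),
    CHANGE_LENGTH_CMP = changeLengthPredicate(spec$op, spec$value),
    REF_LENGTH_CMP = refLengthPredicate(spec$op, spec$value),
    IS_STRUCTURAL_DELETION = structuralDeletionPredicate(spec$minLength %||% 50L),
    stop("unknown predicate kind in spec: ", spec$kind)
  )
}
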