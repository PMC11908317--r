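#' Construct an Individual
#'
#' @param id unique identifier.
#' @param sex `MALE`, `FEMALE` or `UNKNOWN`.
#' @param ageLastEncounterDays age at last encounter in days (`NA` if unknown).
#' @param vitalStatus `ALIVE`, `DECEASED` or `UNKNOWN`.
#' @param ageAtDeathDays age at death in days (requires `DECEASED`).
#' @param diseases data.frame `id`, `label`, `onsetDays`.
#' @param phenotypes data.frame `term`, `status`, `onsetDays`.
#' @param variants list of [VariantRecord-class].
#' @param measurements data.frame `assay`, `value`, `unit`.
#' @return an [Individual-class].
#' @export
Individual <- function(id, sex = "UNKNOWN", ageLastEncounterDays = NA_real_,
                       vitalStatus = "UNKNOWN", ageAtDeathDays = NA_real_,
                       diseases = emptyDiseases(),
                       phenotypes = emptyPhenotypes(),
                       variants = list(),
                       measurements = emptyMeasurements()) {
  new("Individual", id = id, sex = sex,
      ageLastEncounterDays = as.numeric(ageLastEncounterDays),
      vitalStatus = vitalStatus, ageAtDeathDays = as.numeric(ageAtDeathDays),
      diseases = diseases, phenotypes = phenotypes,
      variants = variants, measurements = measurements)
}

#' Construct a VariantRecord
#'
#' @param key stable allele identifier.
#' @param contig,pos,ref,alt VCF-style coordinates (optional for symbolic variants).
#' @param structuralType structural-variant category, or `NA`.
#' @param effects character vector of functional-effect categories.
#' @param proteinStart,proteinEnd 1-based inclusive affected residue interval.
#' @param exons 1-based exon numbers overlapped.
#' @param changeLength signed `alt - ref` length difference; derived from
#'   ref/alt when both are given and `changeLength` is `NA`.
#' @param alleleCount 1 or 2.
#' @return a [VariantRecord-class].
#' @export
VariantRecord <- function(key, contig = NA, pos = NA, ref = NA, alt = NA,
                          structuralType = NA, effects = character(),
                          proteinStart = NA, proteinEnd = NA,
                          exons = integer(), changeLength = NA,
                          alleleCount = 1L) {
  if (is.na(changeLength) && !is.na(ref) && !is.na(alt))
    changeLength <- nchar(alt) - nchar(ref)
  new("VariantRecord", key = as.character(key),
      contig = as.character(contig), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      structuralType = as.character(structuralType),
      effects = as.character(effects),
      proteinStart = as.integer(proteinStart),
      proteinEnd = as.integer(proteinEnd), exons = as.integer(exons),
      changeLength = as.integer(changeLength),
      alleleCount = as.integer(alleleCount))
}

alleleCountFromState <- function(state) {
  switch(tolower(state %||% "heterozygous"),
         homozygous = 2L,
         heterozygous = 1L,
         hemizygous = 1L,
         1L)
}

extensionValue <- function(extensions, name) {
  for (e in extensions) if (identical(e$name, name)) return(e$value)
  NULL
}

parseAge <- function(node, what, id) {
  iso <- node$age$iso8601duration
  if (is.null(iso)) return(NA_real_)
  days <- parseIsoDuration(iso)
  if (is.na(days))
    warning("individual ", id, ": unparseable ", what, " '", iso,
            "' dropped (missing data are not imputed)")
  days
}

#' Read one GA4GH v2 phenopacket
#'
#' Reads the schema subset used by the analysis: `id`, `subject.sex`,
#' `subject.timeAtLastEncounter`, `subject.vitalStatus`,
#' `phenotypicFeatures[].type/.excluded/.onset`, `diseases[]`,
#' `measurements[].assay/.value.quantity` and
#' `interpretations -> genomicInterpretations -> variantInterpretation ->
#' variationDescriptor` (vcfRecord, structuralType, allelicState).
#' Functional effects, exons, protein ranges and change lengths are read
#' from `variationDescriptor.extensions` entries named `functionalEffects`,
#' `exons`, `proteinRange` and `changeLength` (semicolon-separated values;
#' the package performs no transcript annotation of its own). Unrecognized
#' fields are ignored; unparseable onset ages are dropped with a warning and
#' never imputed.
#'
#' @param x path to a phenopacket JSON file, or an already-parsed list.
#' @return an [Individual-class].
#' @export
readPhenopacket <- function(x) {
  doc <- if (is.character(x)) jsonlite::fromJSON(x, simplifyVector = FALSE) else x
  if (is.null(doc$id) || !nzchar(doc$id))
    stop("phenopacket has no id")
  id <- doc$id
  subj <- doc$subject %||% list()
  sex <- toupper(subj$sex %||% "UNKNOWN")
  if (!(sex %in% c("MALE", "FEMALE"))) sex <- "UNKNOWN"
  lastEnc <- parseAge(subj$timeAtLastEncounter %||% list(), "age at last encounter", id)
  vs <- subj$vitalStatus %||% list()
  vitalStatus <- toupper(vs$status %||% "UNKNOWN")
  if (!(vitalStatus %in% c("ALIVE", "DECEASED"))) vitalStatus <- "UNKNOWN"
  ageAtDeath <- if (vitalStatus == "DECEASED")
    parseAge(vs$timeOfDeath %||% list(), "age at death", id) else NA_real_

  feats <- doc$phenotypicFeatures %||% list()
  phenotypes <- if (length(feats)) {
    do.call(rbind, lapply(feats, function(f) {
      excluded <- isTRUE(f$excluded)
      onset <- if (excluded) NA_real_ else parseAge(f$onset %||% list(), "onset", id)
      data.frame(term = f$type$id,
                 status = if (excluded) "excluded" else "observed",
                 onsetDays = onset, stringsAsFactors = FALSE)
    }))
  } else emptyPhenotypes()

  dis <- doc$diseases %||% list()
  diseases <- if (length(dis)) {
    do.call(rbind, lapply(dis, function(d) {
      data.frame(id = d$term$id, label = d$term$label %||% d$term$id,
                 onsetDays = parseAge(d$onset %||% list(), "disease onset", id),
                 stringsAsFactors = FALSE)
    }))
  } else emptyDiseases()

  meas <- doc$measurements %||% list()
  measurements <- if (length(meas)) {
    do.call(rbind, lapply(meas, function(m) {
      q <- m$value$quantity
      data.frame(assay = m$assay$id,
                 value = as.numeric(q$value),
                 unit = q$unit$label %||% q$unit$id %||% "1",
                 stringsAsFactors = FALSE)
    }))
  } else emptyMeasurements()

  variants <- list()
  for (interp in doc$interpretations %||% list()) {
    for (gi in interp$diagnosis$genomicInterpretations %||% list()) {
      vd <- gi$variantInterpretation$variationDescriptor
      if (is.null(vd)) next
      vcf <- vd$vcfRecord
      ext <- vd$extensions %||% list()
      splitNum <- function(x) if (is.null(x)) integer() else as.integer(strsplit(x, ";")[[1]])
      pr <- extensionValue(ext, "proteinRange")
      prRange <- if (is.null(pr)) c(NA_integer_, NA_integer_) else
        as.integer(strsplit(pr, "-")[[1]])
      eff <- extensionValue(ext, "functionalEffects")
      cl <- extensionValue(ext, "changeLength")
      variants[[length(variants) + 1L]] <- VariantRecord(
        key = vd$id %||% paste0(id, "-var", length(variants) + 1L),
        contig = vcf$chrom %||% NA, pos = vcf$pos %||% NA,
        ref = vcf$ref %||% NA, alt = vcf$alt %||% NA,
        structuralType = vd$structuralType$label %||% NA,
        effects = if (is.null(eff)) character() else strsplit(eff, ";")[[1]],
        proteinStart = prRange[1], proteinEnd = prRange[2],
        exons = splitNum(extensionValue(ext, "exons")),
        changeLength = if (is.null(cl)) NA else as.integer(cl),
        alleleCount = alleleCountFromState(vd$allelicState$label)
      )
    }
  }

  Individual(id = id, sex = sex, ageLastEncounterDays = lastEnc,
             vitalStatus = vitalStatus, ageAtDeathDays = ageAtDeath,
             diseases = diseases, phenotypes = phenotypes,
             variants = variants, measurements = measurements)
}

#' Write one individual as a phenopacket-subset JSON document
#'
#' Inverse of [readPhenopacket()] on the recognized field subset: an
#' individual round-trips exactly (ages are written in canonical
#' day-denominated ISO-8601 form).
#'
#' @param individual an [Individual-class].
#' @param path output file; when `NULL` the document list is returned instead.
#' @export
writePhenopacket <- function(individual, path = NULL) {
  ageObj <- function(days) list(age = list(iso8601duration = formatIsoDuration(days)))
  doc <- list(id = individual@id)
  subject <- list(sex = individual@sex)
  if (!is.na(individual@ageLastEncounterDays))
    subject$timeAtLastEncounter <- ageObj(individual@ageLastEncounterDays)
  if (individual@vitalStatus != "UNKNOWN") {
    vs <- list(status = individual@vitalStatus)
    if (!is.na(individual@ageAtDeathDays))
      vs$timeOfDeath <- ageObj(individual@ageAtDeathDays)
    subject$vitalStatus <- vs
  }
  doc$subject <- subject
  ph <- individual@phenotypes
  if (nrow(ph)) {
    doc$phenotypicFeatures <- lapply(seq_len(nrow(ph)), function(i) {
      f <- list(type = list(id = ph$term[i]))
      if (ph$status[i] == "excluded") f$excluded <- TRUE
      if (!is.na(ph$onsetDays[i])) f$onset <- ageObj(ph$onsetDays[i])
      f
    })
  }
  ds <- individual@diseases
  if (nrow(ds)) {
    doc$diseases <- lapply(seq_len(nrow(ds)), function(i) {
      d <- list(term = list(id = ds$id[i], label = ds$label[i]))
      if (!is.na(ds$onsetDays[i])) d$onset <- ageObj(ds$onsetDays[i])
      d
    })
  }
  ms <- individual@measurements
  if (nrow(ms)) {
    doc$measurements <- lapply(seq_len(nrow(ms)), function(i) {
      list(assay = list(id = ms$assay[i]),
           value = list(quantity = list(value = ms$value[i],
                                        unit = list(label = ms$unit[i]))))
    })
  }
  if (length(individual@variants)) {
    gis <- lapply(individual@variants, function(v) {
      ext <- list()
      addExt <- function(name, value) {
        if (length(value) && !all(is.na(value)))
          ext[[length(ext) + 1L]] <<- list(name = name,
                                           value = paste(value, collapse = ";"))
      }
      addExt("functionalEffects", v@effects)
      addExt("exons", v@exons)
      if (!is.na(v@proteinStart))
        addExt("proteinRange", paste0(v@proteinStart, "-", v@proteinEnd))
      addExt("changeLength", v@changeLength)
      vd <- list(id = v@key,
                 allelicState = list(
                   label = if (v@alleleCount == 2L) "homozygous" else "heterozygous"))
      if (!is.na(v@pos))
        vd$vcfRecord <- list(chrom = v@contig, pos = v@pos, ref = v@ref, alt = v@alt)
      if (!is.na(v@structuralType))
        vd$structuralType <- list(label = v@structuralType)
      if (length(ext)) vd$extensions <- ext
      list(variantInterpretation = list(variationDescriptor = vd))
    })
    doc$interpretations <- list(list(diagnosis = list(genomicInterpretations = gis)))
  }
  if (is.null(path)) return(doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
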