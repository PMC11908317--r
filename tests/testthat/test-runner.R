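plantedSim <- function(seed, freqA = 0.9, freqB = 0.1, n = 40L) {
  g <- makeToyOntology(4, 2)
  leaves <- ontologyLeaves(g)
  eff <- data.frame(term = leaves,
                    freqA = c(freqA, rep(0.5, length(leaves) - 1)),
                    freqB = c(freqB, rep(0.5, length(leaves) - 1)),
                    coverage = 1)
  sim <- simulateCohort(g, simulationParams(seed = seed, effects = eff,
                                            nPerClass = c(A = n, B = n)))
  list(graph = g, sim = sim, planted = leaves[1])
}

test_that("a strongly planted term comes out significant after BH", {
  ps <- plantedSim(101)
  res <- runCategorical(ps$sim$cohort, ps$graph, simulationClassifier())
  tab <- gpcResults(res)
  expect_true(ps$planted %in% tab$term)
  expect_lt(tab$p_adjusted[tab$term == ps$planted], 0.05)
  expect_true(tab$significant[tab$term == ps$planted])
  # results are sorted by adjusted p, so the planted term leads
  expect_identical(tab$term[1], ps$planted)
})

test_that("specified-term mode tests exactly one hypothesis with no correction", {
  ps <- plantedSim(102)
  res <- runCategorical(ps$sim$cohort, ps$graph, simulationClassifier(),
                        mode = "specified", terms = ps$planted)
  tab <- gpcResults(res)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$p_adjusted, tab$p_raw)
})

test_that("corrected hypothesis count equals the TESTED filter decisions", {
  ps <- plantedSim(103)
  res <- runCategorical(ps$sim$cohort, ps$graph, simulationClassifier())
  expect_identical(nrow(gpcResults(res)), sum(filterDecisions(res)$tested))
  # every individual lands in a class or is omitted
  asg <- res@meta$assignment
  expect_setequal(asg$id, cohortIds(ps$sim$cohort))
})

test_that("analysis output is deterministic for a fixed cohort and config", {
  ps <- plantedSim(104)
  r1 <- runCategorical(ps$sim$cohort, ps$graph, simulationClassifier())
  r2 <- runCategorical(ps$sim$cohort, ps$graph, simulationClassifier())
  expect_identical(gpcResults(r1), gpcResults(r2))
  d1 <- tempfile(); d2 <- tempfile()
  pc <- phenotypeCounts(ps$sim$cohort, ps$graph, simulationClassifier())
  writeGpcReport(r1, d1, graph = ps$graph, counts = pc$counts)
  writeGpcReport(r2, d2, graph = ps$graph, counts = pc$counts)
  f1 <- file.path(d1, "categorical_results.tsv")
  f2 <- file.path(d2, "categorical_results.tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("all annotated terms filtered out is an empty result, not an error", {
  g <- makeToyOntology(3, 2)
  leaves <- ontologyLeaves(g)
  sim <- simulateCohort(g, simulationParams(
    seed = 105, nPerClass = c(A = 3L, B = 3L),
    effects = data.frame(term = leaves[1], freqA = 0.5, freqB = 0.5,
                         coverage = 1)))  # total 6 < 7: underpowered
  res <- runCategorical(sim$cohort, g, simulationClassifier())
  expect_identical(nrow(gpcResults(res)), 0L)
  expect_gt(nrow(filterDecisions(res)), 0L)
  expect_false(any(filterDecisions(res)$tested))
})

test_that("measurement test uses exactly the individuals carrying the assay", {
  g <- makeToyOntology(3, 2)
  sim <- simulateCohort(g, simulationParams(
    seed = 106, nPerClass = c(A = 10L, B = 10L),
    measurement = list(assay = "LOINC:1668-3", unit = "nmol/L",
                       meanA = 10, meanB = 10, sd = 1)))
  # strip the measurement from half the cohort
  inds <- individuals(sim$cohort)
  for (i in seq(1, 20, by = 2)) inds[[i]]@measurements <- PhenoGPC:::emptyMeasurements()
  cohort <- buildCohort(inds)
  res <- runContinuous(cohort, simulationClassifier(), "LOINC:1668-3")
  tab <- gpcResults(res)
  expect_identical(tab$n_A + tab$n_B, 10L)
  expect_identical(res@meta$nExcluded, 10L)
  # absent assay: not performed
  miss <- runContinuous(cohort, simulationClassifier(), "LOINC:9999")
  expect_false(gpcResults(miss)$performed)
})

test_that("identical measurement values in both classes give p = 1", {
  g <- makeToyOntology(3, 2)
  sim <- simulateCohort(g, simulationParams(
    seed = 107, nPerClass = c(A = 5L, B = 5L),
    measurement = list(assay = "LOINC:1", unit = "U/L", meanA = 3,
                       meanB = 3, sd = 1)))
  inds <- lapply(individuals(sim$cohort), function(ind) {
    ind@measurements$value <- 3
    ind
  })
  res <- runContinuous(buildCohort(inds), simulationClassifier(), "LOINC:1")
  expect_equal(gpcResults(res)$p_raw, 1)
})

test_that("survival runner reports KM tables, missing tallies and the logrank p", {
  g <- makeToyOntology(3, 2)
  leaves <- ontologyLeaves(g)
  sim <- simulateCohort(g, simulationParams(
    seed = 108, nPerClass = c(A = 30L, B = 30L),
    onset = list(term = leaves[1], rateA = 1 / 3650, rateB = 3 / 3650,
                 censoringFraction = 0.2)))
  res <- runSurvival(sim$cohort, g, simulationClassifier(),
                     endpointTermOnset(leaves[1]))
  tab <- gpcResults(res)
  expect_true(tab$performed)
  expect_identical(tab$n_A + tab$n_B + res@meta$nMissing, 60L)
  km <- res@meta$km
  expect_named(km, c("A", "B"))
  expect_true(all(diff(km$A$survival) <= 1e-12))

  # identical survival data in both classes: p = 1
  inds <- c(
    lapply(1:4, function(i) Individual(
      id = paste0("A", i), ageLastEncounterDays = 1000,
      phenotypes = phRow(leaves[1], onsetDays = i * 100),
      variants = list(missenseVariant()))),
    lapply(1:4, function(i) Individual(
      id = paste0("B", i), ageLastEncounterDays = 1000,
      phenotypes = phRow(leaves[1], onsetDays = i * 100),
      variants = list(stopGainedVariant()))))
  same <- runSurvival(buildCohort(inds), g, simulationClassifier(),
                      endpointTermOnset(leaves[1]))
  expect_equal(gpcResults(same)$p_raw, 1)

  # a cohort with no usable timing at all: not performed, everyone missing
  bare <- buildCohort(lapply(1:6, function(i)
    Individual(id = paste0("P", i),
               variants = list(if (i <= 3) missenseVariant() else stopGainedVariant()))))
  none <- runSurvival(bare, g, simulationClassifier(), endpointTermOnset(leaves[1]))
  expect_false(gpcResults(none)$performed)
  expect_identical(none@meta$nMissing, 6L)
})

test_that("lollipop aggregates per-position allele counts and omits structural variants", {
  inds <- c(
    lapply(1:5, function(i) makeInd(paste0("M", i), variants = list(
      VariantRecord(key = "v100", contig = "1", pos = 10L, ref = "A", alt = "G",
                    effects = "missense_variant", proteinStart = 100L,
                    proteinEnd = 100L)))),
    list(makeInd("S1", variants = list(
      VariantRecord(key = "v200", contig = "1", pos = 20L, ref = "C", alt = "T",
                    effects = "stop_gained", proteinStart = 200L,
                    proteinEnd = 200L))),
      makeInd("SV", variants = list(
        VariantRecord(key = "vdel", structuralType = "chromosomal_deletion")))))
  cohort <- buildCohort(inds)
  domains <- data.frame(name = "Atrophin", start = 50L, end = 150L)
  p <- renderLollipop(cohort, proteinLength = 300L, domains = domains)
  pos <- attr(p, "positions")
  expect_identical(pos$count[pos$position == 100], 5L)
  expect_identical(pos$count[pos$position == 200], 1L)
  expect_identical(attr(p, "nOmitted"), 1L)
  expect_s3_class(p, "ggplot")
  expect_error(renderLollipop(cohort, 300L,
                              data.frame(name = "bad", start = 10L, end = 400L)),
               "outside")
  svg <- tempfile(fileext = ".svg")
  renderLollipop(cohort, 300L, domains, file = svg)
  expect_true(file.size(svg) > 0)
  expect_match(readLines(svg, n = 2, warn = FALSE)[2], "svg")
})
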