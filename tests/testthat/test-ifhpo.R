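# counts table helper: one term, per-class (observed, assayed) pairs
countRows <- function(term, obs, assayed, classes = c("A", "B")) {
  data.frame(term = term, class = classes, nObserved = obs,
             nExcluded = assayed - obs, stringsAsFactors = FALSE)
}

# graph: root <- sys1 <- parent <- child ; root <- sys2 (second branch)
filterGraph <- function() {
  ontologyGraph(
    terms = c("HP:0000118", "HP:0000707", "HP:0010696", "HP:0001115",
              "HP:0000152"),
    labels = c("Phenotypic abnormality", "Abnormality of the nervous system",
               "Polar cataract", "Posterior polar cataract",
               "Abnormality of head or neck"),
    edges = rbind(c("HP:0000707", "HP:0000118"),
                  c("HP:0000152", "HP:0000118"),
                  c("HP:0010696", "HP:0000152"),
                  c("HP:0001115", "HP:0010696")),
    root = "HP:0000118")
}

test_that("a parent with counts identical to a child is skipped, the child kept", {
  g <- filterGraph()
  counts <- rbind(countRows("HP:0010696", c(7L, 3L), c(11L, 8L)),
                  countRows("HP:0001115", c(7L, 3L), c(11L, 8L)))
  dec <- selectTestableTerms(counts, g, cohortSize = 19L)
  expect_identical(dec$reason[dec$term == "HP:0010696"], "SAME_AS_CHILD")
  expect_identical(dec$reason[dec$term == "HP:0001115"], "TESTED")
  expect_true(dec$tested[dec$term == "HP:0001115"])
})

test_that("a 2x2 total below seven individuals is underpowered", {
  g <- filterGraph()
  counts <- countRows("HP:0001115", c(2L, 1L), c(3L, 3L))  # total assayed 6
  dec <- selectTestableTerms(counts, g, cohortSize = 10L)
  expect_identical(dec$reason, "UNDERPOWERED_TOTAL")
  # and 7 assayed passes the rule
  counts7 <- countRows("HP:0001115", c(2L, 1L), c(4L, 3L))
  expect_identical(selectTestableTerms(counts7, g, cohortSize = 10L)$reason,
                   "TESTED")
})

test_that("three genotype classes lower the power threshold to six", {
  g <- filterGraph()
  counts6 <- countRows("HP:0001115", c(2L, 1L, 1L), c(2L, 2L, 2L),
                       classes = c("AA", "AB", "BB"))
  dec <- selectTestableTerms(counts6, g, cohortSize = 6L)
  expect_identical(dec$reason, "TESTED")
  counts5 <- countRows("HP:0001115", c(2L, 1L, 1L), c(2L, 2L, 1L),
                       classes = c("AA", "AB", "BB"))
  expect_identical(selectTestableTerms(counts5, g, cohortSize = 6L)$reason,
                   "UNDERPOWERED_TOTAL")
})

test_that("terms assayed in under 40 percent of the cohort are skipped", {
  g <- filterGraph()
  counts <- countRows("HP:0001115", c(15L, 10L), c(20L, 19L))  # 39 of 100
  dec <- selectTestableTerms(counts, g, cohortSize = 100L)
  expect_identical(dec$reason, "LOW_COVERAGE")
  counts40 <- countRows("HP:0001115", c(15L, 10L), c(20L, 20L))
  expect_identical(selectTestableTerms(counts40, g, cohortSize = 100L)$reason,
                   "TESTED")
})

test_that("the subroot and its direct children are general-level skips", {
  g <- filterGraph()
  counts <- rbind(countRows("HP:0000707", c(8L, 7L), c(10L, 10L)),
                  countRows("HP:0000118", c(10L, 10L), c(10L, 10L)))
  dec <- selectTestableTerms(counts, g, cohortSize = 20L)
  expect_identical(dec$reason[dec$term == "HP:0000707"], "GENERAL_LEVEL")
  expect_identical(dec$reason[dec$term == "HP:0000118"], "GENERAL_LEVEL")
  # with depth 2 the grandchild level is also considered general
  dec2 <- selectTestableTerms(
    countRows("HP:0010696", c(8L, 7L), c(10L, 10L)), g, cohortSize = 20L,
    config = ifHpoConfig(generalLevelDepth = 2L))
  expect_identical(dec2$reason, "GENERAL_LEVEL")
})

test_that("a genotype class without any observation skips the term", {
  g <- filterGraph()
  counts <- countRows("HP:0001115", c(9L, 0L), c(12L, 0L))
  dec <- selectTestableTerms(counts, g, cohortSize = 20L)
  expect_identical(dec$reason, "EMPTY_GENOTYPE_CLASS")
})

test_that("each skip is attributed to the first matching rule in order", {
  g <- filterGraph()
  # direct child of the root that is also low-coverage: rule 1 wins
  counts <- countRows("HP:0000707", c(2L, 1L), c(3L, 2L))
  dec <- selectTestableTerms(counts, g, cohortSize = 100L)
  expect_identical(dec$reason, "GENERAL_LEVEL")
  # low coverage and underpowered: rule 3 wins over rule 4
  counts2 <- countRows("HP:0001115", c(2L, 1L), c(3L, 2L))
  dec2 <- selectTestableTerms(counts2, g, cohortSize = 100L)
  expect_identical(dec2$reason, "LOW_COVERAGE")
})

test_that("decisions are deterministic and independent of term order", {
  g <- makeToyOntology(4, 2, seed = 3, diamondFraction = 0.2)
  leaves <- ontologyLeaves(g)
  sim <- simulateCohort(g, simulationParams(
    seed = 21, effects = data.frame(term = leaves[1:4], freqA = 0.6,
                                    freqB = 0.4, coverage = 0.8)))
  pc <- phenotypeCounts(sim$cohort, g, simulationClassifier())
  d1 <- selectTestableTerms(pc$counts, g, pc$nClassified)
  shuffled <- pc$counts[withSeed(1, sample(nrow(pc$counts))), ]
  d2 <- selectTestableTerms(shuffled, g, pc$nClassified)
  expect_identical(d1, d2)
})

test_that("raising the coverage threshold only shrinks the tested set", {
  g <- makeToyOntology(4, 2, seed = 3)
  leaves <- ontologyLeaves(g)
  sim <- simulateCohort(g, simulationParams(
    seed = 22, effects = data.frame(term = leaves[1:6], freqA = 0.6,
                                    freqB = 0.4,
                                    coverage = c(0.3, 0.45, 0.6, 0.75, 0.9, 1))))
  pc <- phenotypeCounts(sim$cohort, g, simulationClassifier())
  prev <- NULL
  for (cov in c(0.2, 0.4, 0.6, 0.8)) {
    dec <- selectTestableTerms(pc$counts, g, pc$nClassified,
                               ifHpoConfig(minCoverage = cov))
    tested <- dec$term[dec$tested]
    if (!is.null(prev)) expect_true(all(tested %in% prev))
    prev <- tested
  }
})

test_that("redundant annotation chains leave fewer tested than annotated terms", {
  g <- makeToyOntology(5, 2)  # deep chains: leaf annotations echo upward
  leaves <- ontologyLeaves(g)
  sim <- simulateCohort(g, simulationParams(
    seed = 23, effects = data.frame(term = leaves[1:4], freqA = 0.7,
                                    freqB = 0.5, coverage = 1)))
  pc <- phenotypeCounts(sim$cohort, g, simulationClassifier())
  dec <- selectTestableTerms(pc$counts, g, pc$nClassified)
  expect_lt(sum(dec$tested), length(unique(pc$counts$term)))
})

test_that("the filter report lists verdicts with per-class counts", {
  g <- filterGraph()
  counts <- rbind(countRows("HP:0010696", c(7L, 3L), c(11L, 8L)),
                  countRows("HP:0001115", c(7L, 3L), c(11L, 8L)))
  dec <- selectTestableTerms(counts, g, cohortSize = 19L)
  path <- tempfile(fileext = ".tsv")
  writeFilterReport(dec, counts, g, path)
  rep <- read.delim(path)
  expect_setequal(rep$term, c("HP:0010696", "HP:0001115"))
  expect_identical(rep$observed_A[rep$term == "HP:0001115"], 7L)
  expect_identical(rep$assayed_B[rep$term == "HP:0001115"], 8L)
})
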