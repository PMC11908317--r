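test_that("toy ontology JSON loads with declared structure", {
  doc <- list(
    root = "TOY:0000001",
    terms = list(list(id = "TOY:0000001", label = "root"),
                 list(id = "TOY:0000002", label = "mid"),
                 list(id = "TOY:0000003", label = "leaf")),
    edges = list(list("TOY:0000003", "TOY:0000002"),
                 list("TOY:0000002", "TOY:0000001"))
  )
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  g <- loadOntology(path)
  expect_setequal(ontologyTerms(g), c("TOY:0000001", "TOY:0000002", "TOY:0000003"))
  expect_identical(ontologyRoot(g), "TOY:0000001")
  expect_identical(igraph::ecount(g@graph), 2)
  expect_identical(termAncestors(g, "TOY:0000003"),
                   c("TOY:0000002", "TOY:0000001"))
})

test_that("referential integrity and acyclicity are enforced at load", {
  expect_error(
    ontologyGraph(terms = c("A", "B"), edges = rbind(c("B", "A"), c("C", "A")),
                  root = "A"),
    "not declared")
  expect_error(
    ontologyGraph(terms = c("A", "B"), edges = rbind(c("A", "B"), c("B", "A")),
                  root = "A"),
    "cycle")
})

test_that("OBO-graph dialect loads, converting IRIs and resolving alt ids", {
  node <- function(num, lbl, alt = NULL, dep = FALSE) {
    n <- list(id = paste0("http://purl.obolibrary.org/obo/HP_", num), lbl = lbl)
    meta <- list()
    if (!is.null(alt))
      meta$basicPropertyValues <- list(list(
        pred = "http://www.geneontology.org/formats/oboInOwl#hasAlternativeId",
        val = paste0("HP:", alt)))
    if (dep) meta$deprecated <- TRUE
    if (length(meta)) n$meta <- meta
    n
  }
  edge <- function(sub, obj) list(
    sub = paste0("http://purl.obolibrary.org/obo/HP_", sub),
    pred = "is_a",
    obj = paste0("http://purl.obolibrary.org/obo/HP_", obj))
  doc <- list(graphs = list(list(
    nodes = list(node("0000118", "Phenotypic abnormality"),
                 node("0000518", "Cataract", alt = "0099999"),
                 node("0010920", "Zonular cataract"),
                 node("7777777", "obsolete thing", dep = TRUE)),
    # one edge points at the alternative id, which must resolve to 0000518
    edges = list(edge("0000518", "0000118"), edge("0010920", "0099999"))
  )))
  g <- loadOntology(doc, root = "HP:0000118")
  expect_setequal(ontologyTerms(g),
                  c("HP:0000118", "HP:0000518", "HP:0010920"))
  expect_true("HP:0000518" %in% termAncestors(g, "HP:0010920"))
  expect_identical(termLabel(g, "HP:0000518"), "Cataract")
})

test_that("ancestors follow the is-a chain up to the root", {
  g <- cataractGraph()
  anc <- termAncestors(g, "HP:0100018")
  expect_true(all(c("HP:0010920", "HP:0000518") %in% anc))
  expect_false("HP:0100018" %in% anc)
  expect_identical(termAncestors(g, "HP:0000118", includeSelf = TRUE),
                   "HP:0000118")
  expect_error(termAncestors(g, "HP:9999999"), "not in ontology")
})

test_that("diamond-shaped multiple inheritance yields the full closure", {
  g <- diamondGraph()
  expect_setequal(termAncestors(g, "D"), c("A", "B", "C"))
  expect_setequal(termDescendants(g, "A"), c("B", "C", "D"))
})

test_that("ancestors match brute-force reachability and are dual to descendants", {
  for (seed in 1:5) {
    g <- randomToyDag(nNodes = 10L + seed * 8L, seed = seed)
    terms <- ontologyTerms(g)
    probe <- withSeed(seed, sample(terms, 5))
    for (t in probe) {
      expect_setequal(termAncestors(g, t), reachOracle(g, t))
    }
    a <- terms[2]; b <- terms[1]
    expect_identical(b %in% termAncestors(g, a), a %in% termDescendants(g, b))
  }
})

test_that("observed annotations propagate to all ancestors", {
  g <- cataractGraph()
  prop <- propagateAnnotations(g, phRow("HP:0100018"))
  st <- setNames(prop$status, prop$term)
  expect_identical(unname(st["HP:0000518"]), "observed")
  expect_identical(unname(st["HP:0010920"]), "observed")
  expect_identical(unname(st["HP:0000118"]), "observed")
})

test_that("excluded annotations propagate to all descendants", {
  g <- cataractGraph()
  prop <- propagateAnnotations(g, phRow("HP:0000518", status = "excluded"))
  st <- setNames(prop$status, prop$term)
  expect_identical(unname(st["HP:0100018"]), "excluded")
  expect_false("HP:0000118" %in% prop$term)  # exclusion never travels upward
})

test_that("contradictory annotations are flagged conflicting, not erased", {
  g <- seizureGraph()
  prop <- propagateAnnotations(g, rbind(
    phRow("HP:0032792"),                       # Tonic seizure observed
    phRow("HP:0001250", status = "excluded"))) # Seizure excluded
  st <- setNames(prop$status, prop$term)
  expect_identical(unname(st["HP:0001250"]), "conflict")
})

test_that("propagation is idempotent and monotone in observed annotations", {
  g <- makeToyOntology(4, 2, seed = 7, diamondFraction = 0.3)
  leaves <- ontologyLeaves(g)
  base <- rbind(phRow(leaves[1]), phRow(leaves[3], status = "excluded"))
  once <- propagateAnnotations(g, base)
  twice <- propagateAnnotations(
    g, data.frame(term = once$term,
                  status = ifelse(once$status == "conflict", "observed", once$status),
                  onsetDays = NA_real_))
  onceClean <- once[once$status != "conflict", ]
  expect_true(all(onceClean$status ==
                    twice$status[match(onceClean$term, twice$term)]))
  # adding an observation never removes an observed status
  more <- propagateAnnotations(g, rbind(base, phRow(leaves[2])))
  obsBefore <- once$term[once$status == "observed"]
  expect_true(all(obsBefore %in% more$term[more$status %in%
                                             c("observed", "conflict")]))
})
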