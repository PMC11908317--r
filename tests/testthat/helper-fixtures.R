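# internal helpers used when building fixtures
withSeed <- PhenoGPC:::withSeed
emptyPhenotypes <- PhenoGPC:::emptyPhenotypes

# Fixture graphs -------------------------------------------------------------

# HP:0000118 <- Cataract <- Zonular cataract <- Nuclear cataract
cataractGraph <- function() {
  ontologyGraph(
    terms = c("HP:0000118", "HP:0000518", "HP:0010920", "HP:0100018"),
    labels = c("Phenotypic abnormality", "Cataract", "Zonular cataract",
               "Nuclear cataract"),
    edges = rbind(c("HP:0000518", "HP:0000118"),
                  c("HP:0010920", "HP:0000518"),
                  c("HP:0100018", "HP:0010920")),
    root = "HP:0000118")
}

# HP:0000118 <- Seizure <- {Tonic seizure, Generalized myoclonic seizure}
seizureGraph <- function() {
  ontologyGraph(
    terms = c("HP:0000118", "HP:0001250", "HP:0032792", "HP:0002123"),
    labels = c("Phenotypic abnormality", "Seizure", "Tonic seizure",
               "Generalized myoclonic seizure"),
    edges = rbind(c("HP:0001250", "HP:0000118"),
                  c("HP:0032792", "HP:0001250"),
                  c("HP:0002123", "HP:0001250")),
    root = "HP:0000118")
}

# diamond: D -> B, D -> C, B -> A, C -> A
diamondGraph <- function() {
  ontologyGraph(terms = c("A", "B", "C", "D"),
                edges = rbind(c("D", "B"), c("D", "C"),
                              c("B", "A"), c("C", "A")),
                root = "A")
}

# random DAG on a layered vertex set; every non-root node gets >= 1 parent
# from an earlier layer, so the root reaches everything
randomToyDag <- function(nNodes, seed) {
  withSeed(seed, {
    ids <- sprintf("TOY:%07d", seq_len(nNodes))
    edges <- NULL
    for (i in 2:nNodes) {
      nParents <- sample(1:min(2L, i - 1L), 1)
      parents <- sample(seq_len(i - 1L), nParents)
      edges <- rbind(edges, cbind(ids[i], ids[parents]))
    }
    ontologyGraph(ids, ids, edges, root = ids[1])
  })
}

# independent reachability oracle: repeated adjacency-matrix closure,
# no igraph involved
reachOracle <- function(graph, from) {
  terms <- ontologyTerms(graph)
  n <- length(terms)
  adj <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  el <- igraph::as_edgelist(graph@graph)
  for (i in seq_len(nrow(el))) adj[el[i, 1], el[i, 2]] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  terms[reach[from, ]]
}

# Individual builders ---------------------------------------------------------

phRow <- function(term, status = "observed", onsetDays = NA_real_) {
  data.frame(term = term, status = status, onsetDays = onsetDays,
             stringsAsFactors = FALSE)
}

makeInd <- function(id, terms = character(), excluded = character(),
                    variants = list(), ...) {
  ph <- rbind(
    if (length(terms)) do.call(rbind, lapply(terms, phRow)) else NULL,
    if (length(excluded)) do.call(rbind, lapply(excluded, phRow,
                                                status = "excluded")) else NULL)
  Individual(id = id, phenotypes = if (is.null(ph)) emptyPhenotypes() else ph,
             variants = variants, ...)
}

missenseVariant <- function(alleleCount = 1L, key = "v-mis") {
  VariantRecord(key = key, contig = "1", pos = 100L, ref = "A", alt = "G",
                effects = "missense_variant", proteinStart = 50L,
                proteinEnd = 50L, exons = 2L, alleleCount = alleleCount)
}

stopGainedVariant <- function(alleleCount = 1L, key = "v-stop") {
  VariantRecord(key = key, contig = "1", pos = 200L, ref = "C", alt = "T",
                effects = "stop_gained", proteinStart = 80L, proteinEnd = 80L,
                exons = 3L, alleleCount = alleleCount)
}

# Statistical oracles ---------------------------------------------------------

# two-sided FET by hypergeometric enumeration (2x2, rows = classes)
fetOracle2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Freeman-Halton exact p for a k x 2 table by full enumeration of tables
# with the observed margins, under the multivariate hypergeometric null
freemanHaltonOracle <- function(tab) {
  rows <- rowSums(tab); cols <- colSums(tab); k <- nrow(tab)
  logProb <- function(x) {
    # x = first column entries; second column = rows - x
    sum(lchoose(rows, x)) - lchoose(sum(rows), cols[1])
  }
  grid <- expand.grid(lapply(seq_len(k), function(i) 0:rows[i]))
  keep <- rowSums(grid) == cols[1]
  grid <- grid[keep, , drop = FALSE]
  lp <- apply(grid, 1, logProb)
  pobs <- logProb(tab[, 1])
  sum(exp(lp[lp <= pobs + log(1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration of all group splits
mwuPermutationOracle <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  uStat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- uStat(a, b)
  splits <- utils::combn(length(pooled), nA)
  mu <- nA * length(b) / 2
  us <- apply(splits, 2, function(idx) uStat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# logrank chi-square by direct risk-table tabulation
logrankOracle <- function(a, b) {
  times <- sort(unique(c(a$duration[a$event], b$duration[b$event])))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    nA <- sum(a$duration >= t); nB <- sum(b$duration >= t); n <- nA + nB
    dA <- sum(a$duration == t & a$event); dB <- sum(b$duration == t & b$event)
    d <- dA + dB
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# definitional BH step-up
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  out <- numeric(m); out[o] <- adj
  out
}

# random contingency tables with bounded totals
randomTable <- function(k, maxTotal, seed) {
  withSeed(seed, {
    repeat {
      tab <- matrix(rpois(2 * k, lambda = 3), nrow = k)
      if (sum(tab) <= maxTotal && sum(tab) > 0) return(tab)
    }
  })
}
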