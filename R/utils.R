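`%||%` <- function(a, b) if (is.null(a)) b else a

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a base seed and an index.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

emptyPhenotypes <- function() {
  data.frame(term = character(), status = character(),
             onsetDays = numeric(), stringsAsFactors = FALSE)
}

emptyDiseases <- function() {
  data.frame(id = character(), label = character(),
             onsetDays = numeric(), stringsAsFactors = FALSE)
}

emptyMeasurements <- function() {
  data.frame(assay = character(), value = numeric(),
             unit = character(), stringsAsFactors = FALSE)
}
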