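---
title: "Statistical characterization of genotype-phenotype correlations in rare-disease cohorts"
author: "PhenoGPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical characterization of genotype-phenotype correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoGPC)
```

## The problem

A genotype-phenotype correlation (GPC) is an above-chance association
between a class of causal variants and a clinical feature, an onset age, or
a severity grade. In rare Mendelian disease such correlations are rarely
absolute -- a variant class shifts the *frequency* of a feature or the
*timing* of its onset. Detecting them requires (i) case-level records that
carry phenotypes, variants, measurements and vital status together, and
(ii) statistics that respect the ontological structure of phenotype
vocabularies. PhenoGPC works on cohorts of GA4GH v2 phenopackets annotated
with Human Phenotype Ontology (HPO) terms and provides the full workflow:
genotype partitioning, annotation propagation, hypothesis filtering,
testing, and reporting.

## Annotation propagation (the true path rule)

HPO curation records the most specific applicable term. Because the
ontology is an is-a DAG, an annotation at *Nuclear cataract* entails the
parent *Zonular cataract* and grandparent *Cataract*: every observed
annotation is therefore propagated to all ancestors before any counting
(`propagateAnnotations()`). Excluded annotations propagate in the opposite
direction: excluding a general term excludes all of its specializations.
The downward rule for exclusions is a design choice -- ontology semantics
entail it, and without it the "excluded" column of the contingency tables
would undercount -- and it is what makes a term reached by both closures
possible. Such a term (e.g. a child observed while its parent is excluded)
is flagged `conflict` and dropped from that individual's analyzable set:
contradictory information is unusable, and no attempt is made to repair it.
Absence of a term always means "not assayed", never "excluded".

## Genotype partitioning

Variant predicates are Boolean trees over variant attributes: functional
effect, exon overlap, protein-region overlap (closed intervals, 1-based),
variant key, structural type, change length, reference length, and a
structural-deletion test (imprecise chromosomal deletion, or sequence
deletion of at least 50 bp by default). A leaf whose attribute is missing
on a variant evaluates to `FALSE` rather than erroring, so one predicate
runs across mixed SNV/SV cohorts. Five classifiers build the partition:
monoallelic, biallelic (three-way AA/AB/BB or either two-way coarsening),
allele count, sex, and diagnosis. Individuals fitting no class are
*omitted* and tallied; classes plus the omitted set always cover the
cohort. Two deliberate edge rules: monoallelic and biallelic classification
presume the A/B predicates bipartition the observed alleles, so an allele
matching both predicates omits the individual with a warning; hemizygous
genotypes count as one allele, which places hemizygous males and
heterozygous females of an X-linked cohort in the same class.

## Independent filtering before categorical testing

Cohorts annotate hundreds of HPO terms, most of them redundant echoes of
more specific annotations, and correcting across all of them wastes power.
The filter decides, per term and *before any p-value is computed*, whether
a Fisher exact test will be run. Five rules apply in a fixed order, each
skip attributed to the first matching rule:

1. **General level** -- the phenotypic-abnormality subroot and its direct
   children. The depth is configurable (`generalLevelDepth`); the default
   of one level reflects the view that a real signal will surface in a
   more specific descendant.
2. **Same as child** -- identical per-class observed/excluded counts as
   one of the term's annotated children; the test would be arithmetically
   identical, and the more specific term is the more informative one.
3. **Low coverage** -- assayed (observed + excluded) in less than
   `minCoverage` (default 0.4) of the cohort. A config flag restricts
   coverage to observed annotations only. The denominator is a choice the
   caller controls: the runner passes the number of genotype-classified
   individuals, since omitted individuals cannot contribute counts.
4. **Underpowered total** -- fewer than 7 assayed individuals for a 2x2
   table (6 for 3x2): no table with those margins can reach nominal
   significance, so the test is pointless. The thresholds are treated as
   fixed constants.
5. **Empty genotype class** -- a class with neither observed nor excluded
   annotations for the term.

Because every decision is a function of counts and graph structure only,
the filter is independent of the test statistic under the null, which is
exactly the property that lets the later correction run over the reduced
hypothesis set without inflating the type-I error. The acceptance suite
demonstrates this by flipping the class-phenotype association (changing
the p-value) without changing a single decision.

## The statistical routes

* **Categorical** (`runCategorical()`): per tested term, a k x 2 table of
  propagated observed/excluded counts and a two-sided Fisher exact test
  (point-probability criterion for 2x2, within a 1e-7 relative tolerance
  against float boundary flips; Freeman-Halton for 3x2; degenerate margins
  give p = 1 by convention). Adjustment runs across exactly the performed
  tests; Benjamini-Hochberg by default, with Bonferroni, Sidak,
  Holm, Holm-Sidak, Hochberg, Hommel, BY, the two adaptive two-stage
  linear step-up procedures and `NONE` as alternatives. Hypotheses can
  also be a user term list (no filter; adjustment across the listed terms)
  or all annotated terms.
* **Scores** (`applyScorer()`): the counting scorer awards one point per
  target term with at least one observed annotation at the term or a
  descendant; the modified de Vries score implements the
  ID/growth/dysmorphism/anomaly rubric over HPO terms (documented in
  `defaultDeVriesRubric()`, total in [0, 10], every term remappable).
  Facial features are counted on *source* annotations, not propagated
  ones, since propagation would inflate a single deep annotation into a
  whole chain. A scorer returning `NaN` excludes the individual. Classes
  are compared by Mann-Whitney U: exact null distribution when both
  groups have at most 8 scores and no ties, otherwise the normal
  approximation with tie and continuity correction.
* **Measurements** (`runContinuous()`): unpaired two-sided t-test on one
  coded assay. The pooled-variance Student form is the default -- the
  source framework does not specify a variant, and the pooled form is the
  textbook reading of "Student's t test" -- with Welch available by flag.
* **Survival** (`runSurvival()`): per individual one right-censored datum
  for a death, disease-onset or term-onset endpoint. Term onsets roll up:
  the youngest onset among the endpoint term and its observed descendants
  is the event age. An observed endpoint without a recorded onset age is
  *missing*, never imputed; individuals without the event censor at the
  age of last encounter; a day-zero (congenital) onset is floored to half
  a day so the positive-time survival machinery keeps the event. The
  logrank test (hypergeometric tie handling, chi-square with 1 df)
  compares the classes, with Kaplan-Meier tables exported per class.

Score, measurement and survival results carry no multiple-testing
correction: each is a distinct user-chosen hypothesis, reported raw with
its exclusion tally. Significance is p < 0.05 throughout unless the caller
overrides `alpha`. Ages are stored in days (1 y = 365.25 d, 1 mo =
30.44 d) and displayed in years.

## What the simulator emulates -- and what it does not

`simulateCohort()` generates phenopacket-subset records from per-individual
RNG streams derived from `(seed, index)`, so cohorts are reproducible and
byte-identical across runs. It emulates: class-conditional variant
templates (heterozygous missense vs stop-gained), Bernoulli
observed/excluded annotations at chosen terms with an assay-coverage
probability (unassayed terms are absent, as in real curation), exponential
onset ages with right censoring, and normally distributed measurements.
Annotations are planted at leaves, so internal-node counts arise only
through propagation -- which is what exercises the same-as-child filter
rule naturally.

It does **not** emulate: correlated phenotypes within an individual,
curation-depth heterogeneity across publications, ascertainment and
publication bias, allelic series beyond the two template variants, or
linkage structure. A passing recovery test therefore shows the pipeline
detects the effects it models, not that real cohorts are free of the
biases the simulator omits.

## Calibration and power conditions

The fixed study conditions used by the tests and the acceptance script:

* **Raw type-I rate**: 1000 null 2x2 tables, 150 individuals per class,
  Bernoulli(0.5) phenotype. The class size was chosen by exhaustively
  enumerating the binomial-weighted rejection probability of the exact
  test before any simulation was run: the true rate is 0.0431 at n = 150
  (0.0352 at n = 50, 0.0400 at n = 100); the discreteness of the exact
  test keeps smaller tables overly conservative, and 150 centres the
  Monte-Carlo estimate in the 0.03-0.06 calibration band.
* **Null pipeline**: 100 replicates, 50 per class, eight leaf terms at
  frequency 0.5 in both classes, full coverage; at least 95% of replicates
  must report zero BH-significant terms.
* **Planted recovery**: frequency 0.8 vs 0.2 at one leaf (siblings at
  0.5/0.5), 50 per class, 100 replicates, detection = adjusted p < 0.05
  for the planted term.
* **Survival power**: hazard ratio 3 (exponential onsets, rates 1/3650
  and 3/3650 per day), 30 per class, 20% censoring, 200 replicates,
  logrank p < 0.05.

These sizes keep the whole acceptance run in a few minutes on one core
while leaving comfortable Monte-Carlo margins around each criterion.

## Known limitations

Only is-a edges are used (no part-of or modifier axes). Variant functional
annotation must arrive in the input records or through a user annotator;
the package deliberately performs no transcript annotation and no network
calls. Individuals with more than two causal alleles are rejected at
validation rather than modeled. The lollipop figure displays only variants
with protein coordinates; non-coding and structural variants are counted
in an omission tally. The de Vries rubric is one documented
operationalization of a score whose original item weights are not fully
recoverable; users with a validated local rubric should override the
defaults.
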