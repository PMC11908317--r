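#' Two-sided Fisher exact test on a k x 2 contingency table
#'
#' Rows are genotype classes, columns are (phenotype observed, phenotype
#' excluded). For 2x2 tables the two-sided p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (within a 1e-7
#' relative tolerance against floating-point boundary flips); for k = 3 the
#' Freeman-Halton generalization enumerates all margin-preserving tables. A
#' degenerate margin (a zero row or column sum) yields p = 1 by convention.
#'
#' @param table integer matrix with k rows (2 or 3 genotype classes) and 2
#'   columns; all entries non-negative.
#' @return the raw two-sided p-value.
#' @export
fisherExactTest <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) != 2L || !(nrow(table) %in% c(2L, 3L)))
    stop("contingency table must be 2x2 or 3x2")
  if (any(table < 0) || any(table != round(table)))
    stop("contingency table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Multiple-testing correction
#'
#' Adjusted p-values under one of ten classical procedures (or `NONE`).
#' `BONFERRONI`, `HOLM`, `HOCHBERG`, `HOMMEL`, `BH` and `BY` follow the
#' standard definitions; `SIDAK` is the single-step Sidak correction
#' `1 - (1 - p)^m`; `HOLM_SIDAK` the step-down Sidak analogue of Holm;
#' `TWO_STAGE_BH` and `FDR_TSBKY` are the adaptive two-stage linear step-up
#' procedures (the latter the Benjamini-Krieger-Yekutieli Definition-6
#' variant), whose adjusted values are specific to `alpha`. `BH` is the
#' default throughout the package.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param method one of `BONFERRONI`, `SIDAK`, `HOLM`, `HOLM_SIDAK`,
#'   `HOCHBERG`, `HOMMEL`, `BH`, `BY`, `TWO_STAGE_BH`, `FDR_TSBKY`, `NONE`.
#' @param alpha target error rate for the two-stage procedures.
#' @return adjusted p-values, in input order, clipped at 1.
#' @export
adjustPvalues <- function(p, method = "BH", alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  method <- toupper(method)
  m <- length(p)
  if (m == 0L) return(numeric())
  out <- switch(method,
    NONE = p,
    BONFERRONI = stats::p.adjust(p, "bonferroni"),
    HOLM = stats::p.adjust(p, "holm"),
    HOCHBERG = stats::p.adjust(p, "hochberg"),
    HOMMEL = stats::p.adjust(p, "hommel"),
    BH = stats::p.adjust(p, "BH"),
    BY = stats::p.adjust(p, "BY"),
    SIDAK = 1 - (1 - p)^m,
    HOLM_SIDAK = {
      o <- order(p)
      raw <- -expm1((m - seq_len(m) + 1) * log1p(-p[o]))
      adj <- cummax(raw)
      res <- numeric(m); res[o] <- adj; res
    },
    TWO_STAGE_BH = twoStageBH(p, alpha, bky = FALSE),
    FDR_TSBKY = twoStageBH(p, alpha, bky = TRUE),
    stop("unknown multiple-testing method: ", method)
  )
  pmin(out, 1)
}

# Adaptive two-stage linear step-up FDR (single iteration). Stage 1
# estimates the number of true nulls m0 from a BH pass at level
# alpha' (= alpha/(1+alpha) for the BKY Definition-6 variant), stage 2
# rescales the BH-adjusted values by m0/m.
twoStageBH <- function(p, alpha, bky) {
  m <- length(p)
  fact <- if (bky) 1 + alpha else 1
  alphaPrime <- alpha / fact
  bh <- stats::p.adjust(p, "BH")
  r1 <- sum(bh <= alphaPrime)
  if (r1 == 0L || r1 == m) return(pmin(bh * fact, 1))
  pmin(bh * ((m - r1) / m) * fact, 1)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided comparison of two score distributions. The exact null
#' distribution is used when both groups have at most 8 non-missing scores
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction. `NaN` scores must be removed by the caller (they
#' mark individuals excluded from scoring).
#'
#' @param scoresA,scoresB numeric vectors, each with at least one value.
#' @return list with `U` (the Mann-Whitney U statistic of the first group)
#'   and `p` (two-sided).
#' @export
mannWhitneyU <- function(scoresA, scoresB) {
  if (!length(scoresA) || !length(scoresB))
    stop("each group needs at least one non-missing score")
  pooled <- c(scoresA, scoresB)
  if (length(unique(pooled)) == 1L) {
    # fully tied: the groups are exchangeable, no evidence either way
    return(list(U = length(scoresA) * length(scoresB) / 2, p = 1))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- length(scoresA) <= 8L && length(scoresB) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(scoresA, scoresB, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Unpaired two-sided t-test
#'
#' Pooled-variance Student form by default (`welch = TRUE` for the Welch
#' unequal-variance form). Degenerate input: zero variance in both groups
#' with equal means gives t = 0, p = 1; with different means the statistic
#' is infinite and p = 0.
#'
#' @param valuesA,valuesB numeric vectors of at least 2 values each.
#' @param welch use the Welch form instead of pooled variance.
#' @return list with `t`, `df` and `p`.
#' @export
studentTTest <- function(valuesA, valuesB, welch = FALSE) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs at least two values")
  if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0) {
    df <- length(valuesA) + length(valuesB) - 2
    if (mean(valuesA) == mean(valuesB)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(valuesA) - mean(valuesB)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(valuesA, valuesB, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Logrank test on two right-censored groups
#'
#' Standard logrank chi-square with 1 degree of freedom over the pooled
#' distinct event times, ties handled by the hypergeometric variance
#' formula; the p-value comes from the chi-square survival function. Groups
#' with no event anywhere cannot be tested (the caller reports the analysis
#' as not performed).
#'
#' @param groupA,groupB data.frames with columns `duration` (positive days)
#'   and `event` (logical; `FALSE` = right-censored).
#' @return list with `chi2` and `p`.
#' @export
logrankTest <- function(groupA, groupB) {
  stopifnot(nrow(groupA) >= 1L, nrow(groupB) >= 1L)
  if (!any(groupA$event) && !any(groupB$event))
    stop("no events in either group")
  time <- c(groupA$duration, groupB$duration)
  if (any(time <= 0)) stop("durations must be positive")
  event <- as.integer(c(groupA$event, groupB$event))
  grp <- rep(c("A", "B"), c(nrow(groupA), nrow(groupB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier table from right-censored data
#'
#' @param data data.frame with columns `duration` and `event`.
#' @return data.frame `time`, `nRisk`, `nEvent`, `survival`; the survival
#'   estimate starts at 1 and is non-increasing.
#' @export
kaplanMeierTable <- function(data) {
  fit <- survival::survfit(survival::Surv(data$duration, as.integer(data$event)) ~ 1)
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             survival = fit$surv)
}
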