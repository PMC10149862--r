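## Cohort statistics: exact tie-corrected Mann-Whitney U, Kruskal-Wallis and
## log-rank wrappers, 2^-ddCt relative expression, and the group summary.

#' Exact tie-corrected Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic with ties counted one half, and a
#' two-sided p-value. For combined sample sizes up to `exactLimit` the
#' p-value is exact: the full permutation distribution of the rank sum over
#' all equally likely assignments of the pooled observations to the two
#' groups is obtained by a shift (dynamic-programming) convolution over the
#' doubled midranks, which are integers even under ties, so the tail count is
#' computed in exact integer arithmetic. For larger samples a
#' tie-corrected normal approximation is used.
#'
#' Two two-sided conventions are available: `"distance"` (default) sums the
#' probability of all assignments whose U lies at least as far from the null
#' mean n1*n2/2 as observed; `"double"` doubles the smaller one-sided tail
#' (capped at 1).
#'
#' For binary data the exact test reduces to a two-tailed hypergeometric
#' computation, since U is affine in the number of positives assigned to one
#' group; this reproduces published two-group incidence contrasts from their
#' printed counts alone.
#'
#' @param x,y numeric samples for the two groups.
#' @param exactLimit use the exact distribution when
#'   `length(x) + length(y) <= exactLimit` (default 40).
#' @param twoSided `"distance"` or `"double"` (see Details).
#' @return object of class `"mwTest"`: list with `U`, `p`, `method`
#'   (`"exact"` or `"normal-approximation"`), `n1`, `n2`.
#' @examples
#' # D-NEC incidence 12/18 vs 4/17 from printed counts:
#' mannWhitneyExact(rep(c(1, 0), c(12, 6)), rep(c(1, 0), c(4, 13)))
#' @export
mannWhitneyExact <- function(x, y, exactLimit = 40,
                             twoSided = c("distance", "double")) {
  twoSided <- match.arg(twoSided)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    validationError("mannWhitneyExact: empty sample")
  if (anyNA(x) || anyNA(y)) validationError("mannWhitneyExact: NA in data")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (N <= exactLimit) {
    r2 <- as.integer(round(2 * r))          # doubled midranks: exact integers
    counts <- rankSumCounts(r2, n1)          # over doubled rank sums 0..maxS
    s2 <- seq_along(counts) - 1L
    m2 <- n1 * (N + 1)                       # doubled null mean rank sum
    s2obs <- sum(r2[seq_len(n1)])
    total <- choose(N, n1)
    if (twoSided == "distance") {
      p <- sum(counts[abs(s2 - m2) >= abs(s2obs - m2)]) / total
    } else {
      lo <- sum(counts[s2 <= s2obs]) / total
      hi <- sum(counts[s2 >= s2obs]) / total
      p <- min(1, 2 * min(lo, hi))
    }
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(U = U, p = p, method = method, n1 = n1, n2 = n2),
            class = "mwTest")
}

## Number of size-n1 subsets of the doubled midranks r2 attaining each doubled
## rank sum 0..max. Counts stay below 2^53 for N <= 40, so doubles are exact.
rankSumCounts <- function(r2, n1) {
  maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, n1 + 1, maxS + 1)
  f[1, 1] <- 1
  for (r in r2) {
    for (k in n1:1) {
      idx <- seq_len(maxS + 1 - r)
      f[k + 1, idx + r] <- f[k + 1, idx + r] + f[k, idx]
    }
  }
  f[n1 + 1, ]
}

#' @export
print.mwTest <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat(sprintf("U = %g, n = %d/%d, two-sided p = %.4g\n",
              x$U, x$n1, x$n2, x$p))
  invisible(x)
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' Thin wrapper over [stats::kruskal.test] returning the tie-corrected H and
#' its chi-square p-value on k-1 degrees of freedom. When every pooled value
#' is identical the statistic is defined as H = 0 with p = 1.
#'
#' @param values numeric vector, or a list of group samples.
#' @param groups group labels parallel to `values` (ignored when `values` is
#'   a list).
#' @return list with `H`, `p`, `df`.
#' @export
kruskalWallisTest <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (any(tabulate(groups) == 0) || nlevels(groups) < 2)
    validationError("kruskalWallisTest: need >= 2 nonempty groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Log-rank (Mantel-Cox) survival contrast
#'
#' Wraps [survival::survdiff] (rho = 0) for the all-cause mortality contrast,
#' censoring survivors at study end.
#'
#' @param time event/censoring times (h).
#' @param event 1 = death/euthanasia, 0 = censored at study end.
#' @param group group labels.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  if (!any(event == 1)) validationError("logrankTest: no events")
  if (length(unique(group)) < 2)
    validationError("logrankTest: need >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data.frame(time = time, event = event,
                                             group = group))
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Relative gene expression by the 2^-ddCt method
#'
#' dCt = Ct(target) - Ct(reference); ddCt subtracts the mean dCt of the
#' calibrator group; fold change is 2^-ddCt, so the calibrator group's
#' geometric-mean fold is 1 by construction.
#'
#' @param ctTarget,ctReference cycle-threshold values per sample.
#' @param group group labels per sample.
#' @param calibrator the calibrator (control) group label.
#' @return data.frame with `group`, `dct`, `ddct`, `fold`.
#' @examples
#' ddctFoldChange(c(25, 24), c(20, 20), c("ctrl", "trt"), "ctrl")
#' @export
ddctFoldChange <- function(ctTarget, ctReference, group, calibrator) {
  if (anyNA(ctReference) || anyNA(ctTarget))
    validationError("ddctFoldChange: missing Ct value")
  if (!any(group == calibrator))
    validationError("ddctFoldChange: calibrator group is empty")
  dct <- ctTarget - ctReference
  ddct <- dct - mean(dct[group == calibrator])
  data.frame(group = group, dct = dct, ddct = ddct, fold = 2^(-ddct))
}

#' Group-level summary of a scored cohort
#'
#' Tabulates per-group incidences of the four D-NEC criteria and the
#' composite call, the percent of the group that died with D-NEC
#' ("percent death associated with NEC": D-NEC-positive non-survivors over
#' group size), mean percent weight change, and exact Mann-Whitney contrasts
#' for the binary D-NEC and translocation calls and for weight change.
#'
#' @param cohort a [PigletCohort-class].
#' @param panel criteria panel from [dnecClassify()]; recomputed if NULL.
#' @return object of class `"cohortSummary"`: list with `groups` (data.frame
#'   of per-group counts/fractions) and `tests` (named p-values).
#' @examples
#' cohortSummary(fixtureCohort())
#' @export
cohortSummary <- function(cohort, panel = NULL) {
  stopifnot(is(cohort, "PigletCohort"))
  if (is.null(panel)) panel <- dnecClassify(cohort)
  p <- piglets(cohort)
  panel <- panel[match(p$id, panel$id), ]
  wchg <- weightChangePercent(p$birth_weight_kg, p$final_weight_kg)
  died <- p$outcome != "survived"

  bygroup <- lapply(split(seq_len(nrow(p)), p$group), function(ix) {
    n <- length(ix)
    data.frame(
      group = p$group[ix[1]], n = n,
      gross = sum(panel$gross_positive[ix]),
      histo = sum(panel$histo_positive[ix]),
      histo_moderate = sum(panel$histo_category[ix] == "moderate" &
                             panel$histo_positive[ix]),
      histo_severe = sum(panel$histo_category[ix] == "severe"),
      translocation = sum(panel$translocation_positive[ix]),
      dnec = sum(panel$dnec[ix]),
      dnec_fraction = mean(panel$dnec[ix]),
      deaths = sum(died[ix]),
      dnec_deaths = sum(panel$dnec[ix] & died[ix]),
      pct_death_with_nec = 100 * sum(panel$dnec[ix] & died[ix]) / n,
      mean_weight_change_pct = mean(wchg[ix]))
  })
  groups <- do.call(rbind, bygroup)
  rownames(groups) <- NULL
  if (nrow(groups) < 2)
    validationError("cohortSummary: need both feeding groups")

  byg <- split(seq_len(nrow(p)), p$group)
  g1 <- byg[["formula"]]; g2 <- byg[["colostrum"]]
  if (is.null(g1) || is.null(g2))
    validationError("cohortSummary: need both feeding groups")
  tests <- list(
    dnec = mannWhitneyExact(as.numeric(panel$dnec[g1]),
                            as.numeric(panel$dnec[g2])),
    translocation = mannWhitneyExact(
      as.numeric(panel$translocation_positive[g1]),
      as.numeric(panel$translocation_positive[g2])),
    weight_change = mannWhitneyExact(wchg[g1], wchg[g2]))
  structure(list(groups = groups,
                 tests = lapply(tests, function(t)
                   list(U = t$U, p = t$p, method = t$method,
                        n1 = t$n1, n2 = t$n2))),
            class = "cohortSummary")
}

#' @export
print.cohortSummary <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$groups, row.names = FALSE)
  for (nm in names(x$tests))
    cat(sprintf("  %s contrast (formula vs colostrum): p = %.4g [%s]\n",
                nm, x$tests[[nm]]$p, x$tests[[nm]]$method))
  invisible(x)
}
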