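## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Brute-force exact two-sided Mann-Whitney p over all C(N, n1) assignments
## of the pooled values to group 1 (distance-from-mean convention, midranks).
mwBruteForce <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  sets <- utils::combn(N, n1)
  dists <- apply(sets, 2, function(ix) abs(sum(r[ix]) - mu))
  mean(dists >= obs - 1e-9)
}

## Closed-form two-tailed hypergeometric reduction for binary data: U is
## affine in the count k of positives assigned to group 1, so the
## distance-tail over assignments is a hypergeometric tail over k.
mwBinaryHypergeom <- function(n1pos, n1, n2pos, n2) {
  K <- n1pos + n2pos
  N <- n1 + n2
  k <- max(0, K - n2):min(n1, K)
  prob <- dhyper(k, K, N - K, n1)
  center <- n1 * K / N
  mean_dist <- abs(n1pos - center)
  sum(prob[abs(k - center) >= mean_dist - 1e-9])
}

## Star tree over the rownames of a relative-abundance matrix; oracle
## distance is sum_i len_i |p_Ai - p_Bi|.
starTree <- function(taxa, lens) {
  txt <- paste0("(", paste(sprintf("%s:%.15f", taxa, lens), collapse = ","),
                ");")
  ape::read.tree(text = txt)
}

starUnifracOracle <- function(P, lens) {
  n <- ncol(P)
  D <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(lens * abs(P[, i] - P[, j]))
  D
}

## Small random FeatureTable (no taxonomy/tree) for structural properties.
randomFeatureTable <- function(nTaxa = 12, nSamples = 5, lambda = 20) {
  m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa,
              dimnames = list(sprintf("t%02d", seq_len(nTaxa)),
                              sprintf("s%02d", seq_len(nSamples))))
  featureTable(m)
}

## One-piglet record pieces for criterion-level property tests.
randomCriteriaInputs <- function() {
  list(gross = sample(1:6, 4, replace = TRUE),
       histo = sample(1:5, 4, replace = TRUE),
       times = seq(12, 48, by = 4),
       totals = sample(0:8, 10, replace = TRUE),
       endTime = 48,
       cfu = round(rexp(3, 1 / 5), 2))
}

dnecFromInputs <- function(z, th = dnecThresholds()) {
  flags <- c(
    animalGrossScore(z$gross, th$gross)$positive,
    animalHistoScore(z$histo, th$histo)$positive,
    maxCssLastWindow(z$times, z$totals, z$endTime, th$cssWindow,
                     th$css)$positive,
    translocationCriterion(c("liver", "spleen", "mln"), z$cfu, th$cfu,
                           th$organs)$positive)
  list(flags = flags, dnec = sum(flags) >= th$minCriteria)
}
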