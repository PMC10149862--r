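## Downstream 16S analysis from a denoised feature table: rarefaction,
## prevalence filter, taxonomy collapse, alpha diversity, weighted UniFrac,
## PCoA, PERMANOVA, per-taxon abundance contrasts.

#' Rarefy a feature table to a common depth
#'
#' Each sample with at least `depth` total reads is subsampled without
#' replacement to exactly `depth`; shallower samples are dropped with a
#' warning. A single draw is taken per sample; the draw is reproducible under
#' `seed`.
#'
#' @param x a [FeatureTable-class].
#' @param depth target reads per sample (the study default is 18755).
#' @param seed integer seed for the subsampling draw (NULL uses the current
#'   RNG stream).
#' @return a rarefied `FeatureTable`; every retained column sums to `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  stopifnot(is(x, "FeatureTable"))
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    validationError("rarefy: depth must be a positive integer")
  tot <- colSums(counts(x))
  keep <- tot >= depth
  if (!any(keep)) validationError("rarefy: no sample reaches the depth")
  if (any(!keep))
    warning("rarefy: dropping ", sum(!keep), " sample(s) below depth ",
            depth, ": ", paste(colnames(counts(x))[!keep], collapse = ", "))
  m <- counts(x)[, keep, drop = FALSE]
  out <- withSeed(seed, {
    apply(m, 2, function(col) {
      reads <- rep.int(seq_along(col), col)
      drawn <- reads[sample.int(length(reads), depth)]
      tabulate(drawn, nbins = length(col))
    })
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m),
                                     dimnames = list(rownames(m), colnames(m)))
  rownames(out) <- rownames(m)
  sub <- subsetFeatureTable(x, samples = which(keep))
  featureTable(out, taxonomy(sub), phyloTree(sub), sampleData(sub))
}

#' Drop low-prevalence taxa
#'
#' Removes taxa present (count > 0) in fewer than `ceiling(minFraction *
#' nSamples)` samples — with 26 samples and the default 10% this is the
#' "present in fewer than 3/26 samples" rule. An explicit `minCount`
#' overrides the fraction.
#'
#' @param x a [FeatureTable-class].
#' @param minFraction minimum fraction of samples a taxon must appear in
#'   (default 0.10).
#' @param minCount absolute minimum number of samples (overrides
#'   `minFraction`).
#' @return filtered `FeatureTable`.
#' @export
prevalenceFilter <- function(x, minFraction = 0.10, minCount = NULL) {
  stopifnot(is(x, "FeatureTable"))
  thr <- minCount %||% ceiling(minFraction * nSamples(x))
  present <- rowSums(counts(x) > 0)
  subsetFeatureTable(x, taxa = which(present >= thr))
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

## Split lineage strings into a ranks matrix, stripping QIIME-style "x__"
## prefixes; unresolved ranks become NA.
parseLineages <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(TAX_RANKS)
    p
  }, character(length(TAX_RANKS))))
  colnames(m) <- TAX_RANKS
  m
}

#' Collapse a feature table to a taxonomic level
#'
#' Sums counts over taxa sharing the lineage down to `level`. Taxa whose
#' lineage is unresolved at that level are pooled under an explicit
#' `"undefined <deepest resolved ancestor>"` label (e.g. an unresolved genus
#' within Enterobacteriaceae becomes `"undefined Enterobacteriaceae"`).
#' Per-sample totals are conserved. The tree is dropped, as leaves no longer
#' correspond to table rows.
#'
#' @param x a [FeatureTable-class] with taxonomy.
#' @param level one of `"class"`, `"family"`, `"genus"`.
#' @return collapsed `FeatureTable` whose rownames are level labels.
#' @export
collapseTaxonomy <- function(x, level = c("class", "family", "genus")) {
  stopifnot(is(x, "FeatureTable"))
  level <- match.arg(level)
  if (!length(taxonomy(x)))
    validationError("collapseTaxonomy: table has no taxonomy")
  tax <- taxonomy(x)[rownames(counts(x))]
  if (anyNA(tax))
    validationError("collapseTaxonomy: missing lineage for taxon ",
                    rownames(counts(x))[which(is.na(tax))[1]])
  ranks <- parseLineages(tax)
  li <- match(level, TAX_RANKS)
  lab <- ranks[, li]
  for (i in which(is.na(lab))) {
    anc <- ranks[i, seq_len(li - 1)]
    anc <- anc[!is.na(anc)]
    lab[i] <- paste("undefined", if (length(anc)) anc[length(anc)] else "root")
  }
  agg <- rowsum(counts(x), lab)
  storage.mode(agg) <- "integer"
  lin <- vapply(split(seq_along(lab), lab), function(ix) {
    anc <- ranks[ix[1], seq_len(li)]
    anc[is.na(anc)] <- ""
    paste(anc, collapse = ";")
  }, character(1))
  featureTable(agg, lin[rownames(agg)], tree = NULL,
               sampleData = sampleData(x))
}

#' Alpha diversity: richness, Shannon index, Pielou evenness
#'
#' Richness S counts taxa with positive count; Shannon H = -sum p log p over
#' present taxa (log base 2 by default); evenness J = H / log S, undefined
#' (NA) for single-taxon samples.
#'
#' @param x a [FeatureTable-class].
#' @param base logarithm base for H (2 by default; use `exp(1)` for nats).
#' @return data.frame with `sample`, `richness`, `shannon`, `evenness`.
#' @examples
#' ft <- featureTable(matrix(c(4L, 4L, 4L, 4L), 4,
#'   dimnames = list(paste0("t", 1:4), "s1")))
#' alphaDiversity(ft)  # S = 4, H = 2 bits, J = 1
#' @export
alphaDiversity <- function(x, base = 2) {
  stopifnot(is(x, "FeatureTable"))
  m <- counts(x)
  if (any(colSums(m) == 0)) validationError("alphaDiversity: empty sample")
  res <- apply(m, 2, function(col) {
    p <- col[col > 0] / sum(col)
    S <- length(p)
    H <- -sum(p * log(p, base = base))
    c(S, H, if (S > 1) H / log(S, base = base) else NA_real_)
  })
  data.frame(sample = colnames(m), richness = as.integer(res[1, ]),
             shannon = res[2, ], evenness = res[3, ], row.names = NULL)
}

#' Weighted UniFrac distances
#'
#' For each pair of samples, the raw weighted UniFrac distance is
#' `sum_b len(b) * |P_A(b) - P_B(b)|` over the branches `b` of the rooted
#' tree, where `P_X(b)` is the fraction of sample X's reads descending
#' through branch `b`; samples are normalized to relative abundance
#' internally. With `normalized = TRUE` the distance is divided by
#' `sum_b len(b) * (P_A(b) + P_B(b))`, bounding it by 1.
#'
#' @param x a [FeatureTable-class] carrying a rooted tree over its taxa.
#' @param normalized logical; return the normalized variant (default FALSE,
#'   the raw metric).
#' @return symmetric distance matrix (samples x samples, zero diagonal).
#' @export
weightedUnifrac <- function(x, normalized = FALSE) {
  stopifnot(is(x, "FeatureTable"))
  tree <- phyloTree(x)
  if (is.null(tree)) validationError("weightedUnifrac: table has no tree")
  absent <- setdiff(rownames(counts(x)), tree$tip.label)
  if (length(absent))
    validationError("weightedUnifrac: taxa absent from tree: ",
                    paste(utils::head(absent, 5), collapse = ", "))
  P <- relativeAbundance(x)
  tree <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  ## node x sample matrix of subtree mass
  M <- matrix(0, nNode, ncol(P))
  idx <- match(tree$tip.label, rownames(P))
  hasRow <- !is.na(idx)
  M[which(hasRow), ] <- P[idx[hasRow], , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    M[parent, ] <- M[parent, ] + M[child, ]
  }
  edgeMass <- M[tree$edge[, 2], , drop = FALSE]
  len <- tree$edge.length
  n <- ncol(P)
  D <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum(len * abs(edgeMass[, i] - edgeMass[, j]))
    if (normalized) {
      denom <- sum(len * (edgeMass[, i] + edgeMass[, j]))
      d <- if (denom > 0) d / denom else 0
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix, eigen-decomposes it, and
#' returns coordinates on the leading `k` positive axes. Negative
#' eigenvalues are reported unchanged rather than clipped; axes are ordered
#' by decreasing eigenvalue.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes to return (default 3).
#' @return list with `points` (n x k), `eig` (all n eigenvalues) and
#'   `rel_eig` (eigenvalues over the sum of positive eigenvalues).
#' @export
pcoa <- function(d, k = 3) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n - 1) validationError("pcoa: k must be <= n - 1")
  if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
    validationError("pcoa: not a valid distance matrix")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- pmax(e$values[seq_len(k)], 0)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = e$values,
       rel_eig = e$values / sum(pmax(e$values, 0)))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance: the pseudo-F
#' compares among-group to within-group sums of squared distances; the
#' p-value is `(1 + #{F_perm >= F_obs}) / (1 + nPerm)` over uniformly random
#' label permutations. For a two-group design with few distinct label
#' assignments (`choose(N, n1) <= nPerm`) the complete enumeration is used
#' instead and the p-value is exact.
#'
#' All samples identical (zero total sum of squares) is reported as p = 1
#' with a warning.
#'
#' @param d symmetric distance matrix.
#' @param labels group labels, one per sample; every group must have >= 2
#'   samples.
#' @param nPerm number of random permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @return list with `F`, `p`, `nPerm`, `method` ("permutation" or
#'   "enumeration"), `df`.
#' @export
permanova <- function(d, labels, nPerm = 999, seed = NULL) {
  d <- as.matrix(d)
  labels <- factor(labels)
  n <- nrow(d)
  if (length(labels) != n) validationError("permanova: labels length != n")
  sizes <- table(labels)
  if (nlevels(labels) < 2 || any(sizes < 2))
    validationError("permanova: need >= 2 groups with >= 2 samples each")
  d2 <- d^2
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  a <- nlevels(labels)
  Fstat <- function(lab) {
    ssW <- 0
    for (lv in levels(labels)) {
      ix <- which(lab == lv)
      ssW <- ssW + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
    }
    ((ssTotal - ssW) / (a - 1)) / (ssW / (n - a))
  }
  Fobs <- Fstat(labels)
  if (!is.finite(ssTotal) || ssTotal <= 1e-12) {
    warning("permanova: no variation among samples; p = 1")
    return(list(F = NaN, p = 1, nPerm = 0, method = "degenerate",
                df = c(a - 1, n - a)))
  }
  geq <- function(fp) fp >= Fobs - 1e-12 | (is.nan(fp) & is.nan(Fobs))
  if (a == 2 && choose(n, sizes[1]) <= nPerm) {
    combs <- utils::combn(n, sizes[1])
    Fall <- apply(combs, 2, function(ix) {
      lab <- factor(rep(levels(labels)[2], n), levels = levels(labels))
      lab[ix] <- levels(labels)[1]
      Fstat(lab)
    })
    p <- mean(geq(Fall))
    return(list(F = Fobs, p = p, nPerm = ncol(combs),
                method = "enumeration", df = c(a - 1, n - a)))
  }
  Fperm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    Fstat(sample(labels)), numeric(1)))
  p <- (1 + sum(geq(Fperm))) / (1 + nPerm)
  list(F = Fobs, p = p, nPerm = nPerm, method = "permutation",
       df = c(a - 1, n - a))
}

#' Per-taxon abundance contrasts by Kruskal-Wallis
#'
#' Runs a tie-corrected Kruskal-Wallis test on each taxon's relative
#' abundance across groups. P-values are reported unadjusted. Taxa constant
#' across all samples get H = 0, p = 1.
#'
#' @param x a (typically collapsed and prevalence-filtered)
#'   [FeatureTable-class].
#' @param labels group labels, one per sample.
#' @return data.frame with `taxon`, `H`, `p`, ordered as the table rows.
#' @export
abundanceContrasts <- function(x, labels) {
  stopifnot(is(x, "FeatureTable"))
  P <- relativeAbundance(x)
  if (length(labels) != ncol(P))
    validationError("abundanceContrasts: labels length != samples")
  res <- t(apply(P, 1, function(row) {
    kt <- kruskalWallisTest(row, labels)
    c(kt$H, kt$p)
  }))
  data.frame(taxon = rownames(P), H = res[, 1], p = res[, 2],
             row.names = NULL)
}
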