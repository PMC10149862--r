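test_that("rarefaction conserves depth exactly and is seed-reproducible", {
  set.seed(21)
  for (i in 1:20) {
    ft <- randomFeatureTable(nTaxa = 10, nSamples = 4, lambda = 30)
    depth <- min(colSums(counts(ft))) - sample(0:5, 1)
    r <- rarefy(ft, depth, seed = i)
    expect_true(all(colSums(counts(r)) == depth))
    expect_true(all(counts(r) <= counts(ft)[, colnames(counts(r))]))
  }
  ft <- randomFeatureTable(nTaxa = 8, nSamples = 3, lambda = 40)
  expect_identical(counts(rarefy(ft, 50, seed = 3)),
                   counts(rarefy(ft, 50, seed = 3)))
  ## sample total equal to depth passes through unchanged
  m <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_identical(counts(rarefy(featureTable(m), 10, seed = 1)), m)
  ## shallow samples are dropped with a warning
  m2 <- cbind(m, s2 = c(2L, 1L))
  expect_warning(r <- rarefy(featureTable(m2), 10, seed = 1), "dropping")
  expect_identical(colnames(counts(r)), "s")
  expect_error(rarefy(featureTable(m), 0), "depth")
})

test_that("prevalence filter applies the ceil(10% of samples) boundary", {
  m <- matrix(0L, 3, 26,
              dimnames = list(c("in2", "in3", "zero"), sprintf("s%d", 1:26)))
  m["in2", 1:2] <- 5L
  m["in3", 1:3] <- 5L
  keepAlive <- matrix(1L, 1, 26, dimnames = list("common", colnames(m)))
  ft <- featureTable(rbind(m, keepAlive))
  f <- prevalenceFilter(ft)  # threshold ceil(2.6) = 3
  expect_false("in2" %in% rownames(counts(f)))
  expect_true("in3" %in% rownames(counts(f)))
  expect_false("zero" %in% rownames(counts(f)))
  ## explicit count override
  f2 <- prevalenceFilter(ft, minCount = 2)
  expect_true("in2" %in% rownames(counts(f2)))
})

test_that("taxonomy collapse sums lineage groups and pools unresolved ranks", {
  m <- matrix(c(3L, 4L, 5L, 2L,
                1L, 2L, 3L, 4L), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  lin <- c(
    a = "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia",
    b = "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Klebsiella",
    c = "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;",
    d = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus")
  ft <- featureTable(m, lin)
  fam <- collapseTaxonomy(ft, "family")
  expect_identical(sort(rownames(counts(fam))),
                   sort(c("Enterobacteriaceae", "Lactobacillaceae")))
  expect_equal(counts(fam)["Enterobacteriaceae", ], c(s1 = 12L, s2 = 6L))
  expect_equal(colSums(counts(fam)), colSums(m))  # conservation
  gen <- collapseTaxonomy(ft, "genus")
  expect_true("undefined Enterobacteriaceae" %in% rownames(counts(gen)))
  expect_equal(colSums(counts(gen)), colSums(m))
  ## conservation at every level on random tables with this taxonomy
  cls <- collapseTaxonomy(ft, "class")
  expect_equal(colSums(counts(cls)), colSums(m))
  ## QIIME-style prefixes are stripped
  lin2 <- setNames(paste0("d__B;p__P;c__C;o__O;f__F;g__G"), "a")
  ft2 <- featureTable(m[1, , drop = FALSE], lin2)
  expect_identical(rownames(counts(collapseTaxonomy(ft2, "family"))), "F")
})

test_that("alpha diversity matches closed forms and the uniform maximum", {
  ft <- featureTable(matrix(4L, 4, 1, dimnames = list(paste0("t", 1:4), "s")))
  a <- alphaDiversity(ft)
  expect_identical(a$richness, 4L)
  expect_equal(a$shannon, 2)      # 4 equal taxa: 2 bits
  expect_equal(a$evenness, 1)
  ## hand computation for [8,4,2,2]/16
  ft <- featureTable(matrix(c(8L, 4L, 2L, 2L), 4,
                            dimnames = list(paste0("t", 1:4), "s")))
  expect_equal(alphaDiversity(ft)$shannon, 1.75)
  ## single taxon: H = 0, evenness undefined
  ft1 <- featureTable(matrix(9L, 1, 1, dimnames = list("t", "s")))
  a1 <- alphaDiversity(ft1)
  expect_equal(a1$shannon, 0)
  expect_true(is.na(a1$evenness))
  ## natural-log variant
  expect_equal(alphaDiversity(featureTable(matrix(c(8L, 4L, 2L, 2L), 4,
    dimnames = list(paste0("t", 1:4), "s"))), base = exp(1))$shannon,
    1.75 * log(2))
  ## Shannon is maximal iff uniform over present taxa
  set.seed(31)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    cnt <- sample(1:50, n, replace = TRUE)
    uni <- rep(max(cnt), n)
    hs <- function(v) alphaDiversity(featureTable(matrix(as.integer(v),
      dimnames = list(paste0("t", seq_along(v)), "s"))))$shannon
    expect_lte(hs(cnt), hs(uni) + 1e-12)
    if (length(unique(cnt)) > 1) expect_lt(hs(cnt), hs(uni))
  }
})

test_that("weighted UniFrac matches closed forms and the star-tree oracle", {
  ## two-leaf tree with unit branches, opposite concentration: raw d = 2
  tr <- ape::read.tree(text = "(a:1,b:1);")
  m <- matrix(c(10L, 0L, 0L, 10L), 2, dimnames = list(c("a", "b"),
                                                      c("s1", "s2")))
  ft <- featureTable(m, tree = tr)
  D <- weightedUnifrac(ft)
  expect_equal(D["s1", "s2"], 2)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))
  ## normalized variant is bounded by 1
  expect_equal(weightedUnifrac(ft, normalized = TRUE)["s1", "s2"], 1)
  ## identical samples at distance zero
  m2 <- matrix(c(3L, 7L, 3L, 7L), 2, dimnames = list(c("a", "b"),
                                                     c("s1", "s2")))
  expect_equal(weightedUnifrac(featureTable(m2, tree = tr))["s1", "s2"], 0)
  ## star-tree closed form on random instances; symmetry
  set.seed(32)
  for (i in 1:25) {
    nt <- sample(4:12, 1); ns <- sample(3:6, 1)
    taxa <- sprintf("t%02d", seq_len(nt))
    lens <- round(runif(nt, 0.1, 2), 3)
    cntm <- matrix(rpois(nt * ns, 15) + 1L, nt,
                   dimnames = list(taxa, sprintf("s%d", seq_len(ns))))
    ft <- featureTable(cntm, tree = starTree(taxa, lens))
    D <- weightedUnifrac(ft)
    P <- sweep(cntm, 2, colSums(cntm), "/")
    expect_equal(D, starUnifracOracle(P, lens), tolerance = 1e-10)
    expect_equal(D, t(D))
  }
  ## missing taxon is named in the error
  bad <- featureTable(rbind(m2, z = c(1L, 1L)))
  bad@tree <- tr
  expect_error(weightedUnifrac(bad), "z")
})

test_that("weighted UniFrac agrees with phyloseq on a random tree", {
  skip_if_not_installed("phyloseq")
  set.seed(33)
  nt <- 15; ns <- 6
  taxa <- sprintf("t%02d", 1:nt)
  tr <- ape::rtree(nt, tip.label = taxa)
  cntm <- matrix(rpois(nt * ns, 20) + 1L, nt,
                 dimnames = list(taxa, sprintf("s%d", 1:ns)))
  D <- weightedUnifrac(featureTable(cntm, tree = tr))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(cntm, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  Dref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                      normalized = FALSE))
  expect_equal(D, Dref[rownames(D), colnames(D)], tolerance = 1e-8)
})

test_that("PCoA reproduces closed forms and round-trips Euclidean input", {
  ## two points at distance d embed at +/- d/2
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- pcoa(d, k = 1)
  expect_equal(sort(as.numeric(r$points)), c(-1.5, 1.5))
  ## Euclidean distances are reproduced by the embedding
  set.seed(34)
  X <- matrix(rnorm(8 * 3), 8)
  D <- as.matrix(dist(X))
  r <- pcoa(D, k = 3)
  expect_equal(as.matrix(dist(r$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## eigenvalue sum equals the trace of the centered Gower matrix
  J <- diag(8) - 1 / 8
  B <- -0.5 * J %*% D^2 %*% J
  expect_equal(sum(r$eig), sum(diag(B)), tolerance = 1e-8)
  ## agreement with the classical-scaling reference
  ref <- cmdscale(D, k = 3, eig = TRUE)
  expect_equal(abs(r$points), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcoa(D, k = 8), "k must be")
})

test_that("PERMANOVA is exact on tiny designs and matches vegan", {
  ## 3+3 perfectly separated clusters: complete enumeration, p = 2/20
  X <- rbind(matrix(rnorm(9, 0, 0.01), 3), matrix(rnorm(9, 10, 0.01), 3))
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  r <- permanova(D, rep(c("a", "b"), each = 3))
  expect_identical(r$method, "enumeration")
  expect_equal(r$p, 0.1)
  ## pseudo-F agrees with vegan::adonis2 on a random problem
  skip_if_not_installed("vegan")
  set.seed(35)
  Y <- matrix(rnorm(12 * 4), 12)
  D2 <- as.matrix(dist(Y))
  dimnames(D2) <- list(paste0("s", 1:12), paste0("s", 1:12))
  lab <- rep(c("a", "b", "c"), each = 4)
  r2 <- permanova(D2, lab, nPerm = 199, seed = 1)
  ref <- vegan::adonis2(as.dist(D2) ~ g, data = data.frame(g = lab),
                        permutations = 199)
  expect_equal(r2$F, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values respect range, invariance and degeneracy", {
  set.seed(36)
  X <- matrix(rnorm(10 * 3), 10)
  D <- as.matrix(dist(X)); dimnames(D) <- list(paste0("s", 1:10),
                                               paste0("s", 1:10))
  lab <- rep(c("a", "b"), 5)
  r <- permanova(D, lab, nPerm = 99, seed = 4)
  expect_true(r$p >= 1 / 100 && r$p <= 1)
  ## joint permutation of matrix and labels leaves F and p unchanged
  perm <- sample(10)
  r2 <- permanova(D[perm, perm], lab[perm], nPerm = 99, seed = 4)
  expect_equal(r2$F, r$F, tolerance = 1e-12)
  ## identical samples: degenerate, p = 1 with warning
  D0 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_warning(r0 <- permanova(D0, rep(c("a", "b"), 2)), "no variation")
  expect_equal(r0$p, 1)
  expect_error(permanova(D[1:3, 1:3], c("a", "a", "b")), "2 samples")
})

test_that("abundance contrasts test every taxon and flag hard separation", {
  set.seed(37)
  m <- matrix(rpois(8 * 10, 30), 8,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  m[1, 1:5] <- 0L; m[1, 6:10] <- 60L  # present only in group B
  lab <- rep(c("A", "B"), each = 5)
  res <- abundanceContrasts(featureTable(m), lab)
  expect_identical(nrow(res), 8L)  # one row per filtered taxon
  expect_lt(res$p[res$taxon == "t1"], 0.02)
  ## constant taxon gets p = 1
  m2 <- m; m2[2, ] <- 0L
  res2 <- abundanceContrasts(featureTable(m2), lab)
  expect_equal(res2$p[res2$taxon == "t2"], 1)
})
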