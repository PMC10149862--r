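#' Construct a validated FeatureTable
#'
#' @param counts taxa-by-samples matrix of non-negative integer counts with
#'   dimnames.
#' @param taxonomy optional named character vector of semicolon-delimited
#'   lineage strings, one per taxon.
#' @param tree optional rooted [ape::phylo] whose tips include every taxon.
#' @param sampleData optional data.frame of per-sample metadata, rownames =
#'   sample ids.
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, dimnames = list(c("t1", "t2"), c("a", "b")))
#' featureTable(m)
#' @export
featureTable <- function(counts, taxonomy = character(), tree = NULL,
                         sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = colnames(counts))
  else {
    sampleData <- as.data.frame(sampleData)
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
    rownames(sampleData) <- colnames(counts)
  }
  if (length(taxonomy) && is.null(names(taxonomy)) &&
      length(taxonomy) == nrow(counts))
    names(taxonomy) <- rownames(counts)
  tryCatch(
    new("FeatureTable", counts = counts, taxonomy = taxonomy,
        tree = tree, sampleData = sampleData),
    error = function(e) validationError(conditionMessage(e)))
}

#' @rdname featureTable
#' @param x,object a `FeatureTable`.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname featureTable
#' @export
setMethod("counts", "FeatureTable", function(x) x@counts)

#' @rdname featureTable
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname featureTable
#' @export
setMethod("taxonomy", "FeatureTable", function(x) x@taxonomy)

#' @rdname featureTable
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))
#' @rdname featureTable
#' @export
setMethod("phyloTree", "FeatureTable", function(x) x@tree)

#' @rdname featureTable
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname featureTable
#' @export
setMethod("sampleData", "FeatureTable", function(x) x@sampleData)

#' @rdname featureTable
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))
#' @rdname featureTable
#' @export
setMethod("nTaxa", "FeatureTable", function(x) nrow(x@counts))

#' @rdname featureTable
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname featureTable
#' @export
setMethod("nSamples", "FeatureTable", function(x) ncol(x@counts))

## Subset a FeatureTable by taxa and/or samples, keeping taxonomy, tree and
## metadata consistent. Tree is pruned to the retained taxa.
subsetFeatureTable <- function(x, taxa = NULL, samples = NULL) {
  counts <- x@counts
  if (!is.null(taxa)) counts <- counts[taxa, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tax <- if (length(x@taxonomy)) x@taxonomy[rownames(counts)] else character()
  tree <- x@tree
  if (!is.null(tree) && !is.null(taxa)) {
    drop <- setdiff(tree$tip.label, rownames(counts))
    if (length(drop))
      tree <- ape::drop.tip(tree, drop)
  }
  sd <- x@sampleData[colnames(counts), , drop = FALSE]
  rownames(sd) <- colnames(counts)
  featureTable(counts, tax, tree, sd)
}

#' Relative abundances of a FeatureTable
#'
#' @param x a `FeatureTable`.
#' @return matrix of per-sample proportions (columns sum to 1).
#' @export
relativeAbundance <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  tot <- colSums(x@counts)
  if (any(tot == 0)) validationError("relativeAbundance: empty sample(s)")
  sweep(x@counts, 2, tot, "/")
}

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@counts), "taxa x", ncol(object@counts),
      "samples\n")
  cat("  taxonomy:", if (length(object@taxonomy)) "present" else "absent",
      "| tree:", if (is.null(object@tree)) "absent" else
        paste0(length(object@tree$tip.label), " tips"), "\n")
  if (ncol(object@sampleData))
    cat("  sampleData columns:",
        paste(names(object@sampleData), collapse = ", "), "\n")
})
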