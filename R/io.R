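## Plain-text I/O: tidy cohort CSVs, feature-table TSV / BIOM-JSON,
## taxonomy TSV, Newick trees, metadata TSV, and provenance manifests.

#' Read / write a piglet cohort as tidy CSV files
#'
#' A cohort directory holds one CSV per entity: `piglets.csv`, `css.csv`,
#' `segments.csv`, `cultures.csv` and optionally `vitals.csv`, with the
#' column schemas documented in [PigletCohort-class] (times in decimal hours
#' since birth, body weights kg, tissue masses g, plated volume ul,
#' homogenate volume ml). Reading validates and reports schema violations
#' with the offending file named.
#'
#' @param dir directory containing (or to receive) the CSV files.
#' @return `readCohort` returns a [PigletCohort-class]; `writeCohort`
#'   invisibly returns the directory.
#' @export
readCohort <- function(dir) {
  rd <- function(name, required = TRUE) {
    f <- file.path(dir, name)
    if (!file.exists(f)) {
      if (required) validationError("readCohort: missing file ", f)
      return(NULL)
    }
    df <- tryCatch(utils::read.csv(f, stringsAsFactors = FALSE),
                   error = function(e)
                     validationError("readCohort: cannot parse ", f, ": ",
                                     conditionMessage(e)))
    if (!nrow(df) && name == "piglets.csv")
      validationError("readCohort: ", f, " is empty")
    df
  }
  tryCatch(
    PigletCohort(rd("piglets.csv"), rd("css.csv"), rd("segments.csv"),
                 rd("cultures.csv"), rd("vitals.csv", required = FALSE)),
    dnecValidationError = function(e)
      validationError("readCohort(", dir, "): ", conditionMessage(e)))
}

#' @rdname readCohort
#' @param cohort a [PigletCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PigletCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(piglets(cohort), "piglets.csv")
  wr(cssObservations(cohort), "css.csv")
  wr(segmentScores(cohort), "segments.csv")
  wr(organCultures(cohort), "cultures.csv")
  if (nrow(vitalSigns(cohort))) wr(vitalSigns(cohort), "vitals.csv")
  invisible(dir)
}

#' Read / write a feature table
#'
#' The TSV layout is taxa in rows and samples in columns with the first
#' column holding taxon ids. Taxonomy is a two-column TSV (taxon id,
#' semicolon-delimited lineage); the tree is Newick (read via
#' [ape::read.tree]); metadata is a TSV keyed by sample id. `format =
#' "biom"` reads/writes BIOM-style JSON (requires the biomformat package).
#'
#' @param countsFile counts TSV (or BIOM JSON) path.
#' @param taxonomyFile,treeFile,metadataFile optional companion files.
#' @param format `"tsv"` or `"biom"`.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(countsFile, taxonomyFile = NULL,
                             treeFile = NULL, metadataFile = NULL,
                             format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(countsFile, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "integer"
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("format = 'biom' requires the biomformat package")
    b <- biomformat::read_biom(countsFile)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "integer"
  }
  tax <- character()
  if (!is.null(taxonomyFile)) {
    td <- utils::read.delim(taxonomyFile, stringsAsFactors = FALSE)
    tax <- setNames(td[[2]], td[[1]])
  }
  tree <- if (!is.null(treeFile)) ape::read.tree(treeFile) else NULL
  sd <- NULL
  if (!is.null(metadataFile)) {
    sd <- utils::read.delim(metadataFile, stringsAsFactors = FALSE)
    rownames(sd) <- sd[[1]]
    sd <- sd[, -1, drop = FALSE]
  }
  featureTable(m, tax, tree, sd)
}

#' @rdname readFeatureTable
#' @param x a [FeatureTable-class].
#' @param dir output directory; writes `feature_table.tsv`, `taxonomy.tsv`,
#'   `tree.nwk`, `metadata.tsv` as applicable.
#' @export
writeFeatureTable <- function(x, dir) {
  stopifnot(is(x, "FeatureTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(taxon = rownames(counts(x)), counts(x),
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "feature_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (length(taxonomy(x)))
    utils::write.table(
      data.frame(taxon = names(taxonomy(x)), lineage = unname(taxonomy(x))),
      file.path(dir, "taxonomy.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  if (!is.null(phyloTree(x)))
    ape::write.tree(phyloTree(x), file.path(dir, "tree.nwk"))
  if (ncol(sampleData(x)))
    utils::write.table(
      data.frame(sample = rownames(sampleData(x)), sampleData(x)),
      file.path(dir, "metadata.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  invisible(dir)
}

## Provenance manifest: config hash + seeds + package version alongside every
## command's outputs.
writeManifest <- function(dir, config, seed) {
  manifest <- list(
    package = "dnec",
    version = as.character(utils::packageVersion("dnec")),
    config_hash = configHash(config),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
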