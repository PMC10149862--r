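## Pipeline commands tying the stages together. Each takes a config list (or
## YAML file path), runs one stage end-to-end, and writes tables, a JSON
## summary and a provenance manifest. A thin command-line wrapper lives at
## inst/scripts/dnec.

readConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) validationError("config must be a list or YAML path")
  config
}

## Default analysis parameters: the D-NEC thresholds plus the microbiome
## pipeline settings (rarefaction depth 18755, 10% prevalence, 999
## permutations, exact Mann-Whitney bound 40).
defaultConfig <- function() {
  list(thresholds = dnecThresholds(),
       rarefactionDepth = 18755,
       prevalenceFraction = 0.10,
       permutations = 999,
       exactLimit = 40)
}

mergeConfig <- function(config) {
  base <- defaultConfig()
  merged <- utils::modifyList(base, config)
  overridden <- names(config)[names(config) %in% names(base)]
  for (nm in overridden)
    if (!identical(base[[nm]], merged[[nm]]))
      message("config override: ", nm)
  merged
}

#' Score a cohort directory and summarize it
#'
#' Reads the cohort CSVs from `config$input`, classifies every piglet with
#' [dnecClassify()], and writes `criteria_panel.csv`, `summary.json` and a
#' provenance manifest under `out`.
#'
#' @param config list or YAML file with at least `input` (cohort directory);
#'   optional `thresholds` overrides.
#' @param out output directory.
#' @param seed integer recorded in the manifest (scoring is deterministic).
#' @return the [cohortSummary()] object, invisibly.
#' @export
cmdScore <- function(config, out, seed = 0) {
  config <- mergeConfig(readConfig(config))
  if (is.null(config$input)) validationError("cmdScore: config$input missing")
  cohort <- readCohort(config$input)
  message("scored input: ", nrow(piglets(cohort)), " piglets")
  panel <- dnecClassify(cohort, config$thresholds)
  summ <- cohortSummary(cohort, panel)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(panel, file.path(out, "criteria_panel.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(groups = summ$groups, tests = summ$tests),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows")
  writeManifest(out, config, seed)
  invisible(summ)
}

#' Run the microbiome stage end-to-end
#'
#' Prevalence-filters, rarefies, and computes alpha diversity, weighted
#' UniFrac, PCoA, PERMANOVA and per-taxon Kruskal-Wallis contrasts at the
#' class, family and genus levels; writes tables plus a JSON report with all
#' seeds and parameters recorded. The grouping column is
#' `config$groupColumn` (default `"group"`) of the metadata.
#'
#' @param config list or YAML file with `counts`, `taxonomy`, `tree`,
#'   `metadata` file paths; optional `rarefactionDepth`,
#'   `prevalenceFraction`, `permutations`, `groupColumn`.
#' @param out output directory.
#' @param seed integer seed driving rarefaction and permutations.
#' @return list with the report components, invisibly.
#' @export
cmdMicrobiome <- function(config, out, seed = 1) {
  config <- mergeConfig(readConfig(config))
  for (f in c("counts", "taxonomy", "tree", "metadata"))
    if (is.null(config[[f]]))
      validationError("cmdMicrobiome: config$", f, " missing")
  ft <- readFeatureTable(config$counts, config$taxonomy, config$tree,
                         config$metadata)
  groupCol <- config$groupColumn %||% "group"
  if (!groupCol %in% names(sampleData(ft)))
    validationError("cmdMicrobiome: metadata lacks column ", groupCol)
  message("input: ", nTaxa(ft), " taxa x ", nSamples(ft), " samples")
  ft <- prevalenceFilter(ft, config$prevalenceFraction)
  message("after prevalence filter: ", nTaxa(ft), " taxa")
  ft <- rarefy(ft, config$rarefactionDepth, seed = seed)
  message("after rarefaction at ", config$rarefactionDepth, ": ",
          nSamples(ft), " samples")
  labels <- sampleData(ft)[[groupCol]]
  alpha <- alphaDiversity(ft)
  alphaTests <- lapply(c(richness = "richness", shannon = "shannon",
                         evenness = "evenness"), function(m)
    kruskalWallisTest(alpha[[m]], labels))
  D <- weightedUnifrac(ft)
  ord <- pcoa(D, k = min(3, nSamples(ft) - 1))
  perm <- permanova(D, labels, nPerm = config$permutations, seed = seed + 1)
  contrasts <- lapply(c(class = "class", family = "family", genus = "genus"),
                      function(lv)
    abundanceContrasts(collapseTaxonomy(ft, lv), labels))

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(alpha, file.path(out, "alpha_diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(D), D, check.names = FALSE),
                   file.path(out, "weighted_unifrac.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(ord$points), ord$points),
                   file.path(out, "pcoa.csv"), row.names = FALSE)
  for (lv in names(contrasts))
    utils::write.csv(contrasts[[lv]],
                     file.path(out, paste0("contrasts_", lv, ".csv")),
                     row.names = FALSE)
  report <- list(parameters = config[c("rarefactionDepth",
                                       "prevalenceFraction",
                                       "permutations")],
                 seed = seed,
                 alpha_tests = alphaTests,
                 permanova = perm[c("F", "p", "nPerm", "method")],
                 pcoa_eigenvalues = ord$eig)
  jsonlite::write_json(report, file.path(out, "microbiome_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeManifest(out, config, seed)
  invisible(list(alpha = alpha, alphaTests = alphaTests, distance = D,
                 pcoa = ord, permanova = perm, contrasts = contrasts))
}

#' Simulate a cohort plus microbiome dataset to disk
#'
#' Writes all input files the other commands consume: the cohort CSVs under
#' `out/cohort/` and the microbiome TSV/Newick files under
#' `out/microbiome/`, with a manifest recording the seed. Microbiome NEC
#' labels are taken from the simulated cohort's D-NEC calls so the two
#' stages are consistent.
#'
#' @param config list or YAML file; optional `cohort` and `microbiome`
#'   sublists override [cohortScenario()] / [microbiomeScenario()]
#'   arguments.
#' @param out output directory.
#' @param seed integer master seed.
#' @return paths of the written directories, invisibly.
#' @export
cmdSimulate <- function(config = list(), out, seed = 1) {
  config <- readConfig(config)
  scen <- do.call(cohortScenario, config$cohort %||% list())
  cohort <- simulateCohort(scen, seed = seed)
  mscen <- do.call(microbiomeScenario, config$microbiome %||% list())
  panel <- dnecClassify(cohort)
  labels <- ifelse(panel$dnec, "NEC", "noNEC")
  ft <- simulateMicrobiome(mscen, labels, seed = seed + 1)
  ## carry piglet ids and feeding group into the sample metadata
  sd <- data.frame(group = labels, piglet = panel$id,
                   feeding = panel$group,
                   row.names = colnames(counts(ft)))
  ft <- featureTable(counts(ft), taxonomy(ft), phyloTree(ft), sd)
  cohortDir <- file.path(out, "cohort")
  microDir <- file.path(out, "microbiome")
  writeCohort(cohort, cohortDir)
  writeFeatureTable(ft, microDir)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  writeManifest(out, config, seed)
  message("simulated ", nrow(piglets(cohort)), " piglets, ",
          nTaxa(ft), " taxa x ", nSamples(ft), " samples")
  invisible(list(cohort = cohortDir, microbiome = microDir))
}
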