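#' @import methods
NULL

SEGMENT_LEVELS <- c("proximal_si", "mid_si", "distal_si", "colon")
ORGAN_LEVELS <- c("liver", "spleen", "mln")
GROUP_LEVELS <- c("colostrum", "formula")
OUTCOME_LEVELS <- c("survived", "euthanized", "died")

#' PigletCohort: one preterm piglet cohort in tidy form
#'
#' Container for a cohort of preterm piglets in a necrotizing-enterocolitis
#' feeding experiment. Holds five tidy tables keyed by piglet id: one row per
#' piglet (`piglets`), longitudinal clinical-sickness-score observations
#' (`css`), per-segment gross/histologic injury scores (`segments`),
#' per-organ culture results (`cultures`) and optional per-feed vitals
#' (`vitals`). Times are decimal hours since birth; body weights are in kg,
#' tissue masses in g, plated volume in microlitres and homogenate volume in
#' ml.
#'
#' The validity method enforces the scoring-rubric invariants: CSS subscores
#' in 0..2 observed from 12 h of life onward at strictly increasing times not
#' exceeding the piglet's end time, gross scores in 1..6 and histologic in
#' 1..5 with at most one row per segment, non-negative colony counts with
#' positive tissue mass, and a plated volume no larger than the homogenate
#' volume.
#'
#' @slot piglets data.frame with columns `id`, `group`
#'   ("colostrum"/"formula"), `sex`, `birth_weight_kg`, `final_weight_kg`,
#'   `outcome` ("survived"/"euthanized"/"died"), `end_time_h`.
#' @slot css data.frame with columns `id`, `time_h`, `motor`, `verbal`,
#'   `alertness`, `color`.
#' @slot segments data.frame with columns `id`, `segment`
#'   ("proximal_si"/"mid_si"/"distal_si"/"colon"), `gross`, `histologic`
#'   (either may be NA).
#' @slot cultures data.frame with columns `id`, `organ`
#'   ("liver"/"spleen"/"mln"), `colonies`, `plated_volume_ul`,
#'   `homogenate_volume_ml`, `tissue_mass_g`.
#' @slot vitals data.frame (possibly empty) with columns `id`, `time_h`,
#'   `weight_kg`, `temperature_c` and logical symptom flags
#'   `extreme_lethargy`, `lethargy`, `bloody_diarrhea`,
#'   `abdominal_distension`, `emesis`, `abnormal_breathing`.
#'
#' @seealso [PigletCohort()] for the validating constructor, [dnecClassify()],
#'   [cohortSummary()], [simulateCohort()], [fixtureCohort()].
#' @export
setClass("PigletCohort",
  slots = c(
    piglets = "data.frame",
    css = "data.frame",
    segments = "data.frame",
    cultures = "data.frame",
    vitals = "data.frame"
  )
)

VITAL_FLAGS <- c("extreme_lethargy", "lethargy", "bloody_diarrhea",
                 "abdominal_distension", "emesis", "abnormal_breathing")

validPigletCohort <- function(object) {
  p <- object@piglets
  msg <- character()
  need <- c("id", "group", "sex", "birth_weight_kg", "final_weight_kg",
            "outcome", "end_time_h")
  if (!all(need %in% names(p)))
    return(paste("piglets: missing column(s)",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (anyDuplicated(p$id)) msg <- c(msg, "piglets: duplicated ids")
  if (!all(p$group %in% GROUP_LEVELS))
    msg <- c(msg, "piglets: group must be 'colostrum' or 'formula'")
  if (!all(p$outcome %in% OUTCOME_LEVELS))
    msg <- c(msg, "piglets: unknown outcome value")
  if (any(p$end_time_h <= 0)) msg <- c(msg, "piglets: end_time_h must be > 0")
  if (any(p$birth_weight_kg <= 0))
    msg <- c(msg, "piglets: birth_weight_kg must be > 0")

  s <- object@css
  if (nrow(s)) {
    if (!all(s$id %in% p$id)) msg <- c(msg, "css: unknown piglet id")
    sub <- as.matrix(s[, c("motor", "verbal", "alertness", "color")])
    if (!all(sub %in% 0:2)) msg <- c(msg, "css: subscores must be in {0,1,2}")
    if (any(s$time_h < 12)) msg <- c(msg, "css: scoring begins at 12 h of life")
    for (id in unique(s$id)) {
      t <- s$time_h[s$id == id]
      if (is.unsorted(t, strictly = TRUE))
        msg <- c(msg, paste0("css: times not strictly increasing for ", id))
      if (any(t > p$end_time_h[p$id == id] + 1e-9))
        msg <- c(msg, paste0("css: observation after end_time for ", id))
    }
  }

  g <- object@segments
  if (nrow(g)) {
    if (!all(g$id %in% p$id)) msg <- c(msg, "segments: unknown piglet id")
    if (!all(g$segment %in% SEGMENT_LEVELS))
      msg <- c(msg, "segments: unknown segment label")
    if (anyDuplicated(g[, c("id", "segment")]))
      msg <- c(msg, "segments: more than one row per segment per piglet")
    if (!all(is.na(g$gross) | g$gross %in% 1:6))
      msg <- c(msg, "segments: gross score must be in 1..6")
    if (!all(is.na(g$histologic) | g$histologic %in% 1:5))
      msg <- c(msg, "segments: histologic score must be in 1..5")
  }

  cu <- object@cultures
  if (nrow(cu)) {
    if (!all(cu$id %in% p$id)) msg <- c(msg, "cultures: unknown piglet id")
    if (!all(cu$organ %in% ORGAN_LEVELS))
      msg <- c(msg, "cultures: organ must be liver/spleen/mln")
    if (any(cu$colonies < 0)) msg <- c(msg, "cultures: negative colony count")
    if (any(cu$tissue_mass_g <= 0))
      msg <- c(msg, "cultures: tissue_mass_g must be > 0")
    if (any(cu$plated_volume_ul <= 0))
      msg <- c(msg, "cultures: plated_volume_ul must be > 0")
    if (any(cu$plated_volume_ul > cu$homogenate_volume_ml * 1000 + 1e-9))
      msg <- c(msg, "cultures: plated volume exceeds homogenate volume")
  }

  v <- object@vitals
  if (nrow(v) && !all(v$id %in% p$id)) msg <- c(msg, "vitals: unknown piglet id")

  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

setValidity("PigletCohort", validPigletCohort)

#' FeatureTable: taxa-by-sample microbiome counts with taxonomy and tree
#'
#' Integer count matrix (taxa in rows, samples in columns) from a denoised
#' 16S workflow, together with per-taxon lineage strings, an optional rooted
#' phylogeny over the taxa and per-sample metadata. Lineages are
#' semicolon-delimited ranked strings (domain;phylum;class;order;family;genus),
#' optionally with QIIME-style `x__` rank prefixes; unresolved trailing ranks
#' may be empty.
#'
#' @slot counts non-negative integer matrix with unique row (taxon) and
#'   column (sample) names.
#' @slot taxonomy named character vector of lineage strings covering every
#'   taxon (may be length zero when no taxonomy is attached).
#' @slot tree an [ape::phylo] rooted tree whose tip labels include every
#'   taxon, or NULL.
#' @slot sampleData data.frame keyed by rownames = sample ids (zero columns
#'   allowed).
#'
#' @seealso [featureTable()] for the constructor; [rarefy()],
#'   [prevalenceFilter()], [collapseTaxonomy()], [alphaDiversity()],
#'   [weightedUnifrac()].
#' @export
setClass("FeatureTable",
  slots = c(
    counts = "matrix",
    taxonomy = "character",
    tree = "ANY",
    sampleData = "data.frame"
  )
)

validFeatureTable <- function(object) {
  x <- object@counts
  msg <- character()
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicated taxon ids")
  if (anyDuplicated(colnames(x))) msg <- c(msg, "duplicated sample ids")
  if (any(x < 0)) msg <- c(msg, "negative counts")
  if (any(x != round(x))) msg <- c(msg, "counts must be integers")
  if (length(object@taxonomy)) {
    missing <- setdiff(rownames(x), names(object@taxonomy))
    if (length(missing))
      msg <- c(msg, paste("taxa without lineage:",
                          paste(utils::head(missing, 3), collapse = ", ")))
  }
  if (!is.null(object@tree)) {
    if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
    else {
      ## the root is the tree's root node; basal polytomies (star trees) are
      ## fine, but branch lengths are required and must be non-negative
      if (is.null(object@tree$edge.length) ||
          any(object@tree$edge.length < 0))
        msg <- c(msg, "tree must have non-negative branch lengths")
      absent <- setdiff(rownames(x), object@tree$tip.label)
      if (length(absent))
        msg <- c(msg, paste("taxa absent from tree:",
                            paste(utils::head(absent, 3), collapse = ", ")))
    }
  }
  if (nrow(object@sampleData) &&
      !identical(rownames(object@sampleData), colnames(x)))
    msg <- c(msg, "sampleData rownames must equal sample ids in order")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

setValidity("FeatureTable", validFeatureTable)
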