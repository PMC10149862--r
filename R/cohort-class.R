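#' Construct a validated PigletCohort
#'
#' Assembles the five tidy tables into a [PigletCohort-class] object, coercing
#' column types and running the validity checks. `vitals` may be omitted.
#'
#' @param piglets,css,segments,cultures,vitals data.frames as documented in
#'   [PigletCohort-class].
#' @return A `PigletCohort` object.
#' @examples
#' coh <- fixtureCohort()
#' coh
#' @export
PigletCohort <- function(piglets, css, segments, cultures, vitals = NULL) {
  assertColumns(piglets, c("id", "group", "sex", "birth_weight_kg",
                           "final_weight_kg", "outcome", "end_time_h"),
                "piglets")
  assertColumns(css, c("id", "time_h", "motor", "verbal", "alertness",
                       "color"), "css")
  assertColumns(segments, c("id", "segment", "gross", "histologic"),
                "segments")
  assertColumns(cultures, c("id", "organ", "colonies", "plated_volume_ul",
                            "homogenate_volume_ml", "tissue_mass_g"),
                "cultures")
  if (is.null(vitals))
    vitals <- data.frame(id = character(), time_h = numeric(),
                         weight_kg = numeric(), temperature_c = numeric())
  piglets$id <- as.character(piglets$id)
  css$id <- as.character(css$id)
  segments$id <- as.character(segments$id)
  cultures$id <- as.character(cultures$id)
  vitals$id <- as.character(vitals$id)
  tryCatch(
    new("PigletCohort",
        piglets = as.data.frame(piglets), css = as.data.frame(css),
        segments = as.data.frame(segments),
        cultures = as.data.frame(cultures),
        vitals = as.data.frame(vitals)),
    error = function(e) validationError(conditionMessage(e)))
}

#' @rdname PigletCohort
#' @param object,x a `PigletCohort`.
#' @export
setGeneric("piglets", function(x) standardGeneric("piglets"))
#' @rdname PigletCohort
#' @export
setMethod("piglets", "PigletCohort", function(x) x@piglets)

#' @rdname PigletCohort
#' @export
setGeneric("cssObservations", function(x) standardGeneric("cssObservations"))
#' @rdname PigletCohort
#' @export
setMethod("cssObservations", "PigletCohort", function(x) x@css)

#' @rdname PigletCohort
#' @export
setGeneric("segmentScores", function(x) standardGeneric("segmentScores"))
#' @rdname PigletCohort
#' @export
setMethod("segmentScores", "PigletCohort", function(x) x@segments)

#' @rdname PigletCohort
#' @export
setGeneric("organCultures", function(x) standardGeneric("organCultures"))
#' @rdname PigletCohort
#' @export
setMethod("organCultures", "PigletCohort", function(x) x@cultures)

#' @rdname PigletCohort
#' @export
setGeneric("vitalSigns", function(x) standardGeneric("vitalSigns"))
#' @rdname PigletCohort
#' @export
setMethod("vitalSigns", "PigletCohort", function(x) x@vitals)

setMethod("show", "PigletCohort", function(object) {
  p <- object@piglets
  cat("PigletCohort with", nrow(p), "piglets (",
      paste(sprintf("%s: %d", names(table(p$group)), table(p$group)),
            collapse = ", "), ")\n")
  cat("  CSS observations:", nrow(object@css),
      "| segment scores:", nrow(object@segments),
      "| organ cultures:", nrow(object@cultures), "\n")
  surv <- sum(p$outcome == "survived")
  cat("  outcomes:", surv, "survived,", nrow(p) - surv, "non-survivors\n")
})
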