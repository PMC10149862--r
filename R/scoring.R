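## D-NEC scoring: clinical sickness score (CSS), gross/histologic injury
## aggregation, bacterial translocation, and the 3-of-4 composite call.

#' Total clinical sickness score of one observation
#'
#' Sums the four 0-2 subscores (motor/tone, verbal, alertness, body color)
#' recorded at a feed; the total therefore lies in 0..8, with 8 the sickest
#' possible animal. Vectorized over observations.
#'
#' @param motor,verbal,alertness,color integer subscores in \{0, 1, 2\}.
#' @return integer vector of totals in 0..8.
#' @examples
#' cssTotal(2, 2, 2, 2)  # maximal sickness, 8
#' cssTotal(1, 0, 2, 1)
#' @export
cssTotal <- function(motor, verbal, alertness, color) {
  sub <- cbind(motor, verbal, alertness, color)
  if (!all(sub %in% 0:2))
    validationError("cssTotal: subscores must be in {0,1,2}")
  as.integer(rowSums(sub))
}

#' Post-mortem imputed CSS series on the cohort feed schedule
#'
#' Returns the piglet's CSS totals aligned to the cohort-wide feed schedule.
#' For a non-survivor, every schedule time after its end time is imputed as
#' the maximal score 8; survivors receive no imputation. Schedule times at or
#' before the end time take the observed total at that time (NA when the
#' piglet was not scored at that feed). The imputed series feeds only the
#' group-average curves, never the D-NEC CSS criterion.
#'
#' @param times,totals observed CSS times (h) and totals for one piglet.
#' @param endTime the piglet's end-of-observation time (h).
#' @param survived logical; TRUE when the piglet reached study end alive.
#' @param schedule sorted vector of cohort feed times (h).
#' @return data.frame with columns `time_h`, `score`, `imputed`.
#' @export
imputeCssSeries <- function(times, totals, endTime, survived, schedule) {
  if (is.unsorted(schedule, strictly = TRUE))
    validationError("imputeCssSeries: schedule must be strictly increasing")
  score <- rep(NA_real_, length(schedule))
  m <- match(schedule, times)
  score[!is.na(m)] <- totals[m[!is.na(m)]]
  imputed <- rep(FALSE, length(schedule))
  if (!survived) {
    after <- schedule > endTime + 1e-9
    score[after] <- 8
    imputed <- after
  }
  data.frame(time_h = schedule, score = score, imputed = imputed)
}

#' Group-average CSS curves with post-mortem imputation
#'
#' The group mean at each feed time uses the imputed series of
#' [imputeCssSeries()], so an animal euthanized mid-study contributes a score
#' of 8 at every remaining feed.
#'
#' @param cohort a [PigletCohort-class].
#' @param schedule sorted feed times (h); defaults to the union of observed
#'   CSS times.
#' @return data.frame with columns `group`, `time_h`, `mean_css`, `n`.
#' @export
groupMeanCss <- function(cohort, schedule = NULL) {
  stopifnot(is(cohort, "PigletCohort"))
  p <- piglets(cohort)
  s <- cssObservations(cohort)
  if (is.null(schedule)) schedule <- sort(unique(s$time_h))
  out <- lapply(split(p, p$group), function(pg) {
    if (!nrow(pg)) validationError("groupMeanCss: empty group")
    series <- lapply(pg$id, function(id) {
      si <- s[s$id == id, ]
      imputeCssSeries(si$time_h,
                      cssTotal(si$motor, si$verbal, si$alertness, si$color),
                      pg$end_time_h[pg$id == id],
                      pg$outcome[pg$id == id] == "survived", schedule)$score
    })
    mat <- do.call(rbind, series)
    data.frame(group = pg$group[1], time_h = schedule,
               mean_css = colMeans(mat, na.rm = TRUE),
               n = colSums(!is.na(mat)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Maximum observed CSS in the last hours of life
#'
#' The D-NEC clinical criterion looks at the highest observed (never imputed)
#' CSS total within the half-open window (endTime - window, endTime]. When no
#' observation falls inside the window, the last observed total before the
#' window is returned and flagged `in_window = FALSE`.
#'
#' @param times,totals observed CSS times (h) and totals for one piglet.
#' @param endTime end of life / study (h).
#' @param window window length in hours (default 12).
#' @return list with `max_css`, `in_window`, and `positive` (max >= 5).
#' @export
maxCssLastWindow <- function(times, totals, endTime, window = 12,
                             threshold = 5) {
  if (!length(times)) validationError("maxCssLastWindow: no CSS observations")
  inside <- times > endTime - window + 1e-9 & times <= endTime + 1e-9
  if (any(inside)) {
    m <- max(totals[inside])
    list(max_css = as.integer(m), in_window = TRUE, positive = m >= threshold)
  } else {
    m <- totals[which.max(times)]
    list(max_css = as.integer(m), in_window = FALSE, positive = m >= threshold)
  }
}

#' @param threshold criterion cutoff on the windowed maximum (default 5).
#' @rdname maxCssLastWindow
NULL

#' Animal-level gross injury score
#'
#' The animal's gross score is the highest score over its intestinal segments
#' (proximal/mid/distal small intestine, colon). Scores 1-3 are classed as no
#' gross injury, 4-6 as gross injury.
#'
#' @param gross vector of per-segment gross scores (1..6, NA allowed).
#' @return list with `score`, `category` ("none"/"gross_injury"), `positive`
#'   (score >= 4); all NA/not-assessable when no score is present.
#' @examples
#' animalGrossScore(c(1, 5, 2, 2))  # score 5, gross injury
#' @export
animalGrossScore <- function(gross, threshold = 4) {
  gross <- gross[!is.na(gross)]
  if (!length(gross))
    return(list(score = NA_integer_, category = NA_character_, positive = NA))
  m <- max(gross)
  list(score = as.integer(m),
       category = if (m <= 3) "none" else "gross_injury",
       positive = m >= threshold)
}

#' Animal-level histologic injury score
#'
#' Highest histologic score over segments; 1-2 no injury, 3-4 moderate, 5
#' severe; scores of 3 or above are consistent with NEC.
#'
#' @param histologic vector of per-segment histologic scores (1..5, NA
#'   allowed).
#' @return list with `score`, `category` ("none"/"moderate"/"severe"),
#'   `positive` (score >= 3).
#' @examples
#' animalHistoScore(c(1, 5, 3, 2))  # severe
#' @export
animalHistoScore <- function(histologic, threshold = 3) {
  histologic <- histologic[!is.na(histologic)]
  if (!length(histologic))
    return(list(score = NA_integer_, category = NA_character_, positive = NA))
  m <- max(histologic)
  cat <- if (m <= 2) "none" else if (m <= 4) "moderate" else "severe"
  list(score = as.integer(m), category = cat, positive = m >= threshold)
}

#' @param threshold criterion cutoff (default 4 gross, 3 histologic).
#' @rdname animalGrossScore
NULL

#' Colony-forming units per gram of organ tissue
#'
#' Standardizes a plate count to CFU per gram: the plate count is scaled by
#' the homogenate-to-plated volume ratio (2 ml homogenate / 50 ul plated =
#' 40x under the default protocol) and divided by the tissue mass.
#' Vectorized.
#'
#' @param colonies plate colony count(s).
#' @param platedVolumeUl plated volume in microlitres.
#' @param homogenateVolumeMl homogenate volume in ml.
#' @param tissueMassG tissue mass in grams.
#' @return CFU per gram.
#' @examples
#' cfuPerGram(5, 50, 2, 0.5)  # 400
#' @export
cfuPerGram <- function(colonies, platedVolumeUl = 50, homogenateVolumeMl = 2,
                       tissueMassG = 1) {
  if (any(tissueMassG <= 0))
    validationError("cfuPerGram: tissue mass must be > 0")
  if (any(platedVolumeUl <= 0))
    validationError("cfuPerGram: plated volume must be > 0")
  if (any(colonies < 0)) validationError("cfuPerGram: negative colony count")
  colonies * (homogenateVolumeMl * 1000 / platedVolumeUl) / tissueMassG
}

#' Bacterial translocation criterion
#'
#' An organ is positive when its standardized load reaches `cfuThreshold`
#' (>= 1 CFU/g); the D-NEC criterion requires two or more distinct positive
#' organs among liver, spleen and mesenteric lymph nodes. Duplicate cultures
#' of one organ are resolved by the per-organ maximum load.
#'
#' @param organ character vector of organ labels.
#' @param cfu standardized loads (CFU/g) parallel to `organ`.
#' @param cfuThreshold per-organ positivity cutoff (default 1 CFU/g).
#' @param organThreshold number of positive organs required (default 2).
#' @return list with `n_positive` and `positive`.
#' @export
translocationCriterion <- function(organ, cfu, cfuThreshold = 1,
                                   organThreshold = 2) {
  if (!length(organ))
    return(list(n_positive = NA_integer_, positive = NA))
  perOrgan <- tapply(cfu, organ, max)
  n <- sum(perOrgan >= cfuThreshold)
  list(n_positive = as.integer(n), positive = n >= organThreshold)
}

#' Percent weight change from birth
#'
#' @param birthWeightKg,finalWeightKg weights in kg.
#' @return percent change, 100 * (final - birth) / birth.
#' @export
weightChangePercent <- function(birthWeightKg, finalWeightKg) {
  if (any(birthWeightKg <= 0))
    validationError("weightChangePercent: birth weight must be > 0")
  100 * (finalWeightKg - birthWeightKg) / birthWeightKg
}

#' Colostrum batch quality control on IgG content
#'
#' Batches pass when they contain at least `minIgG` mg/ml of IgG (default
#' 5 mg/ml, the level below which colostrum fails to protect against early
#' death).
#'
#' @param iggMgMl IgG concentration(s) in mg/ml.
#' @param minIgG acceptance threshold (mg/ml).
#' @return logical vector.
#' @export
colostrumQc <- function(iggMgMl, minIgG = 5) {
  if (any(iggMgMl < 0))
    validationError("colostrumQc: negative IgG concentration")
  iggMgMl >= minIgG
}

#' Humane-endpoint evaluation from per-feed vitals
#'
#' A piglet meets the humane endpoint if any single-trigger rule fires (loss
#' of more than 25% of birth weight, a single temperature above 40.5 C, or
#' extreme lethargy), or if at least two of the listed criteria (loss of
#' >20% of birth weight, significant lethargy, temperature >40 C, bloody
#' diarrhea, abdominal distension, emesis, abnormal breathing) are present at
#' each of two consecutive feeds.
#'
#' @param vitals data.frame ordered by feed with columns `time_h`,
#'   `weight_kg`, `temperature_c` and the logical flags `extreme_lethargy`,
#'   `lethargy`, `bloody_diarrhea`, `abdominal_distension`, `emesis`,
#'   `abnormal_breathing`.
#' @param birthWeightKg birth weight in kg.
#' @return list with `triggered`, `time_h` of the first trigger (NA if none)
#'   and `rule` describing it.
#' @export
humaneEndpoint <- function(vitals, birthWeightKg) {
  if (!nrow(vitals))
    return(list(triggered = FALSE, time_h = NA_real_, rule = NA_character_))
  if (is.unsorted(vitals$time_h))
    validationError("humaneEndpoint: vitals must be ordered by feed time")
  flag <- function(nm) if (nm %in% names(vitals))
    isTRUE_v(vitals[[nm]]) else rep(FALSE, nrow(vitals))
  lossPct <- 100 * (birthWeightKg - vitals$weight_kg) / birthWeightKg
  single <- cbind(
    weight_loss_gt25 = lossPct > 25,
    temp_gt40.5 = !is.na(vitals$temperature_c) & vitals$temperature_c > 40.5,
    extreme_lethargy = flag("extreme_lethargy"))
  listed <- cbind(
    weight_loss_gt20 = lossPct > 20,
    lethargy = flag("lethargy"),
    temp_gt40 = !is.na(vitals$temperature_c) & vitals$temperature_c > 40,
    bloody_diarrhea = flag("bloody_diarrhea"),
    abdominal_distension = flag("abdominal_distension"),
    emesis = flag("emesis"),
    abnormal_breathing = flag("abnormal_breathing"))
  for (i in seq_len(nrow(vitals))) {
    hit <- which(single[i, ])
    if (length(hit))
      return(list(triggered = TRUE, time_h = vitals$time_h[i],
                  rule = colnames(single)[hit[1]]))
    if (i >= 2) {
      both <- listed[i - 1, ] & listed[i, ]
      if (sum(both) >= 2)
        return(list(triggered = TRUE, time_h = vitals$time_h[i],
                    rule = paste0("two_consecutive:",
                                  paste(colnames(listed)[both],
                                        collapse = "+"))))
    }
  }
  list(triggered = FALSE, time_h = NA_real_, rule = NA_character_)
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Default D-NEC thresholds
#'
#' The composite rule: gross injury score >= 4 of 6, histologic injury score
#' >= 3 of 5, CSS >= 5 of 8 within the last 12 h of life, bacterial
#' translocation of >= 1 CFU/g to >= 2 internal organs; D-NEC when at least
#' `minCriteria` = 3 of the four criteria hold.
#'
#' @return named list of thresholds understood by [dnecClassify()].
#' @export
dnecThresholds <- function() {
  list(gross = 4, histo = 3, css = 5, cssWindow = 12,
       cfu = 1, organs = 2, minCriteria = 3)
}

#' Classify every piglet of a cohort with the D-NEC composite rule
#'
#' Evaluates the four D-NEC criteria per piglet and calls D-NEC when at least
#' `thresholds$minCriteria` (default 3) of them hold. Classification is
#' refused with an informative error when any criterion is not assessable
#' (no gross score, no histologic score, no CSS observation, or no culture)
#' unless `partial = TRUE`, in which case affected piglets carry NA.
#'
#' @param cohort a [PigletCohort-class].
#' @param thresholds threshold list as produced by [dnecThresholds()];
#'   individual entries may be overridden.
#' @param partial logical; keep non-assessable piglets as NA rows instead of
#'   refusing (default FALSE).
#' @return data.frame (one row per piglet) with the per-criterion scores and
#'   flags, `n_positive`, and the composite `dnec` call.
#' @examples
#' panel <- dnecClassify(fixtureCohort())
#' table(panel$group, panel$dnec)
#' @export
dnecClassify <- function(cohort, thresholds = dnecThresholds(),
                         partial = FALSE) {
  stopifnot(is(cohort, "PigletCohort"))
  th <- utils::modifyList(dnecThresholds(), thresholds)
  p <- piglets(cohort)
  s <- cssObservations(cohort)
  g <- segmentScores(cohort)
  cu <- organCultures(cohort)

  rows <- lapply(seq_len(nrow(p)), function(i) {
    id <- p$id[i]
    gi <- animalGrossScore(g$gross[g$id == id], th$gross)
    hi <- animalHistoScore(g$histologic[g$id == id], th$histo)
    si <- s[s$id == id, ]
    if (nrow(si)) {
      ci <- maxCssLastWindow(si$time_h,
                             cssTotal(si$motor, si$verbal, si$alertness,
                                      si$color),
                             p$end_time_h[i], th$cssWindow, th$css)
    } else ci <- list(max_css = NA_integer_, in_window = NA, positive = NA)
    cui <- cu[cu$id == id, ]
    ti <- if (nrow(cui)) {
      translocationCriterion(cui$organ,
                             cfuPerGram(cui$colonies, cui$plated_volume_ul,
                                        cui$homogenate_volume_ml,
                                        cui$tissue_mass_g),
                             th$cfu, th$organs)
    } else list(n_positive = NA_integer_, positive = NA)

    flags <- c(gross = gi$positive, histo = hi$positive, css = ci$positive,
               translocation = ti$positive)
    if (anyNA(flags) && !partial)
      validationError("dnecClassify: criterion not assessable for piglet ",
                      id, " (", paste(names(flags)[is.na(flags)],
                                      collapse = ", "), ")")
    nPos <- if (anyNA(flags)) NA_integer_ else as.integer(sum(flags))
    data.frame(id = id, group = p$group[i],
               gross_score = gi$score, gross_positive = flags[["gross"]],
               histo_score = hi$score, histo_category = hi$category,
               histo_positive = flags[["histo"]],
               max_css = ci$max_css, css_in_window = ci$in_window,
               css_positive = flags[["css"]],
               n_translocated_organs = ti$n_positive,
               translocation_positive = flags[["translocation"]],
               n_positive = nPos,
               dnec = if (is.na(nPos)) NA else nPos >= th$minCriteria)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
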