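test_that("cssTotal sums subscores and rejects out-of-range values", {
  expect_identical(cssTotal(2, 2, 2, 2), 8L)
  expect_identical(cssTotal(0, 0, 0, 0), 0L)
  expect_identical(cssTotal(1, 0, 2, 1), 4L)
  expect_identical(cssTotal(c(2, 1), c(2, 0), c(2, 2), c(2, 1)), c(8L, 4L))
  expect_error(cssTotal(3, 0, 0, 0), "subscores")
  expect_error(cssTotal(-1, 0, 0, 0), "subscores")
})

test_that("post-mortem imputation fills 8s after death and only then", {
  schedule <- seq(12, 96, by = 12)
  ## survivor: unchanged, nothing imputed
  s <- imputeCssSeries(schedule, rep(c(0, 1, 0), length.out = 8), 96,
                       survived = TRUE, schedule = schedule)
  expect_false(any(s$imputed))
  ## euthanized at 48 h: every schedule point after 48 scored 8
  s <- imputeCssSeries(c(12, 24, 36, 48), c(2, 3, 5, 6), 48,
                       survived = FALSE, schedule = schedule)
  expect_true(all(s$score[s$time_h > 48] == 8))
  expect_true(all(s$imputed[s$time_h > 48]))
  expect_identical(s$score[s$time_h <= 48], c(2, 3, 5, 6))
  ## death at the final schedule time: nothing to impute
  s <- imputeCssSeries(schedule, rep(1, 8), 96, survived = FALSE,
                       schedule = schedule)
  expect_false(any(s$imputed))
  expect_error(imputeCssSeries(1, 1, 1, TRUE, c(24, 12)), "schedule")
})

test_that("group mean CSS averages imputed series per schedule point", {
  ## two formula piglets: one dead at 24 h (imputed 8), one alive at 0
  mk <- function(id, times, end, outcome) {
    list(p = data.frame(id = id, group = "formula", sex = "M",
                        birth_weight_kg = 1, final_weight_kg = 1,
                        outcome = outcome, end_time_h = end),
         s = data.frame(id = id, time_h = times, motor = 0, verbal = 0,
                        alertness = 0, color = 0))
  }
  a <- mk("a", c(12, 24), 24, "euthanized")
  b <- mk("b", seq(12, 48, 12), 48, "survived")
  coh <- PigletCohort(rbind(a$p, b$p), rbind(a$s, b$s),
                      data.frame(id = character(), segment = character(),
                                 gross = integer(), histologic = integer()),
                      data.frame(id = character(), organ = character(),
                                 colonies = integer(),
                                 plated_volume_ul = numeric(),
                                 homogenate_volume_ml = numeric(),
                                 tissue_mass_g = numeric()))
  gm <- groupMeanCss(coh, schedule = seq(12, 48, 12))
  expect_equal(gm$mean_css, c(0, 0, 4, 4))  # (8 + 0) / 2 after the death
})

test_that("last-12h CSS window is half-open and falls back when empty", {
  ## totals at -11, -5, -1 h relative to end: max 6, criterion true
  r <- maxCssLastWindow(c(37, 43, 47), c(3, 6, 4), endTime = 48)
  expect_identical(r$max_css, 6L)
  expect_true(r$positive && r$in_window)
  expect_false(maxCssLastWindow(c(40, 44), c(4, 3), 48)$positive)
  ## boundary observation exactly at end - 12 is excluded (half-open)
  r <- maxCssLastWindow(c(36, 40), c(8, 2), endTime = 48)
  expect_identical(r$max_css, 2L)
  ## no observation inside the window: last prior total, flagged
  r <- maxCssLastWindow(c(12, 20), c(5, 7), endTime = 48)
  expect_false(r$in_window)
  expect_identical(r$max_css, 7L)
  ## brute-force filter oracle on random series
  set.seed(41)
  for (i in 1:200) {
    times <- sort(sample(seq(12, 96, 4), 8))
    totals <- sample(0:8, 8, replace = TRUE)
    end <- sample(seq(24, 96, 4), 1)
    times <- times[times <= end]; totals <- totals[seq_along(times)]
    if (!length(times)) next
    inw <- times > end - 12 & times <= end
    expected <- if (any(inw)) max(totals[inw]) else totals[length(totals)]
    expect_identical(maxCssLastWindow(times, totals, end)$max_css,
                     as.integer(expected))
  }
})

test_that("animal gross/histologic scores are segment maxima with categories", {
  g <- animalGrossScore(c(1, 5, 2, 2))
  expect_identical(g$score, 5L)
  expect_identical(g$category, "gross_injury")
  expect_identical(animalGrossScore(c(1, 1, 1, 1))$category, "none")
  expect_false(animalGrossScore(c(3, 3, 3, 3))$positive)  # boundary
  h <- animalHistoScore(c(1, 5, 3, 2))
  expect_identical(h$score, 5L)
  expect_identical(h$category, "severe")
  h <- animalHistoScore(c(1, 1, 1, 4))
  expect_identical(h$category, "moderate")
  expect_false(animalHistoScore(c(2, 2, 2, 2))$positive)  # boundary
  ## order invariance against the max() oracle
  set.seed(11)
  for (i in 1:50) {
    v <- sample(1:6, 4, replace = TRUE)
    expect_identical(animalGrossScore(v)$score,
                     animalGrossScore(sample(v))$score)
    expect_identical(animalGrossScore(v)$score, as.integer(max(v)))
  }
  expect_true(is.na(animalGrossScore(c(NA, NA))$positive))
})

test_that("CFU standardization matches the volume-ratio hand computation", {
  expect_equal(cfuPerGram(5, 50, 2, 0.5), 400)
  expect_equal(cfuPerGram(0, 50, 2, 0.5), 0)
  expect_equal(cfuPerGram(1, 50, 2, 40), 1)  # detection boundary
  expect_error(cfuPerGram(1, 50, 2, 0), "tissue mass")
  expect_error(cfuPerGram(1, 0, 2, 1), "plated volume")
})

test_that("translocation requires >= 1 CFU/g in >= 2 distinct organs", {
  r <- translocationCriterion(c("liver", "spleen", "mln"), c(400, 0, 3))
  expect_identical(r$n_positive, 2L)
  expect_true(r$positive)
  expect_false(translocationCriterion(c("liver", "spleen", "mln"),
                                      c(400, 0, 0))$positive)
  expect_identical(translocationCriterion(c("liver", "spleen", "mln"),
                                          c(0.5, 0.5, 0.5))$n_positive, 0L)
  ## duplicate organ rows resolved by per-organ maximum
  r <- translocationCriterion(c("liver", "liver", "spleen"), c(0, 5, 2))
  expect_identical(r$n_positive, 2L)
})

test_that("D-NEC composite is >=3-of-4 and refuses unassessable piglets", {
  coh <- fixtureCohort()
  panel <- dnecClassify(coh)
  expect_identical(panel$n_positive,
                   as.integer(panel$gross_positive + panel$histo_positive +
                                panel$css_positive +
                                panel$translocation_positive))
  expect_identical(panel$dnec, panel$n_positive >= 3)
  ## boundary: exactly 3 criteria is positive
  expect_true(all(panel$dnec[panel$n_positive == 3]))
  expect_false(any(panel$dnec[panel$n_positive == 2]))
  ## stricter composite: requiring 4-of-4 selects a subset
  strict <- dnecClassify(coh, list(minCriteria = 4))
  expect_true(all(strict$dnec <= panel$dnec))
  expect_identical(sum(strict$dnec), sum(panel$n_positive == 4))
  ## removing one piglet's cultures makes it unassessable
  cu <- organCultures(coh)
  broken <- PigletCohort(piglets(coh), cssObservations(coh),
                         segmentScores(coh), cu[cu$id != "F01", ])
  expect_error(dnecClassify(broken), "F01.*translocation")
  partial <- dnecClassify(broken, partial = TRUE)
  expect_true(is.na(partial$dnec[partial$id == "F01"]))
})

test_that("raising any component never turns D-NEC off (monotonicity)", {
  set.seed(99)
  for (i in 1:300) {
    z <- randomCriteriaInputs()
    base <- dnecFromInputs(z)
    z2 <- z
    what <- sample(c("gross", "histo", "totals", "cfu"), 1)
    j <- sample(length(z2[[what]]), 1)
    cap <- c(gross = 6, histo = 5, totals = 8, cfu = Inf)[[what]]
    z2[[what]][j] <- min(cap, z2[[what]][j] + sample(1:3, 1))
    expect_gte(sum(dnecFromInputs(z2)$flags), sum(base$flags))
  }
})

test_that("humane endpoint fires on single triggers and consecutive pairs", {
  vit <- function(w, temp, ...) {
    flags <- list(...)
    df <- data.frame(time_h = seq(12, by = 4, length.out = length(w)),
                     weight_kg = w, temperature_c = temp)
    for (nm in names(flags)) df[[nm]] <- flags[[nm]]
    df
  }
  ## 26% weight loss: single trigger
  r <- humaneEndpoint(vit(c(1.0, 0.73), c(38, 38)), birthWeightKg = 1.0)
  expect_true(r$triggered)
  expect_identical(r$rule, "weight_loss_gt25")
  ## temp > 40.5 once
  expect_true(humaneEndpoint(vit(c(1, 1), c(38, 40.6)), 1)$triggered)
  ## extreme lethargy once
  expect_true(humaneEndpoint(vit(c(1, 1), c(38, 38),
                                 extreme_lethargy = c(FALSE, TRUE)),
                             1)$triggered)
  ## temp 40.2 + emesis at two consecutive feeds
  r <- humaneEndpoint(vit(c(1, 1, 1), c(38, 40.2, 40.2),
                          emesis = c(FALSE, TRUE, TRUE)), 1)
  expect_true(r$triggered)
  expect_match(r$rule, "two_consecutive")
  ## same pair at one feed only: no trigger
  expect_false(humaneEndpoint(vit(c(1, 1, 1), c(38, 40.2, 38),
                                  emesis = c(FALSE, TRUE, FALSE)),
                              1)$triggered)
})

test_that("weight change and colostrum QC follow their thresholds", {
  expect_equal(weightChangePercent(1, 0.9), -10)
  expect_equal(weightChangePercent(1, 1.053), 5.3)
  expect_error(weightChangePercent(0, 1), "birth weight")
  expect_true(colostrumQc(94.898))
  expect_false(colostrumQc(1.123))
  expect_true(colostrumQc(5))  # "minimum of 5 mg/ml" is inclusive
  expect_error(colostrumQc(-1), "negative")
})

test_that("cohort validity rejects malformed inputs", {
  coh <- fixtureCohort()
  s <- cssObservations(coh)
  s$motor[1] <- 5
  expect_error(PigletCohort(piglets(coh), s, segmentScores(coh),
                            organCultures(coh)), "subscores")
  g <- segmentScores(coh)
  g$segment[1] <- "ileum"
  expect_error(PigletCohort(piglets(coh), cssObservations(coh), g,
                            organCultures(coh)), "segment")
  cu <- organCultures(coh)
  cu$tissue_mass_g[1] <- 0
  expect_error(PigletCohort(piglets(coh), cssObservations(coh),
                            segmentScores(coh), cu), "tissue_mass")
})
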