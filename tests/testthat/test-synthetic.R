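test_that("regeneration with the same seed is bit-identical", {
  a <- generateCohort(defaultArchetypes(5L), seed = 13L)
  b <- generateCohort(defaultArchetypes(5L), seed = 13L)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_identical(a$outcomes, b$outcomes)
  c <- generateCohort(defaultArchetypes(5L), seed = 14L)
  expect_false(identical(a$events, c$events))
})

test_that("a no-prodrome archetype produces images empty outside the index
           week", {
  spec <- list(archetypeSpec(1L, 4L, profile = "none"))
  co <- generateCohort(spec, seed = 3L)
  x <- encodeCohort(co$events, patients = co$patients,
                    registry = the_registry)
  px <- pixelMatrix(x)
  pre_index <- SummarizedExperiment::rowData(x)$week != 0
  expect_true(all(px[, pre_index] == 0))
  expect_true(all(px[, !pre_index] >= 0))   # index-week diagnosis present
})

test_that("archetype onset controls where prodromal events appear", {
  spec <- list(archetypeSpec(2L, 20L, onset_week = -6L, profile = "constant",
                             amplitude = 0.9, active_rows = c(61L, 62L)))
  co <- generateCohort(spec, seed = 8L)
  expect_true(all(co$events$week_offset >= -6))
  rows_seen <- unique(co$events$code)
  expect_setequal(rows_seen, c("symptom:depressed_mood",
                               "symptom:anhedonia", "296.4"))
})

test_that("invalid archetype specs are rejected", {
  expect_error(archetypeSpec(1, 0), "n_patients")
  expect_error(archetypeSpec(1, 5, onset_week = -60L))
  expect_error(archetypeSpec(1, 5, amplitude = 1.5))
  expect_error(generateCohort(list(archetypeSpec(1, 2,
                                                 active_rows = 999L))),
               "absent from registry")
})

test_that("planted outcome rates are recovered within 3 binomial SEs", {
  n <- 2000L
  co <- generateCohort(defaultArchetypes(n), seed = 314L,
                       include_events = FALSE)
  merged <- merge(co$outcomes, co$patients[, c("patient_id", "archetype")])
  for (s in co$specs) {
    r <- merged[merged$archetype == s$label, ]
    p_death <- s$death_p
    se <- sqrt(p_death * (1 - p_death) / n)
    expect_lt(abs(mean(r$died_within_1y) - p_death), 3 * se + 1e-12)
    p_hosp <- 1 - dnbinom(0, mu = s$hosp_mu, size = s$hosp_size)
    se_h <- sqrt(p_hosp * (1 - p_hosp) / n)
    expect_lt(abs(mean(r$hospitalizations_1y >= 1) - p_hosp), 3 * se_h)
  }
})

test_that("the no-prodrome archetype has the lowest hospitalization rate as
           generated", {
  co <- generateCohort(defaultArchetypes(500L), seed = 27L,
                       include_events = FALSE)
  merged <- merge(co$outcomes, co$patients[, c("patient_id", "archetype")])
  rates <- tapply(merged$hospitalizations_1y >= 1, merged$archetype, mean)
  expect_identical(names(which.min(rates)), "1")
})

test_that("eligibility filter keeps exactly the patients meeting all three
           criteria", {
  fixture <- data.frame(
    patient_id = paste0("e", 1:5),
    n_bd_codes = c(1L, 3L, 2L, 4L, 2L),
    months_pre = c(24L, 10L, 13L, 36L, 12L),
    months_post = c(24L, 24L, 8L, 14L, 12L))
  res <- eligibilityFilter(fixture)
  expect_identical(res$patients$patient_id, c("e4", "e5"))
  expect_identical(unname(res$counts["retained"]), 2L)
  expect_identical(res$excluded$reason,
                   c("insufficient BD codes",
                     "insufficient pre-index presence",
                     "insufficient post-index presence"))
  # thresholds are parameters
  res2 <- eligibilityFilter(fixture, bd_code_min = 1L, pre_months = 1L,
                            post_months = 1L)
  expect_identical(nrow(res2$patients), 5L)
})

test_that("separation-to-recovery is monotone across separation levels", {
  skip_if_not_installed("mclust")
  make_specs <- function(amp, prob) list(
    archetypeSpec(1L, 30L, onset_week = -40L, profile = "constant",
                  amplitude = amp, active_rows = c(23L, 24L),
                  event_prob = prob),
    archetypeSpec(2L, 30L, onset_week = -40L, profile = "constant",
                  amplitude = amp, active_rows = c(27L, 28L),
                  event_prob = prob),
    archetypeSpec(3L, 30L, onset_week = -40L, profile = "constant",
                  amplitude = amp, active_rows = c(33L, 34L),
                  event_prob = prob))
  ari_at <- function(amp, prob, seed) {
    co <- generateCohort(make_specs(amp, prob), seed = seed)
    x <- encodeCohort(co$events, patients = co$patients,
                      registry = the_registry)
    m <- kmeansFit(blurImages(x), 3, seed = seed)
    mclust::adjustedRandIndex(m@assignments[names(co$true_labels)],
                              co$true_labels)
  }
  aris <- c(low = ari_at(0.05, 0.05, 55),
            mid = ari_at(0.3, 0.3, 55),
            high = ari_at(0.9, 0.8, 55))
  expect_true(aris["low"] <= aris["mid"] + 1e-9)
  expect_true(aris["mid"] <= aris["high"] + 1e-9)
  expect_gt(aris["high"], 0.9)
})
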