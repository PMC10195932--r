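test_that("week binning is toward zero: index week spans its 7 days", {
  idx <- as.Date("2012-06-30")
  expect_identical(weekOffset(idx - 3, idx), 0L)
  expect_identical(weekOffset(idx, idx), 0L)
  expect_identical(weekOffset(idx - 350, idx), -50L)
  expect_identical(weekOffset(idx - 7, idx), -1L)
  expect_identical(weekOffset(idx - 400, idx), -57L)  # outside -52..0
  # agrees with direct day arithmetic over a sweep of offsets
  days <- -380:6
  expect_identical(weekOffset(idx + days, idx), as.integer(trunc(days / 7)))
})

test_that("lab standardizer matches moments and rejects degenerate input", {
  s <- fitLabStandardizer(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_error(fitLabStandardizer(rep(5, 10)), "degenerate")
  expect_error(fitLabStandardizer(3), "at least 2")

  # Monte-Carlo: fitted moments near truth for a large normal sample
  vals <- withr::with_seed(99, rnorm(20000, mean = 100, sd = 15))
  s2 <- fitLabStandardizer(vals)
  expect_lt(abs(s2$mean - 100), 3 * 15 / sqrt(20000))
  expect_lt(abs(s2$sd - 15), 3 * 15 / sqrt(2 * 20000))
})

test_that("lab score is linear in |z| and saturates at the cap", {
  s <- fitLabStandardizer(c(1, 2, 3))     # mean 2, sd 1
  expect_equal(labScore(2, s), 0)
  expect_equal(labScore(2 + 3, s), 1)     # 3 SD with cap 3
  expect_equal(labScore(2 - 3, s), 1)
  expect_equal(labScore(2 + 1.5, s), 0.5)
  expect_equal(labScore(2 + 10, s), 1)    # beyond cap still 1
})

test_that("vital score is 0 in range, 1 at extremes, linear between", {
  v <- list(lo_n = 60, hi_n = 100, lo_e = 25, hi_e = 190)
  expect_equal(vitalScore(c(60, 80, 100), v), c(0, 0, 0))
  expect_equal(vitalScore(c(190, 25, 300, 10), v), c(1, 1, 1, 1))
  expect_equal(vitalScore(145, v), 0.5)   # midway hi_n..hi_e
  expect_equal(vitalScore(42.5, v), 0.5)  # midway lo_n..lo_e
})

test_that("symptom matching is case-insensitive whole-word presence", {
  lex <- defaultLexicon(the_registry)
  expect_identical(matchSymptoms("", lex), character())
  expect_identical(matchSymptoms(NA_character_, lex), character())
  expect_identical(matchSymptoms("Reports severe INSOMNIA nightly.", lex),
                   "insomnia")
  hits <- matchSymptoms("anxious with racing thoughts", lex)
  expect_setequal(hits, c("anxiety", "racing_thoughts"))
  # substring must not match across word boundaries
  expect_false("guilt" %in% matchSymptoms("guiltless", lex))
  # oracle: per-keyword scan agrees on a composite note
  note <- "patient is hopeless, denies suicide, tremor on exam"
  manual <- names(lex)[vapply(lex, function(kws)
    any(vapply(kws, function(k)
      grepl(paste0("\\b", k, "\\b"), tolower(note)), logical(1))),
    logical(1))]
  expect_setequal(matchSymptoms(note, lex), manual)
})

test_that("encoding places events on the anchored pixels", {
  reg <- the_registry
  # no events at all: all-zero image
  x0 <- encodeCohort(data.frame(patient_id = "p9", week_offset = 1L,
                                code = "540"),
                     patients = data.frame(patient_id = "p9"),
                     registry = reg)
  expect_equal(sum(patientImage(suppressMessages(x0), "p9")), 0)

  # single digestive event at week -50: exactly one pixel, row 30
  ev <- data.frame(patient_id = "p1", week_offset = -50L, code = "540")
  img <- patientImage(encodeCohort(ev, registry = reg), "p1")
  expect_equal(sum(img != 0), 1)
  expect_equal(img[30, "-50"], 1)

  # same-week duplicate graded events keep the max score
  s <- fitLabStandardizer(c(90, 100, 110))
  ev2 <- data.frame(patient_id = "p1", week_offset = -4L,
                    code = "glucose", value = c(100 + 0.2 * 3 * s$sd,
                                                100 + 0.7 * 3 * s$sd))
  img2 <- patientImage(
    encodeCohort(ev2, registry = reg,
                 standardizers = list(glucose = s)), "p1")
  expect_equal(img2[lookupFeature(reg, "glucose")$row, "-4"], 0.7)
})

test_that("hospitalization spans mark exactly the overlapped weeks", {
  ev <- data.frame(patient_id = "p1", week_offset = -3L, code = "hosp",
                   duration_weeks = 3L)
  img <- patientImage(encodeCohort(ev, registry = the_registry), "p1")
  expect_equal(unname(img[1, c("-3", "-2", "-1")]), c(1, 1, 1))
  expect_equal(sum(img[1, ]), 3)
  expect_equal(sum(img[-1, ]), 0)
})

test_that("note text sets the matched symptom rows", {
  ev <- data.frame(patient_id = "p1", week_offset = -8L, code = NA,
                   note_text = "pt anxious; reports racing thoughts")
  img <- patientImage(encodeCohort(ev, registry = the_registry), "p1")
  ft <- featureTable(the_registry)
  expect_equal(img[ft$row[ft$name == "anxiety"], "-8"], 1)
  expect_equal(img[ft$row[ft$name == "racing_thoughts"], "-8"], 1)
  expect_equal(sum(img), 2)
})

test_that("encoding is in [0,1], binary rows are 0/1, and is order-invariant
           and monotone under added events", {
  reg <- the_registry
  co <- generateCohort(defaultArchetypes(3L), seed = 5L, registry = reg)
  std <- fitStandardizers(co$events, reg)
  x <- encodeCohort(co$events, patients = co$patients, registry = reg,
                    standardizers = std)
  px <- pixelMatrix(x)
  expect_true(all(px >= 0 & px <= 1))
  binrows <- featureTable(reg)$row[featureTable(reg)$kind == "binary"]
  binpix <- SummarizedExperiment::assay(x, "pixels")[SummarizedExperiment::rowData(x)$feature_row %in% binrows, ]
  expect_true(all(binpix %in% c(0, 1)))

  # permutation invariance
  perm <- withr::with_seed(2, sample(nrow(co$events)))
  x2 <- encodeCohort(co$events[perm, ], patients = co$patients,
                     registry = reg, standardizers = std)
  expect_equal(SummarizedExperiment::assay(x2, "pixels"), SummarizedExperiment::assay(x, "pixels"))

  # monotonicity: dropping events never increases any pixel
  x3 <- encodeCohort(co$events[-seq_len(50), ], patients = co$patients,
                     registry = reg, standardizers = std)
  expect_true(all(SummarizedExperiment::assay(x3, "pixels") <= SummarizedExperiment::assay(x, "pixels") + 1e-12))
})

test_that("unknown codes error by default and can be dropped by policy", {
  ev <- data.frame(patient_id = "p1", week_offset = -5L, code = "zzz9")
  expect_error(encodeCohort(ev, registry = the_registry), "unknown")
  x <- suppressMessages(
    encodeCohort(ev, registry = the_registry, on_unknown = "drop"))
  expect_equal(sum(patientImage(x, "p1")), 0)
})
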