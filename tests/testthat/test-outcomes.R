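test_that("standardized differences are symmetric, nonnegative, zero iff
           equal, and error on degenerate pairs", {
  expect_equal(asdBinary(0.3, 0.3), 0)
  expect_equal(asdBinary(0.2, 0.5), asdBinary(0.5, 0.2))
  expect_gt(asdBinary(0.2, 0.5), 0)
  expect_error(asdBinary(1, 1), "zero denominator")
  expect_error(asdBinary(0, 0), "zero denominator")

  expect_equal(asdContinuous(3, 1, 3, 2), 0)
  expect_equal(asdContinuous(1, 2, 4, 3), asdContinuous(4, 3, 1, 2))
  # affine invariance: rescale both groups by a > 0, shift by b
  expect_equal(asdContinuous(10 * 1.4 + 5, 10 * 2.2, 10 * 0.5 + 5, 10 * 1.1),
               asdContinuous(1.4, 2.2, 0.5, 1.1))
  expect_error(asdContinuous(1, 0, 2, 0), "zero denominator")
  expect_equal(asdContinuous(2, 0, 2, 0), 0)
})

test_that("integer rounding is half away from zero", {
  expect_identical(asdPercent(19.5), 20L)
  expect_identical(asdPercent(19.49), 19L)
  expect_identical(asdPercent(0.4), 0L)
})

test_that("outcome summaries compute rates, moments and the two
           mental-illness proportions", {
  rec <- tiny_outcomes()
  asg <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L), rec$patient_id)
  s <- summarizeOutcomes(rec, asg)
  expect_identical(s$cluster, c(1L, 2L))
  expect_equal(s$n, c(4L, 2L))
  expect_equal(s$death_rate[1], 0.25)
  expect_equal(s$hospitalization_rate[1], 0.5)
  expect_equal(s$mean_hosp[1], 0.75)
  expect_equal(s$sd_hosp[1], sd(c(0, 2, 1, 0)))
  expect_equal(s$mean_los[2], 15)
  # cluster 1: 2 of 3 hospitalization events mental; both hospitalized
  # patients had >= 1 mental admission
  expect_equal(s$prop_hosp_events_mental[1], 2 / 3)
  expect_equal(s$prop_hospitalized_with_mental[1], 1)
  expect_equal(s$prop_hosp_events_mental[2], 2 / 3)
})

test_that("outcome record invariants are enforced", {
  rec <- tiny_outcomes()
  rec$mental_illness_hospitalizations_1y[2] <- 5L   # exceeds total
  expect_error(summarizeOutcomes(rec, setNames(rep(1L, 6), rec$patient_id)),
               "cannot exceed")
  rec2 <- tiny_outcomes()[, -3]
  expect_error(summarizeOutcomes(rec2, setNames(rep(1L, 6),
                                                tiny_outcomes()$patient_id)),
               "missing column")
})

test_that("chi-square on a 2x2 fixture equals the closed form", {
  # clusters 1/2 with binary outcome counts a,b / c,d
  a <- 30; b <- 70; c <- 55; d <- 45
  cl <- rep(1:2, times = c(a + b, c + d))
  y <- c(rep(c(TRUE, FALSE), c(a, b)), rep(c(TRUE, FALSE), c(c, d)))
  tt <- chisq.test(table(cl, y), correct = FALSE)
  n <- a + b + c + d
  closed <- (a * d - b * c)^2 * n /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(unname(tt$statistic), closed)
})

test_that("identical clusters give zero ASDs and non-significant tests", {
  rec <- do.call(rbind, lapply(1:2, function(c) {
    r <- tiny_outcomes()
    r$patient_id <- paste0(r$patient_id, "_", c)
    r
  }))
  asg <- setNames(rep(1:2, each = 6), rec$patient_id)
  cmp <- suppressWarnings(compareClusters(rec, asg))
  expect_true(all(cmp$asd$asd[!is.na(cmp$asd$asd)] == 0))
  expect_true(all(cmp$tests$p_value > 0.9))
})

test_that("cluster comparison flags planted effects at scale", {
  specs <- list(
    archetypeSpec(1L, 2000L, profile = "none", death_p = 0.01,
                  hosp_mu = 0.3, hosp_size = 0.3, psychosis_p = 0.03),
    archetypeSpec(2L, 2000L, profile = "none", death_p = 0.10,
                  hosp_mu = 1.2, hosp_size = 0.5, psychosis_p = 0.03))
  co <- generateCohort(specs, seed = 202L, include_events = FALSE)
  asg <- co$true_labels
  cmp <- compareClusters(co$outcomes, asg)
  a <- cmp$asd
  # planted large effects are meaningful; psychosis (no planted effect) not
  expect_true(a$meaningful[a$outcome == "death" & a$cluster == 2])
  expect_true(a$meaningful[a$outcome == "hospitalization" & a$cluster == 2])
  expect_false(a$meaningful[a$outcome == "psychosis" & a$cluster == 2])
  expect_lt(cmp$tests$p_value[cmp$tests$outcome == "death"], 1e-6)
})

test_that("published group statistics reproduce the published ASD table", {
  ref <- referenceOutcomeStats()
  asd <- asdFromSummaries(ref, reference = 1)
  pub_cols <- c(death = "published_asd_death",
                hospitalization = "published_asd_hospitalization",
                n_hospitalizations = "published_asd_n_hospitalizations",
                length_of_stay = "published_asd_length_of_stay",
                prop_hosp_events_mental = "published_asd_prop_hosp_events_mental",
                prop_hospitalized_with_mental =
                  "published_asd_prop_hospitalized_with_mental")
  for (oc in names(pub_cols)) {
    got <- asd$asd_percent[asd$outcome == oc][order(asd$cluster[asd$outcome == oc])]
    want <- ref[[pub_cols[[oc]]]][ref$cluster != 1][order(ref$cluster[ref$cluster != 1])]
    if (oc == "prop_hospitalized_with_mental") {
      # the cluster-4 cell is published as 15 but its one-decimal published
      # inputs (77.3% vs 71.0%) yield 14.4; only the unrounded underlying
      # rates can give 15, so that single cell is held to +-1
      i4 <- which(ref$cluster[ref$cluster != 1] == 4)
      expect_identical(got[-i4], want[-i4])
      expect_lte(abs(got[i4] - want[i4]), 1L)
    } else {
      expect_identical(got, want, info = oc)
    }
  }
})
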