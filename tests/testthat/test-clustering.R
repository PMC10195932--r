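test_that("k = 1 gives the grand-mean SSE and k = n gives zero", {
  tc <- two_clouds(n_per = 5)
  m1 <- kmeansFit(tc$pts, 1, seed = 3)
  expect_equal(m1@sse, sum(sweep(tc$pts, 2, colMeans(tc$pts))^2))
  expect_true(all(m1@assignments == 1L))
  mn <- kmeansFit(tc$pts, nrow(tc$pts), seed = 3)
  expect_equal(mn@sse, 0)
})

test_that("infeasible k is rejected", {
  pts <- matrix(rep(c(0, 1), each = 6), ncol = 2)  # 2 distinct points
  expect_error(kmeansFit(pts, 3, seed = 1), "infeasible")
})

test_that("k = 2 on separated clouds matches the exhaustive best partition", {
  tc <- two_clouds(n_per = 5, sep = 8, seed = 4)
  m <- kmeansFit(tc$pts, 2, seed = 9)
  oracle <- best_two_partition_sse(tc$pts)
  expect_equal(m@sse, oracle$sse, tolerance = 1e-10)
  # partition equals the planted split (up to label swap)
  expect_equal(length(unique(paste(m@assignments, tc$truth))), 2)
  # every point sits with its nearest centroid
  d <- as.matrix(dist(rbind(m@centroids, tc$pts)))[-(1:2), 1:2]
  expect_true(all(m@assignments == apply(d, 1, which.min)))
})

test_that("fits are deterministic given (data, k, seed, restarts)", {
  tc <- two_clouds(n_per = 6, sep = 3, seed = 8)
  m1 <- kmeansFit(tc$pts, 3, seed = 17, nRestarts = 5)
  m2 <- kmeansFit(tc$pts, 3, seed = 17, nRestarts = 5)
  expect_identical(m1@assignments, m2@assignments)
  expect_identical(m1@sse, m2@sse)
})

test_that("sse scan is consistent with per-k fits and its seed policy", {
  tc <- two_clouds(n_per = 10, sep = 6, seed = 12)
  curve <- sseScan(tc$pts, k_min = 2, k_max = 6, seed = 30, nRestarts = 5)
  expect_identical(curve$k, 2:6)
  expect_true(all(diff(curve$sse) <= 1e-9))
  m4 <- kmeansFit(tc$pts, 4, seed = 30 + 4, nRestarts = 5)
  expect_equal(curve$sse[curve$k == 4], m4@sse)
})

test_that("identical points give zero SSE at every k", {
  pts <- matrix(1, 10, 3) + 0   # all identical -> only k = 1 feasible
  m <- kmeansFit(pts, 1, seed = 2)
  expect_equal(m@sse, 0)
})

test_that("elbow suggestion brackets a constructed sharp bend", {
  curve <- data.frame(k = 2:12,
                      sse = c(100, 80, 60, 40, 20, 18, 16, 14, 12, 10, 8))
  # slope changes from -20 to -2 at k = 6
  expect_equal(suggestElbow(curve), c(5, 7))
  expect_true(6 %in% seq(suggestElbow(curve)[1], suggestElbow(curve)[2]))
})

test_that("a strictly linear SSE curve yields the full range with warning", {
  curve <- data.frame(k = 2:10, sse = seq(90, 10, by = -10))
  expect_warning(rng <- suggestElbow(curve), "no discernible elbow")
  expect_equal(rng, c(2, 10))
})

test_that("fingerprints are means of the original images with exact
           pixel-range and weighted-mean identities", {
  co <- generateCohort(defaultArchetypes(4L), seed = 31L)
  x <- encodeCohort(co$events, patients = co$patients,
                    registry = the_registry)
  asg <- co$true_labels[colnames(x)]
  fps <- fingerprints(x, asg)
  expect_length(fps, 8)

  # a cluster of identical images has itself as fingerprint
  one <- patientImage(x, names(asg)[1])
  xx <- TemporalImageSet(list(a = one, b = one), weeks = imageWeeks(x))
  fp1 <- fingerprints(xx, c(a = 1L, b = 1L))[[1]]
  expect_equal(unname(fp1@meanImage), unname(one))

  # mixed 0/1 pixel averages to 0.5
  z <- matrix(0, 4, 5); o <- z; o[2, 3] <- 1
  fp2 <- fingerprints(TemporalImageSet(list(a = z, b = o)),
                      c(a = 1L, b = 1L))[[1]]
  expect_equal(unname(fp2@meanImage[2, 3]), 0.5)

  # weighted mean of fingerprints == cohort mean image, to 1e-12
  wmean <- Reduce(`+`, lapply(fps, function(f) f@meanImage * f@nPatients)) /
    sum(vapply(fps, function(f) f@nPatients, 1))
  cohort_mean <- matrix(rowMeans(SummarizedExperiment::assay(x, "pixels")),
                        nrow = nFeatures(x))
  expect_equal(unname(wmean), cohort_mean, tolerance = 1e-12)

  # pixels inside member range and [0, 1]
  for (f in fps)
    expect_true(all(f@meanImage >= 0 & f@meanImage <= 1))
})

test_that("empty clusters are excluded from fingerprints with a warning", {
  z <- matrix(0, 2, 3); o <- z + 1
  x <- TemporalImageSet(list(a = z, b = o))
  expect_warning(fps <- fingerprints(x, c(a = 1L, b = 3L)), "empty cluster")
  expect_length(fps, 2)
})

test_that("mass relabelling makes cluster 1 the least-burdened group", {
  co <- generateCohort(defaultArchetypes(5L), seed = 77L)
  x <- encodeCohort(co$events, patients = co$patients,
                    registry = the_registry)
  b <- blurImages(x)
  m <- relabelByMass(kmeansFit(b, 8, seed = 19), b)
  pts <- pixelMatrix(b)
  mass <- vapply(1:8, function(c)
    mean(rowSums(pts[m@assignments == c, , drop = FALSE])), 1)
  expect_true(all(diff(mass) >= 0))
  # the no-prodrome archetype lands in cluster 1
  arch1 <- names(co$true_labels)[co$true_labels == 1]
  expect_true(all(m@assignments[arch1] == 1L))
})
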