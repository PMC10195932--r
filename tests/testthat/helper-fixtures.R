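# Shared fixtures, built in code at test time.

the_registry <- defaultRegistry()

# tiny events table: one patient, a handful of coded events
tiny_events <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p1", "p2"),
    week_offset = c(-50L, -10L, 0L, -3L),
    code = c("540", "296.4", "glucose", "hosp"),
    value = c(NA, NA, 150, NA),
    duration_weeks = c(NA, NA, NA, 3L),
    stringsAsFactors = FALSE)
}

# deterministic small point cloud with two planted clusters
two_clouds <- function(n_per = 5, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    pts <- rbind(matrix(rnorm(n_per * 2, 0, 0.5), ncol = 2),
                 matrix(rnorm(n_per * 2, sep, 0.5), ncol = 2))
    rownames(pts) <- paste0("p", seq_len(2 * n_per))
    list(pts = pts, truth = rep(1:2, each = n_per))
  })
}

# exhaustive best 2-partition by SSE (oracle for k = 2 on <= 12 points)
best_two_partition_sse <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  best_split <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point 1 in group A; skip empty B
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sse <- 0
    for (g in list(which(!grp), which(grp))) {
      m <- pts[g, , drop = FALSE]
      sse <- sse + sum(sweep(m, 2, colMeans(m))^2)
    }
    if (sse < best) { best <- sse; best_split <- grp }
  }
  list(sse = best, split = best_split + 1L)
}

# small outcome records table covering all fields
tiny_outcomes <- function() {
  data.frame(
    patient_id = paste0("p", 1:6),
    died_within_1y = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hospitalizations_1y = c(0L, 2L, 1L, 0L, 3L, 0L),
    total_los_days_1y = c(0, 12.5, 3, 0, 30, 0),
    psychosis_1y = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    mental_illness_hospitalizations_1y = c(0L, 1L, 1L, 0L, 2L, 0L),
    stringsAsFactors = FALSE)
}
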