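## Synthetic cohort generator: patients, pre-diagnosis event streams with
## planted prodromal archetype structure, and one-year outcomes.  Emulates
## the data shape of a large EHR extract (index-dated patients, coded events
## in the 53-week pre-diagnosis window, hospitalization episodes) so that the
## whole fingerprinting pipeline can be exercised without protected data.

#' Define a prodromal archetype
#'
#' An archetype plants a phenotype: a prodrome onset week, an intensity
#' trajectory over the active weeks, a set of active feature rows with a
#' per-week event probability, and one-year outcome parameters.
#' Hospitalization counts are drawn from a negative binomial (the published
#' SDs exceed the means, so an overdispersed count law is required) and
#' per-stay length of stay from a log-normal (right-skewed).
#'
#' @param label Archetype label (integer).
#' @param n_patients Number of patients.
#' @param onset_week Prodrome onset week in \code{-52..0}.
#' @param profile Intensity trajectory over active weeks: \code{"none"} (no
#'   prodromal events), \code{"constant"}, \code{"ramp"} (linear increase
#'   from onset to index) or \code{"early_then_fade"} (fades to zero halfway
#'   to the index).
#' @param amplitude Peak event probability multiplier in [0, 1].
#' @param active_rows Registry feature rows active in the prodrome.
#' @param event_prob Baseline per-row per-active-week event probability
#'   (scaled by the profile weight and \code{amplitude}).
#' @param admit_prob Per-active-week probability of a prodromal hospital
#'   admission (1-2 week stay).
#' @param death_p,psychosis_p One-year death and psychosis probabilities.
#' @param hosp_mu,hosp_size Negative-binomial mean and size for the one-year
#'   hospitalization count.
#' @param los_meanlog,los_sdlog Log-normal parameters for the length of each
#'   stay (days).
#' @param mental_share Probability that a given hospitalization is due to
#'   mental illness.
#' @return A validated list of class \code{"ArchetypeSpec"}.
#' @export
archetypeSpec <- function(label, n_patients, onset_week = 0L,
                          profile = c("none", "constant", "ramp",
                                      "early_then_fade"),
                          amplitude = 0.8, active_rows = integer(),
                          event_prob = 0.8, admit_prob = 0,
                          death_p = 0.01, hosp_mu = 0.5, hosp_size = 0.35,
                          los_meanlog = log(10), los_sdlog = 1.1,
                          psychosis_p = 0.05, mental_share = 0.7) {
  profile <- match.arg(profile)
  stopifnot(n_patients >= 1, onset_week >= -52, onset_week <= 0,
            amplitude >= 0, amplitude <= 1, event_prob >= 0, event_prob <= 1,
            admit_prob >= 0, admit_prob <= 1,
            death_p >= 0, death_p <= 1, psychosis_p >= 0, psychosis_p <= 1,
            mental_share >= 0, mental_share <= 1, hosp_mu >= 0,
            hosp_size > 0)
  structure(list(label = as.integer(label),
                 n_patients = as.integer(n_patients),
                 onset_week = as.integer(onset_week), profile = profile,
                 amplitude = amplitude,
                 active_rows = as.integer(active_rows),
                 event_prob = event_prob, admit_prob = admit_prob,
                 death_p = death_p, hosp_mu = hosp_mu, hosp_size = hosp_size,
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 psychosis_p = psychosis_p, mental_share = mental_share),
            class = "ArchetypeSpec")
}

#' Default suite of eight prodromal archetypes
#'
#' Mirrors the qualitative taxonomy reported for prodromal bipolar-disorder
#' phenotypes: one cluster with no discernible prodrome (lowest subsequent
#' hospitalization burden), one late-onset short prodrome, two gradually
#' intensifying prodromes, three early-persistent prodromes of varying
#' feature mix and intensity, and one early prodrome that fades before the
#' index.  Archetypes occupy disjoint active feature rows (high separation).
#' Outcome parameters vary across archetypes with the same magnitudes as the
#' published eight-cluster outcome table.
#'
#' @param n_per Patients per archetype (default 100).
#' @return List of eight \code{ArchetypeSpec}s.
#' @export
defaultArchetypes <- function(n_per = 100L) {
  list(
    archetypeSpec(1L, n_per, profile = "none",
                  death_p = 0.010, hosp_mu = 0.2, hosp_size = 0.25,
                  los_meanlog = log(6), psychosis_p = 0.03,
                  mental_share = 0.64),
    archetypeSpec(2L, n_per, onset_week = -6L, profile = "constant",
                  amplitude = 0.9, active_rows = c(8L, 61L, 62L, 63L),
                  admit_prob = 0.03,
                  death_p = 0.021, hosp_mu = 0.8, hosp_size = 0.45,
                  los_meanlog = log(11), psychosis_p = 0.06,
                  mental_share = 0.72),
    archetypeSpec(3L, n_per, onset_week = -30L, profile = "ramp",
                  amplitude = 0.8, active_rows = c(12L, 70L, 71L, 72L),
                  admit_prob = 0.02,
                  death_p = 0.008, hosp_mu = 0.5, hosp_size = 0.35,
                  los_meanlog = log(8), psychosis_p = 0.05,
                  mental_share = 0.77),
    archetypeSpec(4L, n_per, onset_week = -40L, profile = "ramp",
                  amplitude = 0.7, active_rows = c(15L, 16L, 17L, 79L),
                  admit_prob = 0.02,
                  death_p = 0.014, hosp_mu = 0.6, hosp_size = 0.40,
                  los_meanlog = log(9), psychosis_p = 0.05,
                  mental_share = 0.66),
    archetypeSpec(5L, n_per, onset_week = -52L, profile = "constant",
                  amplitude = 0.8, active_rows = c(7L, 80L, 81L, 82L),
                  admit_prob = 0.02,
                  death_p = 0.013, hosp_mu = 0.5, hosp_size = 0.35,
                  los_meanlog = log(10), psychosis_p = 0.08,
                  mental_share = 0.73),
    archetypeSpec(6L, n_per, onset_week = -52L, profile = "constant",
                  amplitude = 0.6, active_rows = c(28L, 29L, 37L, 56L),
                  admit_prob = 0.03,
                  death_p = 0.046, hosp_mu = 0.7, hosp_size = 0.40,
                  los_meanlog = log(9), psychosis_p = 0.03,
                  mental_share = 0.35),
    archetypeSpec(7L, n_per, onset_week = -52L, profile = "constant",
                  amplitude = 0.9, active_rows = c(30L, 31L, 46L, 47L),
                  admit_prob = 0.01,
                  death_p = 0.014, hosp_mu = 0.3, hosp_size = 0.30,
                  los_meanlog = log(7), psychosis_p = 0.04,
                  mental_share = 0.58),
    archetypeSpec(8L, n_per, onset_week = -52L, profile = "early_then_fade",
                  amplitude = 0.9, active_rows = c(65L, 66L, 67L, 68L),
                  admit_prob = 0.02,
                  death_p = 0.026, hosp_mu = 1.4, hosp_size = 0.55,
                  los_meanlog = log(14), psychosis_p = 0.07,
                  mental_share = 0.64))
}

.profile_weight <- function(spec, weeks) {
  on <- spec$onset_week
  switch(spec$profile,
    none = rep(0, length(weeks)),
    constant = rep(1, length(weeks)),
    ramp = if (on == 0) rep(1, length(weeks)) else (weeks - on) / (0 - on),
    early_then_fade = {
      span <- max(1, (0 - on) / 2)
      pmax(0, 1 - (weeks - on) / span)
    })
}

## Theoretical hospitalization rate implied by the NB count law: P(X >= 1).
.nb_any_rate <- function(mu, size) 1 - stats::dnbinom(0, mu = mu, size = size)

#' Generate a synthetic cohort with planted archetypes
#'
#' Draws, for each patient of each archetype: an index date, demographics and
#' eligibility fields (all eligible by default); weekly prodromal events on
#' the archetype's active feature rows (graded rows receive plausibly
#' abnormal raw values drawn from the registry's scoring metadata, binary
#' rows plain coded events; hospital admissions span 1--2 weeks); an
#' index-week diagnosis event for every patient; and one-year outcomes from
#' the archetype's parameters.  All draws come from one generator seeded
#' once, so regeneration with the same spec and seed is bit-identical.
#'
#' @param specs List of \code{\link{archetypeSpec}}s (default
#'   \code{defaultArchetypes()}).
#' @param seed Integer seed.
#' @param registry Feature registry used to emit event codes.
#' @param include_events Generate the event stream (set \code{FALSE} when
#'   only outcomes are needed, e.g. for large outcome-calibration runs).
#' @return A list of class \code{"SyntheticCohort"}: \code{patients},
#'   \code{events}, \code{outcomes} data frames, \code{true_labels} (named
#'   integer vector), \code{seed}, \code{specs}.
#' @export
generateCohort <- function(specs = defaultArchetypes(), seed = 1L,
                           registry = defaultRegistry(),
                           include_events = TRUE) {
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "ArchetypeSpec")))
  ft <- registry@features
  for (s in specs)
    if (!all(s$active_rows %in% ft$row))
      stop("archetype ", s$label, " references rows absent from registry")

  withr::with_seed(as.integer(seed), {
    pats <- list(); evs <- list(); outs <- list(); labels <- integer()
    pid_counter <- 0L
    for (s in specs) {
      n <- s$n_patients
      ids <- sprintf("P%05d", pid_counter + seq_len(n))
      pid_counter <- pid_counter + n
      index_date <- as.Date("2001-01-01") +
        sample.int(as.integer(as.Date("2015-09-30") - as.Date("2001-01-01")),
                   n, replace = TRUE)
      died <- stats::rbinom(n, 1, s$death_p) == 1
      pats[[length(pats) + 1L]] <- data.frame(
        patient_id = ids, archetype = s$label, index_date = index_date,
        age = round(stats::rnorm(n, 48, 14)),
        sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.9, 0.1)),
        n_bd_codes = 2L + stats::rpois(n, 2),
        months_pre = 12L + stats::rpois(n, 36),
        months_post = 12L + stats::rpois(n, 36),
        death_date = as.Date(ifelse(died, index_date + sample.int(365, n,
                                                                  TRUE),
                                    NA), origin = "1970-01-01"))
      labels <- c(labels, stats::setNames(rep(s$label, n), ids))

      if (include_events) {
        weeks <- if (s$profile == "none") integer() else s$onset_week:0L
        wt <- .profile_weight(s, weeks)
        pe <- .draw_archetype_events(ids, s, weeks, wt, registry)
        if (!is.null(pe)) evs[[length(evs) + 1L]] <- pe
        # every patient gets the index-week diagnosis event
        evs[[length(evs) + 1L]] <- data.frame(
          patient_id = ids, week_offset = 0L, code = "296.4",
          value = NA_real_, duration_weeks = NA_integer_,
          note_text = NA_character_)
      }

      nh <- stats::rnbinom(n, mu = s$hosp_mu, size = s$hosp_size)
      los <- vapply(nh, function(h) {
        if (h == 0) 0 else sum(stats::rlnorm(h, s$los_meanlog, s$los_sdlog))
      }, numeric(1))
      outs[[length(outs) + 1L]] <- data.frame(
        patient_id = ids, died_within_1y = died, hospitalizations_1y = nh,
        total_los_days_1y = round(los, 1),
        psychosis_1y = stats::rbinom(n, 1, s$psychosis_p) == 1,
        mental_illness_hospitalizations_1y =
          stats::rbinom(n, nh, s$mental_share))
    }
    structure(list(
      patients = do.call(rbind, pats),
      events = if (include_events) do.call(rbind, evs) else NULL,
      outcomes = do.call(rbind, outs),
      true_labels = labels, seed = as.integer(seed), specs = specs),
      class = "SyntheticCohort")
  })
}

## Vectorized event draw for one archetype across all its patients.  Draw
## order is fixed (presence cube, then graded values, then admissions), so
## the stream is reproducible under the cohort seed.
.draw_archetype_events <- function(ids, spec, weeks, wt, registry) {
  n <- length(ids)
  ft <- registry@features
  rows <- spec$active_rows
  W <- length(weeks); R <- length(rows)
  out <- list()
  if (R && W) {
    p <- array(wt * spec$amplitude * spec$event_prob, dim = c(W, R, n))
    hit <- which(array(stats::runif(length(p)) < p, dim(p)), arr.ind = TRUE)
    if (nrow(hit)) {
      rw <- rows[hit[, 2]]
      wk <- weeks[hit[, 1]]
      pid <- ids[hit[, 3]]
      codes <- vapply(rows, function(r) representativeCode(registry, r),
                      character(1))[hit[, 2]]
      idx <- match(rw, ft$row)
      graded <- ft$kind[idx] == "graded"
      val <- rep(NA_real_, length(rw))
      if (any(graded)) {
        # labs: 1-3 SD deviations either side of the population mean;
        # vitals: uniform between the upper normal edge and extreme bound
        sgn <- sample(c(-1, 1), sum(graded), replace = TRUE)
        mag <- stats::runif(sum(graded), 1, 3)
        u <- stats::runif(sum(graded))
        gi <- which(graded)
        for (r in unique(rw[gi])) {
          m <- ft$meta[[match(r, ft$row)]]
          sel <- which(rw[gi] == r)
          val[gi[sel]] <- if (!is.null(m$mean)) {
            m$mean + sgn[sel] * mag[sel] * m$sd
          } else {
            m$hi_n + u[sel] * (m$hi_e - m$hi_n)
          }
        }
      }
      out[[1]] <- data.frame(
        patient_id = pid, week_offset = wk, code = codes, value = val,
        duration_weeks = NA_integer_, note_text = NA_character_)
    }
  }
  if (spec$admit_prob > 0 && W) {
    pa <- matrix(spec$admit_prob * wt, W, n)
    hit <- which(matrix(stats::runif(length(pa)) < pa, W), arr.ind = TRUE)
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = ids[hit[, 2]], week_offset = weeks[hit[, 1]],
        code = "hosp", value = NA_real_,
        duration_weeks = sample(1:2, nrow(hit), replace = TRUE),
        note_text = NA_character_)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort: ", nrow(x$patients), " patients, ",
      length(x$specs), " archetypes, seed ", x$seed, "\n", sep = "")
  if (!is.null(x$events)) cat("  events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Apply the cohort eligibility filters
#'
#' Retains patients with (1) at least \code{bd_code_min} bipolar-disorder
#' diagnosis codes, (2) at least \code{pre_months} months of healthcare-system
#' presence before the index date and (3) at least \code{post_months} months
#' after it.  Exclusions are attributed to the first failed criterion in that
#' order.
#'
#' @param patients Patients data frame with columns \code{n_bd_codes},
#'   \code{months_pre}, \code{months_post} (a \code{SyntheticCohort} is also
#'   accepted).
#' @param bd_code_min Minimum number of diagnosis codes (default 2).
#' @param pre_months,post_months Minimum months of presence (default 12).
#' @return A list with \code{patients} (retained rows), \code{excluded}
#'   (patient_id, reason) and \code{counts} (named exclusion tally).
#' @export
eligibilityFilter <- function(patients, bd_code_min = 2L, pre_months = 12L,
                              post_months = 12L) {
  if (inherits(patients, "SyntheticCohort")) patients <- patients$patients
  need <- c("patient_id", "n_bd_codes", "months_pre", "months_post")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("patients table missing column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(patients))
  reason[is.na(reason) & patients$n_bd_codes < bd_code_min] <-
    "insufficient BD codes"
  reason[is.na(reason) & patients$months_pre < pre_months] <-
    "insufficient pre-index presence"
  reason[is.na(reason) & patients$months_post < post_months] <-
    "insufficient post-index presence"
  keep <- is.na(reason)
  counts <- c(retained = sum(keep),
    `insufficient BD codes` = sum(reason == "insufficient BD codes",
                                  na.rm = TRUE),
    `insufficient pre-index presence` =
      sum(reason == "insufficient pre-index presence", na.rm = TRUE),
    `insufficient post-index presence` =
      sum(reason == "insufficient post-index presence", na.rm = TRUE))
  list(patients = patients[keep, , drop = FALSE],
       excluded = data.frame(patient_id = patients$patient_id[!keep],
                             reason = reason[!keep]),
       counts = counts)
}
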