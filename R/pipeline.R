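## Delimited-text I/O for the pipeline tables and images, plus the end-to-end
## orchestrator with a reproducibility manifest.

#' Read and write pipeline tables
#'
#' Plain CSV readers/writers for the three input tables (patients, events,
#' one-year outcomes) with column validation.  Dates are ISO-8601.
#'
#' @param path File path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
readEvents <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(ev) || !"code" %in% names(ev))
    stop("events table needs patient_id and code columns")
  if (!any(c("week_offset", "event_date") %in% names(ev)))
    stop("events table needs week_offset or event_date")
  if ("event_date" %in% names(ev)) ev$event_date <- as.Date(ev$event_date)
  ev
}

#' @rdname pipeline-io
#' @export
readPatients <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(p))
    stop("patients table needs a patient_id column")
  for (col in intersect(c("index_date", "death_date"), names(p)))
    p[[col]] <- as.Date(p[[col]])
  p
}

#' @rdname pipeline-io
#' @export
readOutcomeRecords <- function(path) {
  .validate_outcomes(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Persist a TemporalImageSet as delimited text
#'
#' Nonzero pixels go to a long-format CSV (\code{patient_id},
#' \code{feature_row}, \code{week}, \code{value}); the image geometry and
#' patient roster go to a YAML sidecar (\code{<path>.meta.yaml}), so the pair
#' round-trips exactly through \code{\link{readImages}}.
#'
#' @param x A \code{\linkS4class{TemporalImageSet}}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
writeImages <- function(x, path) {
  md <- metadata(x)
  px <- assay(x, "pixels")
  nz <- which(px != 0, arr.ind = TRUE)
  rd <- rowData(x)
  long <- data.frame(patient_id = colnames(x)[nz[, 2]],
                     feature_row = rd$feature_row[nz[, 1]],
                     week = rd$week[nz[, 1]],
                     value = px[nz])
  long <- long[order(long$patient_id, long$feature_row, long$week), ]
  utils::write.csv(long, path, row.names = FALSE)
  yaml::write_yaml(list(n_features = md$nFeatures,
                        weeks = as.integer(md$weeks),
                        blurred = isTRUE(md$blurred),
                        patient_ids = colnames(x)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeImages
#' @param registry Optional registry to attach on read.
#' @export
readImages <- function(path, registry = NULL) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  f <- meta$n_features; weeks <- as.integer(meta$weeks)
  ids <- as.character(meta$patient_ids)
  arr <- array(0, dim = c(f, length(weeks), length(ids)),
               dimnames = list(NULL, NULL, ids))
  arr[cbind(long$feature_row, match(long$week, weeks),
            match(long$patient_id, ids))] <- long$value
  TemporalImageSet(arr, registry = registry, weeks = weeks,
                   blurred = isTRUE(meta$blurred))
}

.write_fingerprints <- function(fps, path) {
  long <- do.call(rbind, lapply(fps, function(fp) {
    m <- fp@meanImage
    data.frame(cluster = fp@clusterLabel, n_patients = fp@nPatients,
               feature_row = rep(seq_len(nrow(m)), times = ncol(m)),
               week = rep(as.integer(colnames(m)), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.csv(long[long$value != 0, ], path, row.names = FALSE)
  invisible(path)
}

#' Run the full fingerprinting pipeline
#'
#' Orchestrates: simulate (or load) -> eligibility filter -> encode -> blur
#' -> optional SSE scan with elbow suggestion -> K-means at \code{k} ->
#' relabel by image mass -> fingerprints -> outcome comparison.  All
#' artifacts are written as delimited text under \code{outdir} together with
#' a manifest (config, seed, per-stage counts, MD5 checksums).  Rerunning
#' with an identical config reproduces identical files.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{integer, required; fanned out to stages by fixed offsets.}
#'     \item{outdir}{output directory, required.}
#'     \item{simulate}{list with \code{n_per} (patients per default
#'       archetype) to generate a synthetic cohort, or \code{NULL} to load
#'       \code{patients}/\code{events}/\code{outcomes} CSV paths.}
#'     \item{patients, events, outcomes}{input CSV paths (when not
#'       simulating).}
#'     \item{registry}{optional registry YAML path (default built-in 84-row
#'       schema).}
#'     \item{weeks_pre}{pre-index weeks, default 52.}
#'     \item{blur}{list \code{half_window}, \code{decay}, defaults 10/10.}
#'     \item{k}{cluster count, default 8.}
#'     \item{k_range}{optional \code{c(kmin, kmax)} to run an SSE scan.}
#'     \item{restarts}{K-means restarts, default 10.}
#'     \item{reference}{reference cluster label, default 1 (after mass
#'       relabelling).}
#'   }
#' @return The manifest, invisibly (also written as
#'   \code{manifest.yaml}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed), !is.null(config$outdir))
  seed <- as.integer(config$seed)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  weeks_pre <- if (is.null(config$weeks_pre)) 52L
               else as.integer(config$weeks_pre)
  blur_hw <- if (is.null(config$blur$half_window)) 10L
             else as.integer(config$blur$half_window)
  blur_decay <- if (is.null(config$blur$decay)) 10 else config$blur$decay
  k <- if (is.null(config$k)) 8L else as.integer(config$k)
  restarts <- if (is.null(config$restarts)) 10L
              else as.integer(config$restarts)
  registry <- if (is.null(config$registry)) defaultRegistry()
              else loadRegistry(config$registry)

  ## stage 1: cohort
  if (!is.null(config$simulate)) {
    n_per <- if (is.null(config$simulate$n_per)) 100L
             else as.integer(config$simulate$n_per)
    cohort <- generateCohort(defaultArchetypes(n_per), seed = seed + 1L,
                             registry = registry)
    patients <- cohort$patients; events <- cohort$events
    outcomes <- cohort$outcomes
    utils::write.csv(data.frame(patient_id = names(cohort$true_labels),
                                archetype = cohort$true_labels),
                     file.path(outdir, "true_labels.csv"), row.names = FALSE)
  } else {
    patients <- readPatients(config$patients)
    events <- readEvents(config$events)
    outcomes <- readOutcomeRecords(config$outcomes)
  }
  utils::write.csv(patients, file.path(outdir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(events, file.path(outdir, "events.csv"), row.names = FALSE)
  utils::write.csv(outcomes, file.path(outdir, "outcomes.csv"),
                   row.names = FALSE)

  ## stage 2: eligibility
  elig <- if (all(c("n_bd_codes", "months_pre", "months_post") %in%
                  names(patients))) {
    eligibilityFilter(patients)
  } else list(patients = patients, excluded = NULL,
              counts = c(retained = nrow(patients)))
  patients <- elig$patients
  events <- events[events$patient_id %in% patients$patient_id, , drop = FALSE]
  outcomes <- outcomes[outcomes$patient_id %in% patients$patient_id, ,
                       drop = FALSE]

  ## stage 3: encode
  standardizers <- fitStandardizers(events, registry)
  images <- encodeCohort(events, patients = patients, registry = registry,
                         standardizers = standardizers,
                         weeks_pre = weeks_pre)
  writeImages(images, file.path(outdir, "images.csv"))

  ## stage 4: blur
  blurred <- blurImages(images, half_window = blur_hw, decay = blur_decay)
  writeImages(blurred, file.path(outdir, "images_blurred.csv"))

  ## stage 5: optional SSE scan
  elbow <- NULL
  if (!is.null(config$k_range)) {
    kr <- as.integer(config$k_range)
    curve <- sseScan(blurred, k_min = kr[1], k_max = kr[2],
                     seed = seed + 100L, nRestarts = restarts)
    utils::write.csv(curve, file.path(outdir, "sse_curve.csv"),
                     row.names = FALSE)
    elbow <- tryCatch(suggestElbow(curve), warning = function(w) {
      message("elbow suggestion: ", conditionMessage(w)); NULL
    })
  }

  ## stage 6: cluster + relabel
  model <- kmeansFit(blurred, k = k, seed = seed + 200L,
                     nRestarts = restarts)
  model <- relabelByMass(model, blurred)
  utils::write.csv(data.frame(patient_id = names(model@assignments),
                              cluster = model@assignments),
                   file.path(outdir, "assignments.csv"), row.names = FALSE)

  ## stage 7: fingerprints (original images)
  fps <- fingerprints(images, model)
  .write_fingerprints(fps, file.path(outdir, "fingerprints.csv"))

  ## stage 8: outcomes
  cmp <- compareClusters(outcomes, model,
                         reference = config$reference)
  utils::write.csv(cmp$summary, file.path(outdir, "outcome_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$asd, file.path(outdir, "outcome_asd.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$tests, file.path(outdir, "outcome_tests.csv"),
                   row.names = FALSE)

  files <- sort(setdiff(list.files(outdir), "manifest.yaml"))
  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "outdir")],
    counts = list(patients = nrow(patients), events = nrow(events),
                  images = ncol(images), blurred_images = ncol(blurred),
                  clusters = model@k, fingerprints = length(fps),
                  eligibility = as.list(elig$counts)),
    sse = list(k = k, value = model@sse),
    elbow = if (!is.null(elbow)) as.integer(elbow),
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
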