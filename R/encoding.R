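## Temporal encoding: event records -> per-patient temporal images
## (features x weeks matrices in [0,1]) collected in a TemporalImageSet.

#' Signed week bin of an event relative to the index date
#'
#' Day differences are binned into whole weeks toward zero, so days 0..-6
#' before the index share week 0 with the index itself, days -7..-13 are week
#' -1, and an event exactly 350 days before the index is week -50.  Events
#' outside the analysis window (-\code{weeks_pre}..0 by default) are the
#' caller's responsibility to drop.
#'
#' @param event_date,index_date \code{Date} vectors (recycled).
#' @return Integer week offsets (0 = index week, negative = before).
#' @examples
#' weekOffset(as.Date("2010-06-27"), as.Date("2010-06-30"))  # 0
#' weekOffset(as.Date("2010-06-30") - 350, as.Date("2010-06-30"))  # -50
#' @export
weekOffset <- function(event_date, index_date) {
  d <- as.numeric(difftime(as.Date(event_date), as.Date(index_date),
                           units = "days"))
  as.integer(trunc(d / 7))
}

#' Construct a TemporalImageSet from per-patient matrices
#'
#' @param images Named list of F x W numeric matrices (one per patient, equal
#'   dimensions, values in [0,1]) or a 3-d array F x W x N with patient names
#'   on the third dimension.
#' @param registry Optional \code{\linkS4class{FeatureRegistry}} giving row
#'   names.
#' @param weeks Integer vector of week offsets labelling the columns; default
#'   \code{-(W-1)..0}.
#' @param colData Optional per-patient \code{DataFrame}/\code{data.frame}.
#' @param blurred Whether the images have already been temporally blurred.
#' @return A \code{\linkS4class{TemporalImageSet}}.
#' @export
TemporalImageSet <- function(images, registry = NULL, weeks = NULL,
                             colData = NULL, blurred = FALSE) {
  if (is.array(images) && length(dim(images)) == 3) {
    nm <- dimnames(images)[[3]]
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
    names(images) <- nm
  }
  stopifnot(length(images) > 0, !is.null(names(images)))
  dims <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), dims), logical(1))))
    stop("all images must have identical dimensions")
  f <- dims[1]; w <- dims[2]
  if (is.null(weeks)) weeks <- seq.int(-(w - 1L), 0L)
  stopifnot(length(weeks) == w)
  px <- vapply(images, as.vector, numeric(f * w))
  rd <- S4Vectors::DataFrame(feature_row = rep(seq_len(f), times = w),
                             week = rep(as.integer(weeks), each = f))
  cd <- if (is.null(colData)) {
    S4Vectors::DataFrame(patient_id = names(images), row.names = names(images))
  } else {
    cd <- S4Vectors::DataFrame(colData)
    rownames(cd) <- names(images)
    cd
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pixels = px), rowData = rd, colData = cd,
    metadata = list(nFeatures = as.integer(f), weeks = as.integer(weeks),
                    blurred = isTRUE(blurred), registry = registry))
  new("TemporalImageSet", se)
}

#' @rdname defaultRegistry
#' @export
setMethod("nFeatures", "TemporalImageSet",
          function(x) metadata(x)$nFeatures)

#' Week offsets labelling the image columns
#' @param x A \code{TemporalImageSet}.
#' @return Integer vector, e.g. \code{-52..0}.
#' @export
imageWeeks <- function(x) metadata(x)$weeks

#' Whether a TemporalImageSet has been temporally blurred
#' @param x A \code{TemporalImageSet}.
#' @export
isBlurred <- function(x) isTRUE(metadata(x)$blurred)

#' Extract one patient's temporal image
#'
#' @param x A \code{\linkS4class{TemporalImageSet}}.
#' @param patient Patient id (or column index).
#' @return F x W numeric matrix with week offsets as column names.
#' @export
setMethod("patientImage", "TemporalImageSet", function(x, patient) {
  md <- metadata(x)
  m <- matrix(assay(x, "pixels")[, patient], nrow = md$nFeatures,
              dimnames = list(NULL, md$weeks))
  if (!is.null(md$registry))
    rownames(m) <- md$registry@features$name
  m
})

#' Flattened pixel matrix with patients as rows
#'
#' The representation used for clustering: one row per patient, one column
#' per (feature, week) pixel.
#'
#' @param x A \code{TemporalImageSet}.
#' @return N x (F*W) numeric matrix.
#' @export
pixelMatrix <- function(x) t(assay(x, "pixels"))

## ---- standardizers --------------------------------------------------------

#' Fit lab standardizers from cohort event values
#'
#' For each graded lab feature, fits \code{\link{fitLabStandardizer}} on all
#' event values in the cohort that resolve to that feature.  Labs with fewer
#' than \code{min_n} values (or zero variance) fall back to the registry's
#' default scoring metadata.
#'
#' @param events Events data frame (see \code{\link{encodeCohort}}).
#' @param registry A \code{FeatureRegistry}.
#' @param min_n Minimum number of values required to fit (default 10).
#' @param cap Saturation point in SD units.
#' @return Named list of \code{LabStandardizer} objects, keyed by feature
#'   name.
#' @export
fitStandardizers <- function(events, registry, min_n = 10, cap = 3) {
  ft <- registry@features
  labs <- which(ft$group == "lab")
  rows <- .resolve_rows(events$code, registry)
  out <- list()
  for (i in labs) {
    vals <- events$value[!is.na(rows) & rows == ft$row[i]]
    vals <- vals[!is.na(vals)]
    out[[ft$name[i]]] <- if (length(vals) >= min_n &&
                             stats::sd(vals) > 0) {
      fitLabStandardizer(vals, cap = cap)
    } else {
      structure(list(mean = ft$meta[[i]]$mean, sd = ft$meta[[i]]$sd,
                     cap = cap), class = "LabStandardizer")
    }
  }
  out
}

## Vectorized code -> registry row resolution (NA for unresolvable codes).
.resolve_rows <- function(codes, registry) {
  u <- unique(as.character(codes))
  map <- vapply(u, function(cd) {
    if (is.na(cd) || !nzchar(cd)) return(NA_integer_)
    r <- tryCatch(lookupFeature(registry, cd)$row,
                  phenoprint_unknown_code = function(e) NA_integer_)
    as.integer(r)
  }, integer(1))
  unname(map[match(as.character(codes), u)])
}

## ---- encoding -------------------------------------------------------------

#' Encode patient event records into temporal images
#'
#' Builds one F x W temporal image per patient.  Binary feature rows receive 1
#' in every week with at least one event; graded rows (labs, vitals) receive
#' the maximum abnormality score among same-week events; the hospitalization
#' row marks every week overlapped by an admission--discharge interval
#' (\code{duration_weeks}); events carrying \code{note_text} additionally set
#' the symptom rows matched by \code{\link{matchSymptoms}}.  Events outside
#' the window \code{-weeks_pre..0} are dropped (with a message).
#'
#' @param events Data frame with columns \code{patient_id}, \code{code}, and
#'   either \code{week_offset} (integer) or \code{event_date} (Date, requires
#'   \code{patients} with index dates); optional \code{value} (required for
#'   graded features), \code{duration_weeks} (hospitalization span, default
#'   1), and \code{note_text}.
#' @param patients Optional data frame with \code{patient_id} and
#'   \code{index_date}; defines the patient set (patients without events get
#'   all-zero images).
#' @param registry A \code{\linkS4class{FeatureRegistry}} (default
#'   \code{defaultRegistry()}).
#' @param standardizers Named list of lab standardizers (see
#'   \code{\link{fitStandardizers}}); registry defaults are used for labs not
#'   listed.
#' @param lexicon Symptom lexicon for \code{note_text} matching.
#' @param weeks_pre Number of weeks before the index week (default 52, giving
#'   53 columns \code{-52..0}).
#' @param on_unknown \code{"error"} (default) to fail on codes not owned by
#'   any registry row, or \code{"drop"} to drop them with a message.
#' @return A \code{\linkS4class{TemporalImageSet}}.
#' @examples
#' reg <- defaultRegistry()
#' ev <- data.frame(patient_id = "p1", week_offset = -50L, code = "540")
#' img <- patientImage(encodeCohort(ev, registry = reg), "p1")
#' which(img > 0)   # single pixel: row 30, week -50
#' @export
encodeCohort <- function(events, patients = NULL,
                         registry = defaultRegistry(),
                         standardizers = list(),
                         lexicon = defaultLexicon(registry),
                         weeks_pre = 52L,
                         on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  ft <- registry@features
  f <- nrow(ft); wn <- weeks_pre + 1L
  weeks <- seq.int(-weeks_pre, 0L)

  events <- as.data.frame(events)
  if (!"week_offset" %in% names(events) || all(is.na(events$week_offset))) {
    if (is.null(patients) || !"index_date" %in% names(patients))
      stop("events carry event_date; a patients table with index_date ",
           "is required")
    idx <- as.Date(patients$index_date)[match(events$patient_id,
                                              patients$patient_id)]
    events$week_offset <- weekOffset(events$event_date, idx)
  }
  ids <- if (!is.null(patients)) as.character(patients$patient_id)
         else sort(unique(as.character(events$patient_id)))

  keep <- events$week_offset >= -weeks_pre & events$week_offset <= 0L
  if (any(!keep))
    message(sum(!keep), " event(s) outside week window -", weeks_pre,
            "..0 dropped")
  events <- events[keep, , drop = FALSE]

  rows <- .resolve_rows(events$code, registry)
  has_note <- "note_text" %in% names(events)
  note_ok <- if (has_note) {
    !is.na(events$note_text) & nzchar(events$note_text, keepNA = FALSE)
  } else rep(FALSE, nrow(events))
  has_note <- any(note_ok)
  unknown <- is.na(rows) & !note_ok
  if (any(unknown)) {
    bad <- unique(events$code[unknown])
    if (on_unknown == "error")
      stop("unknown code(s): ", paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ...")
    message(sum(unknown), " event(s) with unknown codes dropped")
  }

  arr <- array(0, dim = c(f, wn, length(ids)), dimnames = list(NULL, NULL, ids))
  pidx <- match(as.character(events$patient_id), ids)
  cidx <- events$week_offset + weeks_pre + 1L
  ok <- !is.na(rows) & !is.na(pidx)

  kind <- ft$kind[match(rows, ft$row)]
  group <- ft$group[match(rows, ft$row)]

  ## hospitalization spans: expand to all overlapped weeks
  hosp <- ok & group == "hospitalization"
  if (any(hosp)) {
    dur <- if ("duration_weeks" %in% names(events)) {
      d <- events$duration_weeks[hosp]
      ifelse(is.na(d), 1L, pmax(as.integer(d), 1L))
    } else rep(1L, sum(hosp))
    hi <- which(hosp)
    for (j in seq_along(hi)) {
      e <- hi[j]
      cols <- cidx[e]:min(cidx[e] + dur[j] - 1L, wn)
      arr[cbind(rows[e], cols, pidx[e])] <- 1
    }
  }

  ## binary rows (diagnoses, procedures, symptoms-as-codes): presence
  bin <- ok & kind == "binary" & group != "hospitalization"
  if (any(bin))
    arr[cbind(rows[bin], cidx[bin], pidx[bin])] <- 1

  ## graded rows: max abnormality score among same-week events.  Duplicate
  ## (row, week, patient) writes resolve to the last one, so assign in
  ## ascending score order.
  grd <- ok & kind == "graded"
  if (any(grd)) {
    gi <- which(grd)
    if (!"value" %in% names(events) || anyNA(events$value[gi]))
      stop("graded feature events require a numeric 'value'")
    sc <- numeric(length(gi))
    for (r in unique(rows[gi])) {
      i <- match(r, ft$row)
      sel <- which(rows[gi] == r)
      sc[sel] <- if (ft$group[i] == "lab") {
        s <- standardizers[[ft$name[i]]]
        if (is.null(s)) s <- ft$meta[[i]]
        labScore(events$value[gi[sel]], s)
      } else {
        vitalScore(events$value[gi[sel]], ft$meta[[i]])
      }
    }
    ## duplicate (row, week, patient) writes resolve to the last one, so
    ## assigning in ascending score order implements max aggregation
    o <- order(sc)
    arr[cbind(rows[gi][o], cidx[gi][o], pidx[gi][o])] <- sc[o]
  }

  ## note text -> symptom rows
  if (has_note) {
    srow <- ft$row[ft$group == "symptom"]
    names(srow) <- ft$name[ft$group == "symptom"]
    ni <- which(note_ok & !is.na(pidx))
    for (e in ni) {
      grp <- matchSymptoms(events$note_text[e], lexicon)
      if (length(grp))
        arr[cbind(srow[grp], cidx[e], pidx[e])] <- 1
    }
  }

  TemporalImageSet(arr, registry = registry, weeks = weeks,
                   colData = if (!is.null(patients))
                     patients[match(ids, patients$patient_id), , drop = FALSE]
                   else NULL)
}
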