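#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Feature registry: the ordered feature schema of a temporal image
#'
#' A \code{FeatureRegistry} fixes the y-axis of every temporal image: an
#' ordered set of clinical feature definitions, each owning a row index, a
#' feature group, a value kind (\code{"binary"} presence or \code{"graded"}
#' abnormality score in [0,1]) and the source codes that map events onto the
#' row.  The default registry (\code{\link{defaultRegistry}}) has 84 rows.
#'
#' @slot features A \code{DataFrame} with columns \code{row} (integer),
#'   \code{name}, \code{group}, \code{kind} (\code{"binary"}/\code{"graded"}),
#'   and list columns \code{codes} (code patterns owned by the row) and
#'   \code{meta} (scoring metadata: lab mean/sd, vital normal and extreme
#'   bounds, symptom keywords).
#' @slot version Character version tag of the schema.
#'
#' @seealso \code{\link{defaultRegistry}}, \code{\link{loadRegistry}},
#'   \code{\link{lookupFeature}}
#' @export
setClass("FeatureRegistry",
  slots = c(features = "DataFrame", version = "character"))

.FEATURE_GROUPS <- c("hospitalization", "diagnosis_mental", "diagnosis_other",
                     "procedure_group", "lab", "vital", "symptom",
                     "medication_class")

setValidity("FeatureRegistry", function(object) {
  ft <- object@features
  need <- c("row", "name", "group", "kind", "codes", "meta")
  if (!all(need %in% colnames(ft)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(ft$row))
    msgs <- c(msgs, "duplicate row indices in registry")
  if (any(ft$row < 1))
    msgs <- c(msgs, "row indices must be positive")
  if (!all(ft$group %in% .FEATURE_GROUPS))
    msgs <- c(msgs, "unknown feature group")
  if (!all(ft$kind %in% c("binary", "graded")))
    msgs <- c(msgs, "kind must be 'binary' or 'graded'")
  bad <- ft$kind == "graded" & !(ft$group %in% c("lab", "vital"))
  if (any(bad))
    msgs <- c(msgs, "graded value kind is only allowed for lab and vital rows")
  if (anyDuplicated(tolower(ft$name)))
    msgs <- c(msgs, "duplicate feature names")
  if (length(msgs)) msgs else TRUE
})

#' Cohort of temporal images
#'
#' A \code{TemporalImageSet} holds one temporal image per patient: an
#' F-features-by-W-weeks matrix with values in [0,1], flattened column-wise
#' (feature index fastest) into the \code{"pixels"} assay of a
#' \code{SummarizedExperiment} whose columns are patients.  \code{rowData}
#' records the (feature row, week offset) of every pixel; \code{metadata}
#' records the image geometry, the registry, and whether the images have been
#' temporally blurred.
#'
#' @seealso \code{\link{encodeCohort}}, \code{\link{blurImages}},
#'   \code{\link{patientImage}}
#' @export
setClass("TemporalImageSet", contains = "SummarizedExperiment")

setValidity("TemporalImageSet", function(object) {
  md <- metadata(object)
  if (is.null(md$nFeatures) || is.null(md$weeks))
    return("metadata must contain nFeatures and weeks")
  if (!"pixels" %in% SummarizedExperiment::assayNames(object))
    return("assay 'pixels' is required")
  px <- assay(object, "pixels")
  if (nrow(px) != md$nFeatures * length(md$weeks))
    return("pixel count does not match nFeatures * nWeeks")
  rng <- range(px)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    return("pixel values must lie in [0, 1]")
  TRUE
})

#' Fitted K-means clustering of blurred temporal images
#'
#' @slot k Number of clusters.
#' @slot centroids \code{k x (F*W)} matrix of cluster centroids in flattened
#'   blurred-image space.
#' @slot assignments Named integer vector (names = patient ids) of cluster
#'   labels in \code{1..k}.
#' @slot sse Total within-cluster sum of squared Euclidean distances.
#' @slot seed,nRestarts The RNG seed and number of random restarts used.
#'
#' @seealso \code{\link{kmeansFit}}, \code{\link{sseScan}}
#' @export
setClass("ClusterModel",
  slots = c(k = "integer", centroids = "matrix", assignments = "integer",
            sse = "numeric", seed = "integer", nRestarts = "integer"))

setValidity("ClusterModel", function(object) {
  msgs <- character()
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (nrow(object@centroids) != object@k)
    msgs <- c(msgs, "centroids must have k rows")
  if (is.null(names(object@assignments)))
    msgs <- c(msgs, "assignments must be named by patient id")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    msgs <- c(msgs, "assignments must be in 1..k")
  if (object@sse < 0) msgs <- c(msgs, "sse must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Phenotype fingerprint of a cluster
#'
#' The per-cluster element-wise mean of the members' original (unblurred)
#' temporal images.
#'
#' @slot clusterLabel Integer cluster label.
#' @slot meanImage F x W numeric matrix of mean pixel values.
#' @slot nPatients Number of patients in the cluster.
#'
#' @seealso \code{\link{fingerprints}}
#' @export
setClass("Fingerprint",
  slots = c(clusterLabel = "integer", meanImage = "matrix",
            nPatients = "integer"))

setValidity("Fingerprint", function(object) {
  msgs <- character()
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
  rng <- range(object@meanImage)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    msgs <- c(msgs, "fingerprint pixels must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FeatureRegistry", function(object) {
  ft <- object@features
  cat("FeatureRegistry (version ", object@version, ") with ", nrow(ft),
      " features\n", sep = "")
  tab <- table(factor(ft$group, levels = .FEATURE_GROUPS))
  tab <- tab[tab > 0]
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "TemporalImageSet", function(object) {
  md <- metadata(object)
  cat("TemporalImageSet: ", ncol(object), " patients, ",
      md$nFeatures, " features x ", length(md$weeks), " weeks (",
      min(md$weeks), "..", max(md$weeks), ")",
      if (isTRUE(md$blurred)) ", blurred" else "", "\n", sep = "")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k = ", object@k, ", n = ", length(object@assignments),
      ", SSE = ", format(object@sse), "\n", sep = "")
  print(table(cluster = object@assignments))
})

setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint of cluster ", object@clusterLabel, " (n = ",
      object@nPatients, "), ", nrow(object@meanImage), " x ",
      ncol(object@meanImage), " mean image\n", sep = "")
})
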