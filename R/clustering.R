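## K-means clustering of blurred temporal images, SSE scan over k, elbow-area
## suggestion, and per-cluster phenotype fingerprints.

## k-means++ spreading initialization: first center uniform, each further
## center drawn with probability proportional to the squared distance to the
## nearest center chosen so far.  Duplicate points have zero pick probability
## once represented, so the k centers are distinct whenever k <= #distinct.
.kmpp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(pts, 2, pts[centers[1], ], "-")^2)
  for (c in 2:k) {
    if (all(d2 <= 0)) {
      centers[c] <- sample.int(n, 1)
    } else {
      centers[c] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[centers[c], ], "-")^2))
  }
  centers
}

.as_points <- function(x) {
  if (is(x, "TemporalImageSet")) {
    if (!isBlurred(x))
      warning("clustering an unblurred image set; apply blurImages() first ",
              "for the intended distance semantics")
    pixelMatrix(x)
  } else if (is.matrix(x)) {
    if (is.null(rownames(x)))
      rownames(x) <- paste0("p", seq_len(nrow(x)))
    x
  } else stop("x must be a TemporalImageSet or a numeric matrix")
}

#' K-means on flattened blurred images
#'
#' Euclidean-distance K-means (Lloyd iterations, \code{nRestarts} seeded
#' random restarts, best restart by SSE) on the row-major flattened pixel
#' vectors.  Deterministic given (data, k, seed, nRestarts).
#'
#' @param x A blurred \code{\linkS4class{TemporalImageSet}}, or an N x D
#'   matrix with one row per patient.
#' @param k Number of clusters (\code{1 <= k <=} number of distinct points).
#' @param seed Integer RNG seed.
#' @param nRestarts Number of independent random restarts (default 10).
#' @param iter_max Maximum Lloyd iterations per restart (default 300).
#' @return A \code{\linkS4class{ClusterModel}}.
#' @export
kmeansFit <- function(x, k, seed = 1L, nRestarts = 10L, iter_max = 300L) {
  pts <- .as_points(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  ndistinct <- nrow(unique(pts))
  if (k > ndistinct)
    stop("infeasible k: ", k, " clusters requested but only ", ndistinct,
         " distinct points")
  ## When D >> N, rotate onto an orthonormal basis of the point cloud first:
  ## Euclidean distances, SSE and the restart semantics are all preserved
  ## exactly, and Lloyd iterations run on N coordinates instead of D.
  basis <- NULL
  if (ncol(pts) > nrow(pts)) {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr), nu = 0)
    keep <- sv$d > max(sv$d[1], 1) * 1e-12
    basis <- list(V = sv$v[, keep, drop = FALSE], center = ctr)
    full <- pts
    pts <- sweep(full, 2, ctr) %*% basis$V
    rownames(pts) <- rownames(full)
  }
  km <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      init <- .kmpp_init(pts, k)
      res <- tryCatch(
        withCallingHandlers(
          stats::kmeans(pts, centers = pts[init, , drop = FALSE],
                        iter.max = iter_max, algorithm = "Lloyd"),
          warning = function(w) {
            if (grepl("empty cluster|did not converge", conditionMessage(w)))
              invokeRestart("muffleWarning")
          }),
        error = function(e) NULL)
      if (!is.null(res) &&
          (is.null(best) || res$tot.withinss < best$tot.withinss))
        best <- res
    }
    if (is.null(best)) stop("k-means failed in all ", nRestarts, " restarts")
    best
  })
  asg <- as.integer(km$cluster)
  names(asg) <- rownames(pts)
  centers <- km$centers
  if (!is.null(basis))
    centers <- sweep(centers %*% t(basis$V), 2, basis$center, "+")
  new("ClusterModel", k = k, centroids = unname(centers),
      assignments = asg, sse = km$tot.withinss, seed = as.integer(seed),
      nRestarts = as.integer(nRestarts))
}

#' @rdname kmeansFit
#' @param model A \code{ClusterModel}.
#' @export
clusterAssignments <- function(model) model@assignments

#' @rdname kmeansFit
#' @export
clusterSSE <- function(model) model@sse

#' Relabel clusters by ascending mean image mass
#'
#' K-means labels are arbitrary; this fixes a deterministic convention in
#' which cluster 1 has the smallest mean total pixel mass (i.e. the least
#' prodromal burden), making it the natural reference group for outcome
#' comparisons.
#'
#' @param model A \code{\linkS4class{ClusterModel}} fit on \code{x}.
#' @param x The image set (or point matrix) the model was fit on.
#' @return A relabelled \code{ClusterModel}.
#' @export
relabelByMass <- function(model, x) {
  pts <- .as_points(x)
  mass <- vapply(seq_len(model@k), function(c) {
    mean(rowSums(pts[model@assignments == c, , drop = FALSE]))
  }, numeric(1))
  ord <- order(mass)                 # ord[new] = old
  remap <- integer(model@k); remap[ord] <- seq_len(model@k)
  asg <- remap[model@assignments]
  names(asg) <- names(model@assignments)
  new("ClusterModel", k = model@k,
      centroids = model@centroids[ord, , drop = FALSE],
      assignments = asg, sse = model@sse, seed = model@seed,
      nRestarts = model@nRestarts)
}

#' SSE scan over a range of cluster counts
#'
#' Runs one independent \code{\link{kmeansFit}} per k (seed policy:
#' \code{seed + k}, so each k is individually reproducible and
#' \code{sseScan} at k matches \code{kmeansFit} with seed \code{seed + k}).
#'
#' @param x Blurred image set or point matrix.
#' @param k_min,k_max Inclusive k range (defaults 2 and 20).
#' @param seed Base RNG seed.
#' @param nRestarts Restarts per fit.
#' @return A \code{data.frame} with columns \code{k} and \code{sse}.
#' @export
sseScan <- function(x, k_min = 2L, k_max = 20L, seed = 1L, nRestarts = 10L) {
  pts <- .as_points(x)
  if (k_max > nrow(pts)) stop("k_max exceeds the number of patients")
  ks <- seq.int(k_min, k_max)
  sse <- vapply(ks, function(k) {
    kmeansFit(pts, k, seed = seed + k, nRestarts = nRestarts)@sse
  }, numeric(1))
  data.frame(k = ks, sse = sse)
}

#' Suggest the elbow area of an SSE curve
#'
#' Locates the k with maximum discrete curvature (second difference) of the
#' SSE curve and returns the bracketing range \code{c(k-1, k+1)} (clipped to
#' the scanned range).  Advisory only: the final choice of k is the
#' analyst's, guided by clinical interpretability.  A flat or strictly linear
#' curve has no elbow; the full range is returned with a warning.
#'
#' @param curve A data frame with columns \code{k} and \code{sse} (at least 4
#'   points, k strictly increasing), as returned by \code{\link{sseScan}}.
#' @return Integer vector \code{c(k_low, k_high)}.
#' @export
suggestElbow <- function(curve) {
  stopifnot(all(c("k", "sse") %in% names(curve)))
  k <- curve$k; sse <- curve$sse
  if (length(k) < 4) stop("need at least 4 curve points")
  if (any(diff(k) <= 0)) stop("k must be strictly increasing")
  d2 <- sse[-c(length(sse) - 1, length(sse))] -
    2 * sse[-c(1, length(sse))] + sse[-c(1, 2)]
  scale <- max(abs(sse), 1)
  if (max(d2) <= 1e-8 * scale) {
    warning("SSE curve has no discernible elbow; returning the full range")
    return(c(min(k), max(k)))
  }
  kstar <- k[-c(1, length(k))][which.max(d2)]
  c(max(min(k), kstar - 1L), min(max(k), kstar + 1L))
}

#' Phenotype fingerprints: per-cluster mean temporal images
#'
#' The fingerprint of a cluster is the elementwise mean of its members'
#' \emph{original} (unblurred) temporal images.  Empty clusters are excluded
#' with a warning.
#'
#' @param x The original \code{\linkS4class{TemporalImageSet}} (not the
#'   blurred set).
#' @param model A \code{\linkS4class{ClusterModel}} or a named integer vector
#'   of cluster assignments covering all patients in \code{x}.
#' @return A list of \code{\linkS4class{Fingerprint}} objects, one per
#'   non-empty cluster, in label order.
#' @export
fingerprints <- function(x, model) {
  asg <- if (is(model, "ClusterModel")) model@assignments else model
  ids <- colnames(x)
  if (!all(ids %in% names(asg)))
    stop("assignments must cover every patient in the image set")
  asg <- asg[ids]
  md <- metadata(x)
  px <- assay(x, "pixels")
  labels <- sort(unique(asg))
  k <- if (is(model, "ClusterModel")) model@k else max(asg)
  if (length(labels) < k)
    warning("empty cluster(s) excluded: ",
            paste(setdiff(seq_len(k), labels), collapse = ", "))
  lapply(labels, function(c) {
    cols <- which(asg == c)
    m <- matrix(rowMeans(px[, cols, drop = FALSE]), nrow = md$nFeatures,
                dimnames = list(NULL, md$weeks))
    if (!is.null(md$registry)) rownames(m) <- md$registry@features$name
    new("Fingerprint", clusterLabel = as.integer(c), meanImage = m,
        nPatients = length(cols))
  })
}

#' Plot a fingerprint (or any temporal image) as a grayscale heat map
#'
#' @param m A \code{\linkS4class{Fingerprint}}, or an F x W matrix in [0,1].
#' @param main Plot title.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @return Invisibly, the plotted matrix.
#' @export
plotFingerprint <- function(m, main = NULL, ...) {
  if (is(m, "Fingerprint")) {
    if (is.null(main))
      main <- paste0("Cluster ", m@clusterLabel, " (n = ", m@nPatients, ")")
    m <- m@meanImage
  }
  wk <- suppressWarnings(as.integer(colnames(m)))
  if (anyNA(wk)) wk <- seq_len(ncol(m)) - ncol(m)
  graphics::image(x = wk, y = seq_len(nrow(m)), z = t(m[nrow(m):1, ]),
                  col = grDevices::gray(seq(1, 0, length.out = 256)),
                  xlab = "week relative to index", ylab = "feature row",
                  main = main, useRaster = TRUE, ...)
  invisible(m)
}
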