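## Temporal blurring: the max-Gaussian smoothing operator applied along the
## time axis before Euclidean distances are computed.  For an image A,
##
##   B(i, j) = max_{j-h <= k <= j+h} A(i, k) * exp(-(k - j)^2 / decay)
##
## with h = 10 and decay = 10 by default.  The window is truncated at the
## matrix edges (no padding), so B >= A always holds via the k = j term.

#' Temporal blurring of a single image matrix
#'
#' Each output pixel is the maximum, over time offsets within
#' \code{half_window} columns, of the input pixel attenuated by a Gaussian
#' factor \code{exp(-offset^2 / decay)}.  Rows (features) are independent;
#' only the time axis is blurred.  The output dominates the input elementwise
#' and stays in [0,1] whenever the input does.
#'
#' @param A Numeric matrix (features x weeks).
#' @param half_window Window half-width in weeks (default 10).
#' @param decay Gaussian decay constant (default 10); the attenuation one
#'   column away is \code{exp(-1/10)} and ten columns away \code{exp(-10)}.
#' @return Matrix of the same dimensions as \code{A}.
#' @examples
#' A <- matrix(0, 1, 53); A[1, 27] <- 1
#' B <- temporalBlur(A)
#' B[1, 27]      # 1
#' B[1, 28]      # exp(-1/10)
#' B[1, 38]      # 0: beyond the +-10 window
#' @export
temporalBlur <- function(A, half_window = 10L, decay = 10) {
  stopifnot(is.matrix(A), all(is.finite(A)), half_window >= 0, decay > 0)
  W <- ncol(A)
  B <- A
  for (d in seq_len(min(half_window, W - 1L))) {
    wgt <- exp(-d^2 / decay)
    left <- seq_len(W - d)
    right <- left + d
    B[, right] <- pmax(B[, right, drop = FALSE], A[, left, drop = FALSE] * wgt)
    B[, left] <- pmax(B[, left, drop = FALSE], A[, right, drop = FALSE] * wgt)
  }
  B
}

#' Brute-force reference implementation of temporal blurring
#'
#' Explicit triple loop over (row, column, window offset); identical contract
#' to \code{\link{temporalBlur}}.  Intended for validation in tests, not for
#' production use.
#'
#' @inheritParams temporalBlur
#' @return Matrix of the same dimensions as \code{A}.
#' @export
blurOracle <- function(A, half_window = 10L, decay = 10) {
  F <- nrow(A); W <- ncol(A)
  B <- matrix(0, F, W)
  for (i in seq_len(F)) {
    for (j in seq_len(W)) {
      best <- 0
      for (k in max(1L, j - half_window):min(W, j + half_window)) {
        v <- A[i, k] * exp(-(k - j)^2 / decay)
        if (v > best) best <- v
      }
      B[i, j] <- best
    }
  }
  B
}

#' Temporal blurring of a whole image set
#'
#' Applies \code{\link{temporalBlur}} to every patient image.  Implemented on
#' the stacked pixel matrix: because pixels are flattened feature-fastest, a
#' shift of one week is a shift of \code{nFeatures} rows, so all patients are
#' blurred simultaneously.
#'
#' @param x A \code{\linkS4class{TemporalImageSet}} (unblurred).
#' @param half_window,decay See \code{\link{temporalBlur}}.
#' @return A \code{TemporalImageSet} with \code{isBlurred(x)} \code{TRUE}.
#' @export
setMethod("blurImages", "TemporalImageSet",
          function(x, half_window = 10L, decay = 10) {
  if (isBlurred(x))
    warning("image set is already blurred; blurring again")
  md <- metadata(x)
  f <- md$nFeatures
  W <- length(md$weeks)
  P <- assay(x, "pixels")
  B <- P
  for (d in seq_len(min(half_window, W - 1L))) {
    wgt <- exp(-d^2 / decay)
    off <- d * f
    n <- f * W
    B[(off + 1):n, ] <- pmax(B[(off + 1):n, , drop = FALSE],
                             P[1:(n - off), , drop = FALSE] * wgt)
    B[1:(n - off), ] <- pmax(B[1:(n - off), , drop = FALSE],
                             P[(off + 1):n, , drop = FALSE] * wgt)
  }
  out <- x
  SummarizedExperiment::assay(out, "pixels") <- B
  metadata(out)$blurred <- TRUE
  out
})
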