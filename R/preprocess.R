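#' Gaussian-smooth every trace of a recording
#'
#' Convolves each neuron's trace with a unit-area discrete Gaussian kernel of
#' standard deviation \code{sigmaFrames}, truncated at 4 sigma, with reflect
#' padding at the boundaries (affects at most ~3 sigma frames at each end).
#' The default sigma of 1 frame is orders of magnitude below typical calcium
#' trace autocorrelation times, so the smoothing removes shot noise without
#' distorting dynamics.
#'
#' @param rec a \linkS4class{Recording}.
#' @param sigmaFrames kernel SD in frames (> 0); default 1.
#' @return a smoothed \linkS4class{Recording} of identical shape.
#' @examples
#' rec <- Recording(matrix(rnorm(300), 100, 3))
#' sm <- gaussianSmooth(rec)
#' @export
gaussianSmooth <- function(rec, sigmaFrames = 1) {
  stopifnot(is(rec, "Recording"), sigmaFrames > 0)
  x <- activity(rec)
  n <- nrow(x)
  if (n < 3) stop("gaussianSmooth needs at least 3 frames")
  half <- max(1L, ceiling(4 * sigmaFrames))
  k <- stats::dnorm(seq(-half, half), sd = sigmaFrames)
  k <- k / sum(k)
  idx <- c(pmin(n, pmax(1, rev(seq_len(half) + 1))),  # reflect left
           seq_len(n),
           pmin(n, pmax(1, n - seq_len(half))))       # reflect right
  sm <- apply(x[idx, , drop = FALSE], 2, function(col)
    stats::filter(col, k, sides = 2))
  sm <- sm[(half + 1):(half + n), , drop = FALSE]
  .replaceActivity(rec, sm)
}

#' Z-score every trace of a recording
#'
#' Transforms each neuron's trace to mean 0 and (sample) SD 1.
#'
#' @param rec a \linkS4class{Recording}.
#' @return a z-scored \linkS4class{Recording}.
#' @examples
#' zs <- zscore(Recording(matrix(rnorm(60, 5, 2), 30, 2)))
#' round(colMeans(activity(zs)), 10)
#' @export
zscore <- function(rec) {
  stopifnot(is(rec, "Recording"))
  x <- activity(rec)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance neuron(s): ",
         paste(neuronNames(rec)[sds == 0], collapse = ", "))
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  .replaceActivity(rec, z)
}

#' Time derivative of every trace
#'
#' Central finite difference \code{(x[t+1] - x[t-1]) / 2} in the interior,
#' one-sided differences at the boundaries; units are activity per frame.
#'
#' @param rec a \linkS4class{Recording} with at least 3 frames.
#' @param method \code{"central"} (default) or \code{"forward"}.
#' @return a \linkS4class{Recording} of derivatives, same shape.
#' @examples
#' d <- derivative(Recording(matrix(seq_len(20), 10, 2)))
#' @export
derivative <- function(rec, method = c("central", "forward")) {
  stopifnot(is(rec, "Recording"))
  method <- match.arg(method)
  x <- activity(rec)
  n <- nrow(x)
  if (n < 3) stop("derivative needs at least 3 frames")
  d <- matrix(0, n, ncol(x))
  if (method == "central") {
    d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / 2
    d[1, ] <- x[2, ] - x[1, ]
    d[n, ] <- x[n, ] - x[n - 1, ]
  } else {
    d[1:(n - 1), ] <- x[2:n, , drop = FALSE] - x[1:(n - 1), , drop = FALSE]
    d[n, ] <- d[n - 1, ]
  }
  .replaceActivity(rec, d)
}

#' Standard preprocessing chain
#'
#' Smooth, then z-score, then differentiate the z-scored signal. Returns both
#' the z-scored activity and its derivative, the two inputs of
#' \code{\link{delayEmbed}}.
#'
#' @param rec a \linkS4class{Recording}.
#' @param sigmaFrames Gaussian smoothing SD in frames.
#' @return list with elements \code{activity} and \code{deriv}, both
#'   \linkS4class{Recording}s.
#' @export
preprocessRecording <- function(rec, sigmaFrames = 1) {
  z <- zscore(gaussianSmooth(rec, sigmaFrames))
  list(activity = z, deriv = derivative(z))
}

# swap in a new activity matrix, keeping names / behavior / metadata
.replaceActivity <- function(rec, m) {
  m <- as.matrix(m)
  Recording(m, neuronNames = neuronNames(rec), frameRate = frameRate(rec),
            behavior = behaviorLabels(rec), animalId = animalId(rec))
}
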