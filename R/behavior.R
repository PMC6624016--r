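#' Warp one behavior instance to normalized behavioral phase
#'
#' Converts raw time to behavioral phase
#' \eqn{\phi_b = (t - t_{start})/(t_{end} - t_{start})}, resamples the trace
#' at 100 equally spaced phases by linear interpolation, and subtracts the
#' instance mean (so inter-individual comparisons reflect temporal pattern,
#' not overall level).
#'
#' @param trace numeric trace of one neuron over the whole recording.
#' @param tStart,tEnd first and last frame (1-based, inclusive) of the
#'   behavior instance; must span at least 2 frames.
#' @param nPhase number of phase samples (default 100).
#' @return numeric vector of length \code{nPhase}, mean 0.
#' @examples
#' w <- phaseWarp(sin(seq(0, pi, length.out = 60)), 10, 50)
#' round(mean(w), 12)
#' @export
phaseWarp <- function(trace, tStart, tEnd, nPhase = 100L) {
  if (tEnd <= tStart) stop("tEnd must exceed tStart")
  if (tEnd - tStart + 1 < 2) stop("behavior instance shorter than 2 frames")
  seg <- trace[tStart:tEnd]
  phi <- seq(0, 1, length.out = length(seg))
  v <- stats::approx(phi, seg, xout = seq(0, 1, length.out = nPhase))$y
  v - mean(v)
}

#' Inter-individual consistency test of warped trajectories
#'
#' Stacks phase-warped instances into an n x 100 matrix, projects onto the
#' first principal axis (removing the strong phase-to-phase correlations),
#' and runs a one-way ANOVA of the PC1 scores across animals. A small
#' p-value indicates that the neuron's activation pattern during the
#' behavior differs consistently between individuals. Callers testing many
#' neuron/behavior combinations should Bonferroni-correct (alpha = 0.05).
#'
#' @param warped matrix (instances x phases) of \code{\link{phaseWarp}}
#'   outputs, or a list of such vectors.
#' @param animalIds factor/character of the source animal per instance.
#' @return list with \code{p.value}, the PC1 \code{scores}, and
#'   \code{degenerate} (TRUE when within-group variance is zero and the
#'   ANOVA is undefined; p is then NA).
#' @export
consistencyTest <- function(warped, animalIds) {
  if (is.list(warped)) warped <- do.call(rbind, warped)
  animalIds <- as.factor(animalIds)
  if (nlevels(animalIds) < 2)
    stop("need instances from at least 2 animals")
  if (any(table(animalIds) < 2))
    stop("need at least 2 instances per animal")
  stopifnot(nrow(warped) == length(animalIds))
  pc1 <- stats::prcomp(warped, center = TRUE, scale. = FALSE)$x[, 1]
  withinVar <- stats::ave(pc1, animalIds,
                          FUN = function(x) x - mean(x))
  if (all(abs(withinVar) < 1e-14))
    return(list(p.value = NA_real_, scores = pc1, degenerate = TRUE))
  fit <- stats::aov(pc1 ~ animalIds)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(p.value = p, scores = pc1, degenerate = FALSE)
}

#' Optimal event-detection threshold
#'
#' Scans every observed score as a candidate threshold X and maximizes the
#' probability of correct identification
#' \deqn{p(X) = \frac{\|X_{true} \ge X\|}{\|X_{true}\| + \|X_{false} \ge X\|},}
#' the number of true events above threshold over all true events plus the
#' false events above threshold. Ties resolve to the lowest threshold.
#'
#' @param scoresTrue scores at true events.
#' @param scoresFalse scores at false events.
#' @return list with \code{threshold} and the achieved \code{probability}.
#' @examples
#' optimizeThreshold(c(5, 6, 7), c(1, 2, 3))$probability  # 1
#' @export
optimizeThreshold <- function(scoresTrue, scoresFalse) {
  stopifnot(length(scoresTrue) > 0, length(scoresFalse) > 0)
  cand <- sort(unique(c(scoresTrue, scoresFalse)))
  nT <- length(scoresTrue)
  p <- vapply(cand, function(x)
    sum(scoresTrue >= x) / (nT + sum(scoresFalse >= x)), numeric(1))
  best <- which.max(p)              # which.max returns the first (lowest) max
  list(threshold = cand[best], probability = p[best])
}

#' Build an event template from training onsets
#'
#' Mean per-neuron activity in a window of \code{windowFrames} frames ending
#' at each training event onset.
#'
#' @param activityMat frames x neurons matrix.
#' @param onsets integer frame indices of event onsets.
#' @param windowFrames template length (default 10).
#' @return neurons x window template matrix.
#' @export
eventTemplate <- function(activityMat, onsets, windowFrames = 10L) {
  stopifnot(length(onsets) >= 1)
  onsets <- onsets[onsets >= windowFrames]
  if (!length(onsets)) stop("no onset has a full template window before it")
  slabs <- lapply(onsets, function(o)
    t(activityMat[(o - windowFrames + 1L):o, , drop = FALSE]))
  Reduce(`+`, slabs) / length(slabs)
}

#' Template similarity score over a recording
#'
#' Sliding inner product of the template with the activity; the score at
#' frame t summarizes the match of the window ending at t.
#'
#' @param activityMat frames x neurons matrix.
#' @param template neurons x window matrix from \code{\link{eventTemplate}}.
#' @return numeric score per frame (NA for frames without a full window).
#' @export
templateScore <- function(activityMat, template) {
  w <- ncol(template)
  n <- nrow(activityMat)
  if (n < w) stop("recording shorter than the template window")
  score <- rep(NA_real_, n)
  tm <- t(template)                 # window x neurons
  for (t in w:n)
    score[t] <- sum(activityMat[(t - w + 1L):t, , drop = FALSE] * tm)
  score
}

.localMaxima <- function(x) {
  n <- length(x)
  which(!is.na(x) &
          x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf))
}

#' Template-based decoding of behavioral event onsets
#'
#' Builds a template from training event onsets, scores training and
#' validation recordings by sliding inner product, optimizes the detection
#' threshold on the training scores, and evaluates the probability of
#' correct identification on the validation set: local maxima of the score
#' above threshold count as detections, and a detection within
#' \code{toleranceFrames} of a true onset is a hit.
#'
#' @param trainActivity frames x neurons training matrix.
#' @param trainOnsets integer training event onsets.
#' @param validActivity frames x neurons validation matrix.
#' @param validOnsets integer validation event onsets.
#' @param windowFrames template window (default 10).
#' @param toleranceFrames matching tolerance (default 10 frames, ~3 s at 3
#'   fps).
#' @param ignoreOnsets onsets whose vicinity is excluded from validation
#'   scoring -- pass the training onsets when training and validation share
#'   a recording, so that correctly detected training events are not counted
#'   as false positives.
#' @return list with \code{probability} (the correct-identification
#'   probability on validation), \code{threshold}, \code{detections} (frame
#'   indices), \code{hits}.
#' @export
templateDecode <- function(trainActivity, trainOnsets, validActivity,
                           validOnsets, windowFrames = 10L,
                           toleranceFrames = 10L,
                           ignoreOnsets = integer(0)) {
  tmpl <- eventTemplate(trainActivity, trainOnsets, windowFrames)
  trScore <- templateScore(trainActivity, tmpl)
  peaks <- .localMaxima(trScore)
  isTrue <- vapply(peaks, function(p)
    any(abs(p - trainOnsets) <= toleranceFrames), logical(1))
  if (!any(isTrue) || all(isTrue))
    thr <- stats::median(trScore, na.rm = TRUE)
  else
    thr <- optimizeThreshold(trScore[peaks[isTrue]],
                             trScore[peaks[!isTrue]])$threshold
  vScore <- templateScore(validActivity, tmpl)
  vPeaks <- .localMaxima(vScore)
  det <- vPeaks[vScore[vPeaks] >= thr]
  if (length(ignoreOnsets))
    det <- det[vapply(det, function(p)
      all(abs(p - ignoreOnsets) > toleranceFrames), logical(1))]
  hit <- vapply(det, function(p)
    any(abs(p - validOnsets) <= toleranceFrames), logical(1))
  nTrue <- length(validOnsets)
  prob <- if (nTrue + sum(!hit) == 0) 0 else {
    found <- sum(vapply(validOnsets, function(o)
      any(abs(det - o) <= toleranceFrames), logical(1)))
    found / (nTrue + sum(!hit))
  }
  list(probability = prob, threshold = thr, detections = det, hits = hit)
}

#' Bootstrap template decoding over event partitions
#'
#' Repeatedly splits the event onsets 50/50 into training and validation
#' halves within one recording and evaluates \code{\link{templateDecode}}.
#'
#' @param activityMat frames x neurons matrix.
#' @param onsets integer event onsets.
#' @param nBoot number of resampled partitions (default 100).
#' @param seed integer seed.
#' @param ... passed to \code{\link{templateDecode}}.
#' @return numeric vector of decoding probabilities, one per partition.
#' @export
bootstrapDecode <- function(activityMat, onsets, nBoot = 100L, seed = 1L,
                            ...) {
  stopifnot(length(onsets) >= 2)
  set.seed(seed)
  one <- function() {
    tr <- sort(sample(onsets, ceiling(length(onsets) / 2)))
    va <- setdiff(onsets, tr)
    if (!length(va)) return(NA_real_)
    templateDecode(activityMat, tr, activityMat, va,
                   ignoreOnsets = tr, ...)$probability
  }
  # NB: not replicate(): its expression is wrapped in function(...) and the
  # enclosing dots would be shadowed by the loop index
  vapply(seq_len(nBoot), function(i) one(), numeric(1))
}

#' Discrete Kullback-Leibler divergence in nats
#'
#' \eqn{D_{KL}(P\|Q) = \sum_i p_i \ln(p_i/q_i)} with an additive floor
#' \code{eps} on both distributions (renormalized) to avoid log 0.
#'
#' @param p,q nonnegative vectors of equal length (normalized internally).
#' @param eps additive floor (default 1e-12).
#' @return KL divergence in nats (>= 0 up to the floor's perturbation).
#' @examples
#' klDivergence(c(0.5, 0.5), c(0.9, 0.1))  # ~0.511 nats
#' @export
klDivergence <- function(p, q, eps = 1e-12) {
  stopifnot(length(p) == length(q))
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Minimal KL divergence between two samples over a scan of binnings
#'
#' Kernel-smoothed histograms of the two samples are compared on a shared
#' support (the union range) for every bin count in \code{binRange}, and the
#' minimum divergence over the scan is returned -- information-theoretic
#' quantities depend strongly on binning, so the scan removes that
#' arbitrariness conservatively.
#'
#' @param obs,sim numeric samples (need >= 2 distinct values each).
#' @param binRange integer range of bin counts (default 40:200).
#' @param eps additive floor passed to \code{\link{klDivergence}}.
#' @return minimal \eqn{D_{KL}(P_{obs}\|P_{sim})} in nats.
#' @export
minBinnedKL <- function(obs, sim, binRange = 40:200, eps = 1e-12) {
  if (length(unique(obs)) < 2 || length(unique(sim)) < 2)
    stop("degenerate one-point distribution")
  lo <- min(obs, sim); hi <- max(obs, sim)
  vals <- vapply(binRange, function(nb) {
    d1 <- stats::density(obs, from = lo, to = hi, n = nb)$y
    d2 <- stats::density(sim, from = lo, to = hi, n = nb)$y
    klDivergence(d1 / sum(d1), d2 / sum(d2), eps)
  }, numeric(1))
  min(vals)
}

#' Relative information between reference and modified simulations
#'
#' For each behavior distribution in scope (forward and backward dwells and
#' backing bouts), computes the minimal binned KL divergence between
#' observation and simulation; sums them into a total information
#' \eqn{I_{tot}}, and reports the ratio
#' \eqn{I_{rel} = I_{tot}^{reference}/I_{tot}^{modified}}.
#'
#' @param obsDwells named list of observed dwell samples (e.g. forward,
#'   backward, bouts).
#' @param simReference named list of reference-model simulated samples
#'   (same names).
#' @param simModified named list of modified-model simulated samples.
#' @param binRange bin-count scan (default 40:200).
#' @return list with \code{iTotReference}, \code{iTotModified}, \code{iRel},
#'   and the per-distribution divergences.
#' @export
relativeInformation <- function(obsDwells, simReference, simModified,
                                binRange = 40:200) {
  nms <- names(obsDwells)
  stopifnot(!is.null(nms), setequal(nms, names(simReference)),
            setequal(nms, names(simModified)))
  dRef <- vapply(nms, function(b)
    minBinnedKL(obsDwells[[b]], simReference[[b]], binRange), numeric(1))
  dMod <- vapply(nms, function(b)
    minBinnedKL(obsDwells[[b]], simModified[[b]], binRange), numeric(1))
  list(iTotReference = sum(dRef), iTotModified = sum(dMod),
       iRel = sum(dRef) / sum(dMod), perDistribution = rbind(reference = dRef,
                                                             modified = dMod))
}
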