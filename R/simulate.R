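#' Simulate the manifold as a Markov chain over bins
#'
#' Samples successive bins from the rows of the model's bin-level transition
#' matrix. One simulation step equals one acquisition frame (transition
#' probabilities were estimated on that time scale). Deterministic under a
#' fixed seed. If an absorbing bin with no outgoing row is reached the path
#' terminates early and is flagged.
#'
#' @param model a \linkS4class{ManifoldModel}.
#' @param startBin occupied starting bin index.
#' @param nSteps number of steps to simulate.
#' @param seed integer RNG seed.
#' @return integer vector of bin indices of length <= nSteps + 1 (including
#'   the start), with attribute \code{"terminated"} TRUE if an absorbing bin
#'   cut the path short.
#' @examples
#' sim <- simulateMarkovSwitcher(c(0.9, 0.9), list(c(1, 0), c(0, 1)),
#'   noiseSd = 0.05, nFrames = 2000, seed = 1,
#'   stateNames = c("forward", "backward"))
#' model <- fitPipeline(list(sim$recording), tau = 3, nDelays = 2,
#'   cluster = FALSE, deltaTheta = 0.2, seed = 1)
#' path <- runMarkov(model, startBin = binInfo(model)$occupancy |>
#'   which.max(), nSteps = 50, seed = 2)
#' @export
runMarkov <- function(model, startBin, nSteps, seed = 1L) {
  stopifnot(is(model, "ManifoldModel"))
  P <- model@binTrans
  if (startBin < 1 || startBin > nrow(P) ||
      model@bins$occupancy[startBin] == 0)
    stop("startBin must be an occupied bin")
  set.seed(seed)
  path <- integer(nSteps + 1L)
  path[1] <- as.integer(startBin)
  terminated <- FALSE
  cur <- as.integer(startBin)
  Pm <- as.matrix(P)   # bins are few; dense rows sample faster
  for (s in seq_len(nSteps)) {
    row <- Pm[cur, ]
    if (sum(row) == 0) { terminated <- TRUE; path <- path[1:s]; break }
    cur <- sample.int(length(row), 1L, prob = row)
    path[s + 1L] <- cur
  }
  attr(path, "terminated") <- terminated
  path
}

#' Map a simulated bin path back to neuronal activity
#'
#' In \code{"mean"} mode each step emits the bin's mean raw-neuron snapshot
#' (deterministic given the path); in \code{"sample"} mode a stored training
#' snapshot assigned to that bin is drawn at random (seeded).
#'
#' @param path integer bin sequence from \code{\link{runMarkov}}.
#' @param model the \linkS4class{ManifoldModel}.
#' @param mode \code{"mean"} (default) or \code{"sample"}.
#' @param seed RNG seed for sample mode.
#' @return numeric matrix, steps x neurons (all reconstructed neurons).
#' @export
pathToActivity <- function(path, model, mode = c("mean", "sample"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(model, "ManifoldModel"))
  if (mode == "mean")
    return(model@meanActivity[path, , drop = FALSE])
  set.seed(seed)
  members <- split(seq_along(model@assignments), model@assignments)
  out <- matrix(NA_real_, length(path), ncol(model@trainActivity),
                dimnames = list(NULL, colnames(model@trainActivity)))
  for (i in seq_along(path)) {
    m <- members[[as.character(path[i])]]
    out[i, ] <- if (is.null(m)) model@meanActivity[path[i], ]
      else model@trainActivity[m[sample.int(length(m), 1L)], ]
  }
  out
}

#' Map a simulated bin path to behavioral labels
#'
#' \code{"sample"} mode draws from each bin's behavioral-state distribution;
#' \code{"modal"} mode (used for dwell statistics) takes the most prevalent
#' behavior. Bins flagged unassigned emit "unassigned".
#'
#' @param path integer bin sequence.
#' @param model the \linkS4class{ManifoldModel} (must carry behaviors).
#' @param mode \code{"modal"} (default) or \code{"sample"}.
#' @param seed RNG seed for sample mode.
#' @return character vector of behavior labels, one per step.
#' @export
pathToBehavior <- function(path, model, mode = c("modal", "sample"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(model, "ManifoldModel"))
  if (!length(model@behaviorLevels))
    stop("model carries no behavioral distributions")
  if (mode == "modal")
    return(model@bins$modalBehavior[path])
  set.seed(seed)
  lev <- model@behaviorLevels
  vapply(path, function(b) {
    p <- model@behaviorProb[b, ]
    if (model@bins$unassigned[b] || sum(p) == 0) "unassigned"
    else sample(lev, 1L, prob = p)
  }, character(1))
}

#' Sliding majority filter for categorical sequences
#'
#' Categorical analogue of a running median: each frame is replaced by the
#' most frequent label in the centered window; ties keep the incumbent
#' label. For two-label sequences this coincides with a median filter on the
#' label codes.
#'
#' @param labels character vector.
#' @param window odd window length (default 11).
#' @return filtered character vector, same length.
#' @export
medianFilterLabels <- function(labels, window = 11L) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(labels)
  if (n == 0) stop("empty sequence")
  lev <- unique(labels)
  if (length(lev) == 1 || window == 1) return(labels)
  half <- (window - 1L) %/% 2L
  counts <- vapply(lev, function(l) {
    ind <- as.numeric(labels == l)
    cs <- cumsum(ind)
    lo <- pmax(seq_len(n) - half - 1L, 0L)
    hi <- pmin(seq_len(n) + half, n)
    cs[hi] - c(0, cs)[lo + 1L]
  }, numeric(n))
  best <- max.col(counts, ties.method = "first")
  out <- lev[best]
  # ties keep the incumbent
  mx <- counts[cbind(seq_len(n), best)]
  inc <- match(labels, lev)
  tie <- counts[cbind(seq_len(n), inc)] == mx
  out[tie] <- labels[tie]
  out
}

#' Dwell-time and bout statistics of a behavior sequence
#'
#' Median-filters the sequence, tabulates the durations of contiguous runs
#' of the forward and backward states, and merges backward runs separated by
#' forward interruptions of at most \code{boutGap} frames into backing
#' bouts (a bout's duration spans from the start of its first backward run
#' to the end of its last).
#'
#' @param behavior character vector of per-frame labels.
#' @param forwardLabel,backwardLabel names of the two locomotor states
#'   (defaults "forward", "backward").
#' @param medianWindow median filter window (default 11 frames).
#' @param boutGap maximum forward interruption inside a bout (default 30
#'   frames).
#' @return list with numeric vectors \code{forward}, \code{backward},
#'   \code{bouts} (durations in frames) and the filtered sequence.
#' @examples
#' seqs <- c(rep("forward", 50), rep("backward", 20), rep("forward", 50))
#' dwellStatistics(seqs, medianWindow = 1)
#' @export
dwellStatistics <- function(behavior, forwardLabel = "forward",
                            backwardLabel = "backward",
                            medianWindow = 11L, boutGap = 30L) {
  if (!length(behavior)) stop("empty sequence")
  filt <- medianFilterLabels(behavior, medianWindow)
  r <- rle(filt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fw <- r$lengths[r$values == forwardLabel]
  bw <- which(r$values == backwardLabel)
  bwDur <- r$lengths[bw]
  bouts <- numeric(0)
  if (length(bw)) {
    boutStart <- starts[bw[1]]
    boutEnd <- ends[bw[1]]
    if (length(bw) > 1) for (i in 2:length(bw)) {
      gap <- starts[bw[i]] - boutEnd - 1L
      if (gap <= boutGap) {
        boutEnd <- ends[bw[i]]
      } else {
        bouts <- c(bouts, boutEnd - boutStart + 1L)
        boutStart <- starts[bw[i]]
        boutEnd <- ends[bw[i]]
      }
    }
    bouts <- c(bouts, boutEnd - boutStart + 1L)
  }
  list(forward = as.numeric(fw), backward = as.numeric(bwDur),
       bouts = as.numeric(bouts), filtered = filt)
}

#' Kernel-smoothed r-squared agreement between two dwell distributions
#'
#' Evaluates Gaussian kernel density estimates of two dwell-time samples on
#' a shared grid and returns the squared Pearson correlation of the two
#' smoothed histograms.
#'
#' @param obs,sim numeric dwell-time samples.
#' @param n grid size (default 128).
#' @return r-squared in [0, 1].
#' @export
dwellR2 <- function(obs, sim, n = 128L) {
  stopifnot(length(obs) > 1, length(sim) > 1)
  lo <- min(obs, sim); hi <- max(obs, sim)
  d1 <- stats::density(obs, from = lo, to = hi, n = n)$y
  d2 <- stats::density(sim, from = lo, to = hi, n = n)$y
  stats::cor(d1, d2)^2
}

#' Forecast time to a target behavior from a start bin
#'
#' Runs seeded Markov simulations from a start bin and records, for each,
#' the number of steps until the modal per-bin behavior first equals the
#' target (0 if the start bin is already in the target). Runs that never
#' reach the target within \code{maxSteps} are censored at \code{maxSteps};
#' censored runs enter the mean only when fewer than 5\% of runs are
#' censored, otherwise the mean is reported over uncensored runs with a
#' flag.
#'
#' @param model a \linkS4class{ManifoldModel} carrying behaviors.
#' @param startBin occupied starting bin.
#' @param targetBehavior label to be reached.
#' @param nSims number of simulations (default 200).
#' @param maxSteps censoring horizon (default 10x the longest observed
#'   dwell, approximated by 10x the number of training states when no
#'   behaviors are stored).
#' @param seed integer seed.
#' @param bootstrap number of bootstrap resamples for the CI (default 200).
#' @return list with \code{times} (per-simulation steps, censored at
#'   maxSteps), \code{mean}, \code{ci95}, \code{censoredFraction}.
#' @export
timeToTransition <- function(model, startBin, targetBehavior, nSims = 200L,
                             maxSteps = NULL, seed = 1L, bootstrap = 200L) {
  stopifnot(is(model, "ManifoldModel"), nSims >= 1)
  if (!targetBehavior %in% model@bins$modalBehavior)
    stop("target behavior '", targetBehavior,
         "' is not the modal behavior of any bin")
  if (is.null(maxSteps))
    maxSteps <- 10L * max(sum(model@bins$occupancy), 100L)
  times <- numeric(nSims)
  if (model@bins$modalBehavior[startBin] == targetBehavior) {
    times[] <- 0
  } else {
    for (i in seq_len(nSims)) {
      path <- runMarkov(model, startBin, maxSteps, seed = seed + i - 1L)
      beh <- model@bins$modalBehavior[path[-1]]
      hit <- which(beh == targetBehavior)
      times[i] <- if (length(hit)) hit[1] else maxSteps
    }
  }
  censored <- times >= maxSteps
  useAll <- mean(censored) < 0.05
  est <- if (useAll) mean(times) else mean(times[!censored])
  set.seed(seed)
  bs <- replicate(bootstrap, {
    x <- sample(times, replace = TRUE)
    if (useAll) mean(x) else mean(x[x < maxSteps])
  })
  list(times = times, mean = est,
       ci95 = stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE),
       censoredFraction = mean(censored))
}

#' Frames elapsed since the onset of the current behavior
#'
#' For each frame, the number of frames since the running behavior bout
#' began (0 at onset). Used to condition the dwell-time null forecast on the
#' average elapsed time of the states in a phase bin.
#'
#' @param labels character vector of per-frame behavior labels.
#' @return integer vector, same length.
#' @export
timeSinceOnset <- function(labels) {
  r <- rle(as.character(labels))
  unlist(lapply(r$lengths, function(l) seq_len(l) - 1L), use.names = FALSE)
}

#' Dwell-time null forecast of time to transition
#'
#' The phase-blind null: given the empirical dwell-time distribution of the
#' current behavior and the elapsed time \code{tStart} since its onset, the
#' expected residual time is the mean of \code{dwell - tStart} over dwells
#' exceeding \code{tStart} (the right tail / survival function of the dwell
#' histogram).
#'
#' @param dwells numeric sample of dwell durations (frames).
#' @param tStart elapsed time since behavior onset (frames, >= 0).
#' @return list with \code{mean} residual time, the conditional
#'   \code{residuals} sample, and \code{defined} (FALSE when no dwell
#'   exceeds tStart; mean is then NA).
#' @examples
#' nullTimeToTransition(rexp(1000, 0.1), tStart = 5)$mean  # ~ 10
#' @export
nullTimeToTransition <- function(dwells, tStart = 0) {
  stopifnot(length(dwells) >= 1, tStart >= 0)
  tail <- dwells[dwells > tStart]
  if (!length(tail))
    return(list(mean = NA_real_, residuals = numeric(0), defined = FALSE))
  res <- tail - tStart
  list(mean = mean(res), residuals = res, defined = TRUE)
}
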