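#' Estimate the embedding delay from a single trace
#'
#' Returns the smallest lag at which the autocorrelation function first
#' crosses zero (<= 0), the point at which delayed copies of the trace stop
#' being redundant. If the autocorrelation never crosses zero within
#' length/4 lags, length/4 is returned with a warning.
#'
#' @param trace numeric vector (a single neuron's series).
#' @return integer lag in frames.
#' @examples
#' estimateDelay(cos(2 * pi * (1:2000) / 40))  # T/4 = 10
#' @export
estimateDelay <- function(trace) {
  trace <- as.numeric(trace)
  maxLag <- floor(length(trace) / 4)
  if (length(trace) <= 8 || maxLag < 1)
    stop("trace too short to estimate a delay")
  ac <- stats::acf(trace, lag.max = maxLag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  hit <- which(ac <= 0)
  if (!length(hit)) {
    warning("autocorrelation never crosses zero within length/4 lags; ",
            "returning length/4")
    return(maxLag)
  }
  as.integer(hit[1])
}

#' Delay-embed activity and derivative into phase-space points
#'
#' Builds the delay-embedded state vector at each frame t by concatenating
#' activity snapshots at lags \code{0, tau, ..., nDelays*tau} followed by
#' derivative snapshots at the same lags. Frames with incomplete lag history
#' are dropped, so the first embedded point sits at frame
#' \code{nDelays*tau + 1} (1-based). The embedded dimension is
#' \code{2 * nNeurons * (nDelays + 1)}.
#'
#' @param act a \linkS4class{Recording} of (typically z-scored) activity.
#' @param deriv a \linkS4class{Recording} of its time derivative, same shape.
#' @param config an \code{\link{EmbedConfig}}.
#' @param recordingId integer id tagged onto all points (used when
#'   concatenating multiple recordings; transitions never span recordings).
#' @return an \linkS4class{EmbeddedSeries}.
#' @examples
#' pre <- preprocessRecording(Recording(matrix(rnorm(900), 300, 3)))
#' emb <- delayEmbed(pre$activity, pre$deriv, EmbedConfig(tau = 5, nDelays = 2))
#' dim(embeddedPoints(emb))  # 2 * 3 * 3 = 18 columns
#' @export
delayEmbed <- function(act, deriv, config = EmbedConfig(), recordingId = 1L) {
  stopifnot(is(act, "Recording"), is(deriv, "Recording"),
            is(config, "EmbedConfig"))
  a <- activity(act); d <- activity(deriv)
  if (!all(dim(a) == dim(d)))
    stop("activity and derivative recordings must share shape")
  tau <- config@tau; nd <- config@nDelays
  n <- nrow(a)
  first <- nd * tau + 1L
  if (n < first + 1L)
    stop("recording too short for this embedding: need at least ",
         first + 1L, " frames, got ", n)
  frames <- first:n
  lagBlock <- function(m) {
    do.call(cbind, lapply(0:nd, function(k) m[frames - k * tau, , drop = FALSE]))
  }
  pts <- cbind(lagBlock(a), lagBlock(d))
  nn <- neuronNames(act)
  colnames(pts) <- c(
    as.vector(vapply(0:nd, function(k) paste0(nn, ".act.lag", k * tau),
                     character(length(nn)))),
    as.vector(vapply(0:nd, function(k) paste0(nn, ".der.lag", k * tau),
                     character(length(nn)))))
  new("EmbeddedSeries", points = pts, frameIndex = as.integer(frames),
      recordingId = rep(as.integer(recordingId), length(frames)),
      neurons = nn, config = config)
}

#' Concatenate embedded series from multiple recordings
#'
#' Stacks points from independently embedded recordings. Recording ids are
#' kept so that downstream transition estimation never pairs a point with
#' the first point of the next recording.
#'
#' @param ... \linkS4class{EmbeddedSeries} objects sharing neurons and config.
#' @return a single \linkS4class{EmbeddedSeries}.
#' @export
bindEmbedded <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && !is(lst[[1]], "EmbeddedSeries"))
    lst <- lst[[1]]
  stopifnot(length(lst) >= 1,
            all(vapply(lst, is, logical(1), "EmbeddedSeries")))
  nn <- lst[[1]]@neurons
  for (e in lst)
    if (!identical(e@neurons, nn))
      stop("all embedded series must share the same neuron set and order")
  new("EmbeddedSeries",
      points = do.call(rbind, lapply(lst, slot, "points")),
      frameIndex = do.call(c, lapply(lst, slot, "frameIndex")),
      recordingId = do.call(c, lapply(seq_along(lst), function(i)
        rep(i, nrow(lst[[i]]@points)))),
      neurons = nn, config = lst[[1]]@config)
}
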