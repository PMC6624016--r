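#' Read a trace CSV into a Recording
#'
#' Expects a delimited text file with one row per frame and the neuron names
#' as the header; an optional leading \code{time} column is dropped. A
#' comment line of the form \code{# frame_rate: 3} may carry the frame rate;
#' otherwise the \code{frameRate} argument is used.
#'
#' @param path file path.
#' @param frameRate frames/s, used when no metadata comment is present.
#' @param animalId identifier for the recording (default: the file name).
#' @param sep field separator (default ",").
#' @return a \linkS4class{Recording}.
#' @export
readTraces <- function(path, frameRate = 3, animalId = basename(path),
                       sep = ",") {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("frame_rate:\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2) frameRate <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, sep = sep, comment.char = "#",
                        check.names = FALSE)
  if (tolower(colnames(df)[1]) == "time") df <- df[, -1, drop = FALSE]
  if (anyDuplicated(colnames(df)))
    stop("duplicate neuron column(s): ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in trace file ", path)
  Recording(m, neuronNames = colnames(df), frameRate = frameRate,
            animalId = animalId)
}

#' Write a Recording's traces to CSV
#'
#' Inverse of \code{\link{readTraces}}: header row of neuron names, one row
#' per frame, preceded by a \code{# frame_rate} metadata comment. Full
#' double precision is kept so a round trip is bit-equal.
#'
#' @param rec a \linkS4class{Recording}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTraces <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame_rate: ", frameRate(rec)), con)
  writeLines(paste(neuronNames(rec), collapse = ","), con)
  m <- activity(rec)
  writeLines(apply(m, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = ",")), con)
  invisible(path)
}

#' Read per-frame behavior labels
#'
#' Expects a one-column text file with header \code{behavior}; an optional
#' comment line \code{# levels: a,b,c} declares the label vocabulary, in
#' which case unknown labels raise an error.
#'
#' @param path file path.
#' @param nFrames optional expected frame count (error on mismatch).
#' @return character vector of labels.
#' @export
readBehaviors <- function(path, nFrames = NULL) {
  first <- readLines(path, n = 1L)
  levels <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("levels:\\s*(.+)$", first))[[1]]
    if (length(m) == 2) levels <- trimws(strsplit(m[2], ",")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#")
  lab <- as.character(df[[1]])
  if (!is.null(levels)) {
    bad <- setdiff(unique(lab), levels)
    if (length(bad))
      stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(nFrames) && length(lab) != nFrames)
    stop("behavior file has ", length(lab), " labels but the recording has ",
         nFrames, " frames")
  lab
}

#' Derive forward/backward labels from a reference neuron
#'
#' For recordings whose native behavior annotation differs from the model's,
#' labels are normalized by thresholding the z-scored trace of a reference
#' command neuron (canonically AVAL): frames below the threshold are called
#' forward locomotion, frames above it backward locomotion.
#'
#' @param rec a \linkS4class{Recording}.
#' @param referenceNeuron neuron name (e.g. "AVAL").
#' @param thresholdZ z-score threshold (default 0).
#' @return character vector ("forward"/"backward") per frame.
#' @export
normalizeExternalBehavior <- function(rec, referenceNeuron, thresholdZ = 0) {
  if (!referenceNeuron %in% neuronNames(rec))
    stop("reference neuron '", referenceNeuron, "' absent from recording")
  x <- unname(activity(rec)[, referenceNeuron])
  z <- (x - mean(x)) / stats::sd(x)
  ifelse(z < thresholdZ, "forward", "backward")
}

#' Save a manifold model as a JSON archive
#'
#' Serializes the full \linkS4class{ManifoldModel} (bin table, per-bin
#' summaries, sparse bin transitions as coordinate triplets, configs, and
#' stored training snapshots) into a single JSON file at full double
#' precision. Deterministic: identical models produce byte-identical files.
#'
#' @param model a \linkS4class{ManifoldModel}.
#' @param path output path (conventionally .json).
#' @return invisibly, the path.
#' @export
saveManifoldModel <- function(model, path) {
  bt <- methods::as(model@binTrans, "TsparseMatrix")
  obj <- list(
    format = "fluxmap-manifold-1",
    bins = model@bins,
    meanEmbedded = model@meanEmbedded,
    meanActivity = model@meanActivity,
    behaviorProb = model@behaviorProb,
    behaviorLevels = model@behaviorLevels,
    binTransitions = list(i = bt@i + 1L, j = bt@j + 1L, x = bt@x,
                          dim = dim(bt)),
    modelNeurons = model@modelNeurons,
    allNeurons = model@allNeurons,
    embed = list(tau = model@config@tau, nDelays = model@config@nDelays),
    preprocess = model@preprocess,
    assignments = model@assignments,
    trainActivity = model@trainActivity,
    trainRecordingId = model@trainRecordingId,
    seed = model@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' Load a manifold model from a JSON archive
#'
#' @param path path written by \code{\link{saveManifoldModel}}.
#' @return a \linkS4class{ManifoldModel}.
#' @export
loadManifoldModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "fluxmap-manifold-1"))
    stop("not a fluxmap manifold archive: ", path)
  asMat <- function(m, ncolHint = NULL) {
    m <- as.matrix(m)
    if (!is.null(ncolHint) && length(m) == 0)
      m <- matrix(0, 0, ncolHint)
    m
  }
  bt <- Matrix::sparseMatrix(i = o$binTransitions$i, j = o$binTransitions$j,
                             x = o$binTransitions$x,
                             dims = o$binTransitions$dim)
  bins <- as.data.frame(o$bins)
  if (length(o$behaviorLevels)) {
    bp <- asMat(o$behaviorProb)
    if (ncol(bp) == length(o$behaviorLevels))
      colnames(bp) <- o$behaviorLevels
  } else {
    bp <- matrix(0, nrow(bins), 0)
  }
  ma <- asMat(o$meanActivity)
  colnames(ma) <- o$allNeurons
  ta <- asMat(o$trainActivity)
  colnames(ta) <- o$allNeurons
  new("ManifoldModel", bins = bins, meanEmbedded = asMat(o$meanEmbedded),
      meanActivity = ma, behaviorProb = bp,
      behaviorLevels = as.character(o$behaviorLevels),
      binTrans = methods::as(bt, "CsparseMatrix"),
      modelNeurons = as.character(o$modelNeurons),
      allNeurons = as.character(o$allNeurons),
      config = EmbedConfig(o$embed$tau, o$embed$nDelays),
      preprocess = as.list(o$preprocess),
      assignments = as.integer(o$assignments),
      trainActivity = ta,
      trainRecordingId = as.integer(o$trainRecordingId),
      seed = as.integer(o$seed))
}
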