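#' @include AllGenerics.R
NULL

# Delimited-text dialect used throughout: comma-separated, UTF-8, '.'
# decimal, mandatory header row.

#' Read a recording from delimited text
#'
#' Expects the package's delimited dialect: a mandatory header row of
#' channel names and one sample per line (columns = channels). The sampling
#' rate is not stored in the file and must be supplied. EDF input is not
#' supported; convert to this dialect upstream.
#'
#' @param path file path.
#' @param rate sampling rate of the stored signal, Hz.
#' @param regionMap optional channel -> region named character vector.
#' @return An \linkS4class{EEGRecording}.
#' @export
readRecordingCSV <- function(path, rate, regionMap = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(df)) stop("no samples in ", path)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric values in column ", bad, " of ", path)
  }
  EEGRecording(t(as.matrix(df)), rate, colnames(df), regionMap)
}

#' Write a recording as delimited text
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path destination path.
#' @export
writeRecordingCSV <- function(rec, path) {
  df <- as.data.frame(t(rec@data))
  colnames(df) <- rec@channelNames
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gait-event table
#'
#' Columns time_s, event, condition; validated against the event grammar
#' (strictly increasing times, cyclic LC -> RO -> RC -> LO order, known
#' labels) with the offending row reported.
#'
#' @param path file path.
#' @return A \linkS4class{GaitEvents}.
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("time_s", "event", "condition")
  if (!all(need %in% names(df)))
    stop(path, " must have columns ", paste(need, collapse = ", "))
  GaitEvents(df[, need])
}

#' Write a gait-event table
#'
#' @param events a \linkS4class{GaitEvents}.
#' @param path destination path.
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(gaitEvents(events), path, row.names = FALSE)
  invisible(path)
}

#' Read a channel -> region map
#'
#' Delimited text with columns channel, region.
#'
#' @param path file path.
#' @return named character vector channel -> region.
#' @export
readRegionMap <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("channel", "region") %in% names(df)))
    stop(path, " must have columns channel, region")
  stats::setNames(df$region, df$channel)
}

#' Write ground truth to JSON
#'
#' Stores the generative coupling tensor (with its condition/phase/channel
#' dimnames) and the gait schedule in a single documented JSON file.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param path destination path.
#' @export
writeGroundTruth <- function(gt, path) {
  dn <- dimnames(gt@coupling)
  payload <- list(
    format = "gaitpli-groundtruth-v1",
    dims = dim(gt@coupling),
    conditions = dn[[1]], phases = dn[[2]], channels = dn[[3]],
    coupling = as.vector(gt@coupling),  # column-major over dims
    schedule = gaitEvents(gt@schedule))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path a file written by \code{\link{writeGroundTruth}}.
#' @return A \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "gaitpli-groundtruth-v1"))
    stop(path, " is not a gaitpli ground-truth file")
  coupling <- array(p$coupling, dim = p$dims,
                    dimnames = list(p$conditions, p$phases,
                                    p$channels, p$channels))
  new("GroundTruth", coupling = coupling,
      schedule = GaitEvents(as.data.frame(p$schedule)))
}

#' Write a connectivity tensor (CSV payload + JSON sidecar)
#'
#' The tensor values are stored column-major as a single CSV column; the
#' JSON sidecar records dims, the window grid, conditions and channels, so
#' the pair round-trips exactly.
#'
#' @param tensor a \linkS4class{ConnectivityTensor}.
#' @param prefix path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @export
writeConnectivity <- function(tensor, prefix) {
  header <- list(
    format = "gaitpli-tensor-v1", dims = dim(tensor@values),
    grid = list(winLen = tensor@grid@winLen, step = tensor@grid@step,
                epochLen = tensor@grid@epochLen),
    condition = tensor@condition, channels = tensor@channelNames)
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(data.frame(value = as.vector(tensor@values)),
                   paste0(prefix, ".csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a connectivity tensor written by \code{\link{writeConnectivity}}
#'
#' @param prefix path prefix used at write time.
#' @return A \linkS4class{ConnectivityTensor}.
#' @export
readConnectivity <- function(prefix) {
  h <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(h$format, "gaitpli-tensor-v1"))
    stop(prefix, " is not a gaitpli tensor")
  vals <- utils::read.csv(paste0(prefix, ".csv"))$value
  grid <- windowGrid(h$grid$epochLen, h$grid$winLen, h$grid$step)
  new("ConnectivityTensor", values = array(vals, dim = h$dims),
      grid = grid, condition = as.character(h$condition),
      channelNames = as.character(h$channels))
}

#' Export a weighted graph as an edge list
#'
#' Delimited text (node_i, node_j, weight), upper-triangle nonzero edges.
#'
#' @param W symmetric weight matrix (optionally thresholded first).
#' @param path destination path.
#' @export
writeEdgeList <- function(W, path) {
  W <- .checkWeights(W)
  labels <- rownames(W)
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(nrow(W)))
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(node_i = labels[idx[, 1]], node_j = labels[idx[, 2]],
                   weight = W[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
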