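#' @include AllClasses.R
NULL

#' Accessors for gaitpli data objects
#'
#' \code{channelData} returns the underlying numeric payload (signal matrix
#' or tensor); \code{samplingRate}, \code{channelNames}, \code{regionMap},
#' \code{conditionLabels} and \code{nEpochs} return the obvious metadata;
#' \code{gaitEvents} returns the event table as a data.frame;
#' \code{windowOffsets} and \code{nWindows} describe a window grid.
#'
#' @param x a gaitpli object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))
#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("gaitEvents", function(x) standardGeneric("gaitEvents"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("windowOffsets", function(x) standardGeneric("windowOffsets"))
#' @rdname accessors
#' @export
setGeneric("couplingProfiles", function(x) standardGeneric("couplingProfiles"))

#' @rdname accessors
#' @export
setMethod("channelData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("channelData", "EpochSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("channelData", "ConnectivityTensor", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("channelData", "PhaseConnectivity", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("channelData", "FeatureSet", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "ConnectivityTensor", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "PhaseConnectivity", function(x) x@channelNames)

#' @rdname accessors
#' @export
setMethod("regionMap", "EEGRecording", function(x) x@regionMap)
#' @rdname accessors
#' @export
setMethod("regionMap", "EpochSet", function(x) x@regionMap)
#' @rdname accessors
#' @export
setMethod("regionMap", "SimConfig", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("conditionLabels", "EpochSet", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "ConnectivityTensor", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "PhaseConnectivity", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "FeatureSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])
#' @rdname accessors
#' @export
setMethod("nEpochs", "ConnectivityTensor", function(x) dim(x@values)[1])
#' @rdname accessors
#' @export
setMethod("nEpochs", "PhaseConnectivity", function(x) dim(x@values)[1])

#' @rdname accessors
#' @export
setMethod("gaitEvents", "GaitEvents", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("gaitEvents", "GroundTruth", function(x) x@schedule@events)

#' @rdname accessors
#' @export
setMethod("nWindows", "WindowGrid", function(x) length(x@offsets))
#' @rdname accessors
#' @export
setMethod("nWindows", "ConnectivityTensor", function(x) dim(x@values)[2])
#' @rdname accessors
#' @export
setMethod("windowOffsets", "WindowGrid", function(x) x@offsets)
#' @rdname accessors
#' @export
setMethod("windowOffsets", "ConnectivityTensor", function(x) x@grid@offsets)

#' @rdname accessors
#' @export
setMethod("couplingProfiles", "SimConfig", function(x) x@coupling)
#' @rdname accessors
#' @export
setMethod("couplingProfiles", "GroundTruth", function(x) x@coupling)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples at %g Hz (%.2f s)\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate))
  if (length(object@regionMap))
    cat("  regions:", paste(sort(unique(object@regionMap)), collapse = " "),
        "\n")
})

setMethod("show", "GaitEvents", function(object) {
  ev <- object@events
  cat(sprintf("GaitEvents: %d events", nrow(ev)))
  if (nrow(ev))
    cat(sprintf(" over %.2f s, conditions: %s",
                diff(range(ev$time_s)),
                paste(names(table(ev$condition)), collapse = " ")))
  cat("\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples at %g Hz\n",
              d[1], d[2], d[3], object@rate))
  cat(sprintf("  t0 offset %g s; conditions: %s\n", object@t0Offset,
              paste(sprintf("%s=%d", names(table(object@condition)),
                            table(object@condition)), collapse = " ")))
})

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d windows of %g ms, step %g ms over %g s\n",
              length(object@offsets), 1000 * object@winLen,
              1000 * object@step, object@epochLen))
})

setMethod("show", "ConnectivityTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("ConnectivityTensor: %d epochs x %d windows x %d x %d PLI\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "PhaseConnectivity", function(object) {
  d <- dim(object@values)
  cat(sprintf("PhaseConnectivity: %d epochs x %d phases (%s) x %d x %d\n",
              d[1], d[2], paste(object@phases, collapse = ", "), d[3], d[4]))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d channels at %g Hz, carrier %g Hz, %d epochs/condition\n",
    object@nChannels, object@samplingRate, object@carrierFreq,
    object@nEpochsPerCondition))
  cat(sprintf("  coupled pairs: %d; noise sd %g; seed %d\n",
              sum(apply(object@coupling, c(3, 4), max) > 0) / 2,
              object@noiseSigma, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth coupling:",
      paste(dim(object@coupling), collapse = " x "), "\n")
  show(object@schedule)
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s': %d epochs x %d features\n",
              object@family, nrow(object@matrix), ncol(object@matrix)))
})
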