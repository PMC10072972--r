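#' @import methods
NULL

GAIT_EVENTS <- c("LC", "RO", "RC", "LO")
GAIT_PHASES <- c("LC->RO", "RO->RC", "RC->LO", "LO->LC")
CONDITIONS <- c("FF", "FU", "UF")
REGIONS <- c("LMO", "RMO", "LSS", "RSS", "RSP", "VIS")

# cyclic gait grammar: each event's legal successor
.EVENT_SUCCESSOR <- c(LC = "RO", RO = "RC", RC = "LO", LO = "LC")

#' EEGRecording: a multichannel electrophysiology recording
#'
#' Holds a channels x samples signal matrix together with its sampling rate,
#' channel names and a channel-to-brain-region map. Regions follow the
#' 32-electrode cortical grid layout: somatomotor (LMO/RMO), somatosensory
#' (LSS/RSS), retrosplenial (RSP) and visual (VIS) areas.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot rate sampling rate in Hz.
#' @slot channelNames unique channel labels, one per row of \code{data}.
#' @slot regionMap named character vector mapping channel name to region label.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    rate = "numeric",
    channelNames = "character",
    regionMap = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "one channel name per data row required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(object@regionMap) &&
      !all(names(object@regionMap) %in% object@channelNames))
    msg <- c(msg, "regionMap names must be channel names")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix.
#' @param rate sampling rate, Hz.
#' @param channelNames channel labels; defaults to rownames or CH01..CHnn.
#' @param regionMap named character vector channel -> region.
#' @return An \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(data, rate, channelNames = NULL, regionMap = character()) {
  data <- as.matrix(data)
  if (is.null(channelNames)) {
    channelNames <- rownames(data)
    if (is.null(channelNames))
      channelNames <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  rownames(data) <- channelNames
  new("EEGRecording", data = data, rate = as.numeric(rate),
      channelNames = channelNames, regionMap = regionMap)
}

#' GaitEvents: an ordered table of gait events
#'
#' Rows of (time_s, event, condition) where event is one of RO/RC/LO/LC
#' (right/left hind paw off/contacting the ground) and condition is the
#' locomotion task: FF (flat-to-flat), FU (flat-to-uneven) or UF
#' (uneven-to-flat). Times must be strictly increasing and consecutive
#' events must follow the cyclic grammar LC -> RO -> RC -> LO -> LC.
#'
#' @slot events data.frame with columns time_s, event, condition.
#' @export
setClass("GaitEvents", representation(events = "data.frame"))

setValidity("GaitEvents", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("time_s", "event", "condition") %in% names(ev)))
    return("events needs columns time_s, event, condition")
  if (nrow(ev)) {
    if (!all(ev$event %in% GAIT_EVENTS))
      msg <- c(msg, sprintf("unknown event label at row %d",
                            which(!ev$event %in% GAIT_EVENTS)[1]))
    if (!all(ev$condition %in% CONDITIONS))
      msg <- c(msg, sprintf("unknown condition label at row %d",
                            which(!ev$condition %in% CONDITIONS)[1]))
    if (nrow(ev) > 1L) {
      if (any(diff(ev$time_s) <= 0))
        msg <- c(msg, sprintf("times not strictly increasing at row %d",
                              which(diff(ev$time_s) <= 0)[1] + 1L))
      if (all(ev$event %in% GAIT_EVENTS)) {
        expected <- .EVENT_SUCCESSOR[ev$event[-nrow(ev)]]
        bad <- which(ev$event[-1L] != expected)
        if (length(bad))
          msg <- c(msg, sprintf(
            "event grammar violated at row %d: %s cannot follow %s",
            bad[1] + 1L, ev$event[bad[1] + 1L], ev$event[bad[1]]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GaitEvents table
#'
#' @param time_s event times in seconds (strictly increasing), or a
#'   data.frame with columns time_s, event, condition.
#' @param event event labels in \{LC, RO, RC, LO\}.
#' @param condition condition labels in \{FF, FU, UF\}, recycled.
#' @return A \linkS4class{GaitEvents}.
#' @export
GaitEvents <- function(time_s, event = NULL, condition = NULL) {
  if (is.data.frame(time_s)) {
    ev <- time_s
  } else {
    ev <- data.frame(time_s = as.numeric(time_s),
                     event = as.character(event),
                     condition = rep_len(as.character(condition),
                                         length(time_s)))
  }
  ev$time_s <- as.numeric(ev$time_s)
  rownames(ev) <- NULL
  new("GaitEvents", events = ev)
}

#' EpochSet: event-locked EEG segments
#'
#' Epochs cut around the right-paw-contact (RC) event; by default each epoch
#' starts 1 s before RC and lasts 2.5 s (1250 samples at 500 Hz), covering
#' two preparation phases and one complete walking phase.
#'
#' @slot data numeric array, epochs x channels x samples.
#' @slot rate sampling rate, Hz.
#' @slot t0Offset epoch start relative to the alignment event, seconds.
#' @slot condition condition label per epoch.
#' @slot channelNames channel labels.
#' @slot regionMap channel -> region map.
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    rate = "numeric",
    t0Offset = "numeric",
    condition = "character",
    channelNames = "character",
    regionMap = "character"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    return("data must be a 3-d array (epochs x channels x samples)")
  if (d[1] != length(object@condition))
    msg <- c(msg, "one condition label per epoch required")
  if (d[2] != length(object@channelNames))
    msg <- c(msg, "one channel name per channel required")
  if (length(msg)) msg else TRUE
})

#' WindowGrid: sliding-window layout over an epoch
#'
#' 250-ms windows advanced in 125-ms steps (50% overlap) over a 2.5-s epoch
#' give 19 windows; over a 750-ms preparation segment, 5 windows.
#'
#' @slot winLen window length, seconds.
#' @slot step step between window starts, seconds (half the window length).
#' @slot epochLen epoch length the grid was built for, seconds.
#' @slot offsets window start offsets relative to epoch start, seconds.
#' @export
setClass("WindowGrid",
  representation(winLen = "numeric", step = "numeric",
                 epochLen = "numeric", offsets = "numeric")
)

setValidity("WindowGrid", function(object) {
  msg <- character()
  if (object@winLen <= 0 || object@step <= 0 || object@epochLen <= 0)
    msg <- c(msg, "winLen, step and epochLen must be positive")
  if (abs(object@step - object@winLen / 2) > 1e-9)
    msg <- c(msg, "step must be half the window length (50% overlap)")
  if (length(msg)) msg else TRUE
})

#' Build a WindowGrid
#'
#' @param epochLen epoch length, seconds.
#' @param winLen window length, seconds (default 0.25).
#' @param step step, seconds (default 0.125, i.e. 50\% overlap).
#' @return A \linkS4class{WindowGrid}; the number of windows is
#'   \code{floor((epochLen - winLen)/step) + 1}.
#' @examples
#' nWindows(windowGrid(2.5))   # 19
#' nWindows(windowGrid(0.75))  # 5
#' @export
windowGrid <- function(epochLen, winLen = 0.25, step = winLen / 2) {
  if (epochLen < winLen)
    stop("epoch (", epochLen, " s) shorter than window (", winLen, " s)")
  n <- floor((epochLen - winLen) / step + 1e-9) + 1L
  new("WindowGrid", winLen = winLen, step = step, epochLen = epochLen,
      offsets = (seq_len(n) - 1L) * step)
}

#' ConnectivityTensor: windowed PLI values
#'
#' @slot values numeric array, epochs x windows x channels x channels,
#'   each slice symmetric with zero diagonal, entries in [0, 1].
#' @slot grid the \linkS4class{WindowGrid} used.
#' @slot condition condition label per epoch.
#' @slot channelNames channel labels.
#' @export
setClass("ConnectivityTensor",
  representation(values = "array", grid = "WindowGrid",
                 condition = "character", channelNames = "character")
)

setValidity("ConnectivityTensor", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 4L)
    return("values must be epochs x windows x channels x channels")
  if (d[3] != d[4]) msg <- c(msg, "channel dimensions must match")
  if (d[1] != length(object@condition))
    msg <- c(msg, "one condition label per epoch required")
  if (length(object@values)) {
    rng <- range(object@values)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "PLI values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' PhaseConnectivity: gait-phase-collapsed PLI
#'
#' One 32 x 32 PLI matrix per epoch per gait phase, in the order
#' LC->RO (preparation), RO->RC, RC->LO, LO->LC.
#'
#' @slot values numeric array, epochs x 4 x channels x channels.
#' @slot phases phase labels (third dimension order).
#' @slot condition condition label per epoch.
#' @slot channelNames channel labels.
#' @export
setClass("PhaseConnectivity",
  representation(values = "array", phases = "character",
                 condition = "character", channelNames = "character")
)

setValidity("PhaseConnectivity", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 4L)
    return("values must be epochs x phases x channels x channels")
  if (d[2] != length(object@phases))
    msg <- c(msg, "one label per phase required")
  if (d[1] != length(object@condition))
    msg <- c(msg, "one condition label per epoch required")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic-recording configuration
#'
#' Describes a population of phase-lag-coupled narrow-band oscillators on a
#' 32-channel, 6-region grid, with coupling strengths that switch with gait
#' phase and locomotion condition. Each coupled channel pair shares a
#' narrow-band source; the second channel receives it with a fixed nonzero
#' time lag so the pair has a consistent nonzero phase difference, which is
#' what the phase-lag index detects (a zero lag would yield PLI 0).
#'
#' @slot nChannels number of channels.
#' @slot samplingRate raw sampling rate, Hz.
#' @slot regions named character vector channel -> region.
#' @slot nEpochsPerCondition gait cycles (hence epochs) per condition.
#' @slot carrierFreq oscillator carrier frequency, Hz, strictly inside the
#'   3-50 Hz analysis band.
#' @slot coupling numeric array, condition x phase x channel x channel, in
#'   [0, 1], symmetric with zero diagonal.
#' @slot lag channel x channel matrix of source time lags, seconds; nonzero
#'   wherever coupling is nonzero.
#' @slot noiseSigma additive white-noise SD, signal units.
#' @slot driftSD Wiener phase-drift SD, rad/sqrt(s).
#' @slot backgroundAmp amplitude of each channel's private background
#'   oscillator (0 disables).
#' @slot backgroundBand frequency band (Hz) from which each private
#'   background oscillator draws its carrier.
#' @slot lineAmp amplitude of an optional 50 Hz line-noise tone.
#' @slot seed RNG seed.
#' @export
setClass("SimConfig",
  representation(
    nChannels = "integer", samplingRate = "numeric", regions = "character",
    nEpochsPerCondition = "integer", carrierFreq = "numeric",
    coupling = "array", lag = "matrix", noiseSigma = "numeric",
    driftSD = "numeric", backgroundAmp = "numeric",
    backgroundBand = "numeric", lineAmp = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  nc <- object@nChannels
  if (length(object@regions) != nc)
    msg <- c(msg, "regions must map every channel")
  if (!all(object@regions %in% REGIONS))
    msg <- c(msg, paste("region labels must be in",
                        paste(REGIONS, collapse = "/")))
  if (object@carrierFreq <= 3 || object@carrierFreq >= 50)
    msg <- c(msg, "carrierFreq must lie strictly inside the 3-50 Hz band")
  d <- dim(object@coupling)
  if (length(d) != 4L || d[1] != length(CONDITIONS) ||
      d[2] != length(GAIT_PHASES) || d[3] != nc || d[4] != nc) {
    msg <- c(msg, "coupling must be condition x phase x channel x channel")
  } else {
    if (min(object@coupling) < 0 || max(object@coupling) > 1)
      msg <- c(msg, "coupling strengths must lie in [0, 1]")
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      m <- object@coupling[i, j, , ]
      if (any(abs(m - t(m)) > 1e-12) || any(diag(m) != 0)) {
        msg <- c(msg, "coupling slices must be symmetric with zero diagonal")
        break
      }
    }
    cmax <- apply(object@coupling, c(3, 4), max)
    if (any(cmax > 0 & object@lag == 0))
      msg <- c(msg, "every coupled pair needs a nonzero lag (zero lag gives PLI 0)")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(object@backgroundBand) != 2L ||
      object@backgroundBand[1] < 3 || object@backgroundBand[2] > 50 ||
      object@backgroundBand[1] >= object@backgroundBand[2])
    msg <- c(msg, "backgroundBand must be an increasing pair inside [3, 50]")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generative coupling and the schedule actually generated
#'
#' @slot coupling condition x phase x channel x channel generative coupling.
#' @slot schedule the \linkS4class{GaitEvents} used to drive the simulation.
#' @export
setClass("GroundTruth",
  representation(coupling = "array", schedule = "GaitEvents"))

#' FeatureSet: a classifier-ready feature matrix
#'
#' @slot matrix epochs x dim feature matrix (no missing values).
#' @slot labels condition label per epoch.
#' @slot family feature family identifier.
#' @export
setClass("FeatureSet",
  representation(matrix = "matrix", labels = "character", family = "character"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (nrow(object@matrix) != length(object@labels))
    msg <- c(msg, "one label per row required")
  if (anyNA(object@matrix)) msg <- c(msg, "feature matrix contains NA")
  if (length(msg)) msg else TRUE
})
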