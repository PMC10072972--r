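#' @include AllGenerics.R
NULL

# idealized gait-phase durations, seconds: preparation then three walking
# sub-phases (LC->RO, RO->RC, RC->LO, LO->LC)
.PHASE_DUR <- c(0.75, 0.25, 0.25, 0.25)
.CYCLE_LEN <- sum(.PHASE_DUR)

#' Default channel-to-region map for the 32-electrode grid
#'
#' Six cortical regions: left/right somatomotor (LMO, RMO), left/right
#' somatosensory (LSS, RSS), retrosplenial (RSP) and visual (VIS) areas.
#'
#' @param nChannels number of channels (default 32).
#' @return named character vector, channel name -> region label.
#' @export
defaultRegionMap <- function(nChannels = 32L) {
  if (nChannels != 32L)
    stop("the default region layout is defined for 32 channels")
  regions <- rep(REGIONS, times = c(6, 6, 6, 6, 4, 4))
  names(regions) <- sprintf("CH%02d", seq_len(nChannels))
  regions
}

#' Default phase- and condition-dependent coupling profiles
#'
#' A condition x phase x channel x channel array of coupling strengths in
#' [0, 1] emulating the qualitative connectivity structure of bipedal
#' locomotion on intermittently uneven terrain: strong motor-retrosplenial
#' coupling during the preparation phase in all conditions, sustained
#' right-motor-retrosplenial coupling during the right-limb swing, a
#' somatosensory burst after unexpected contact with uneven terrain
#' (condition FU, phase RC->LO), and globally weakened coupling when the
#' upcoming terrain is predictable (condition UF, late phases).
#'
#' @param regions named channel -> region map (default
#'   \code{defaultRegionMap()}).
#' @return numeric array, 3 x 4 x n x n, dimnames condition/phase/channel.
#' @export
defaultCouplingProfiles <- function(regions = defaultRegionMap()) {
  nc <- length(regions)
  cp <- array(0, dim = c(length(CONDITIONS), length(GAIT_PHASES), nc, nc),
              dimnames = list(CONDITIONS, GAIT_PHASES,
                              names(regions), names(regions)))
  first <- function(reg) which(regions == reg)[1:2]
  lmo <- first("LMO"); rmo <- first("RMO"); lss <- first("LSS")
  rss <- first("RSS"); rsp <- first("RSP"); vis <- first("VIS")

  set_pair <- function(cond, phase, i, j, w) {
    cp[cond, phase, i, j] <<- w
    cp[cond, phase, j, i] <<- w
  }
  for (cond in CONDITIONS) {
    # preparation: bilateral motor and motor-retrosplenial coupling
    set_pair(cond, "LC->RO", lmo[1], rsp[1], 0.80)
    set_pair(cond, "LC->RO", rmo[1], rsp[1], 0.90)
    set_pair(cond, "LC->RO", lmo[2], rmo[2], 0.70)
    # right-limb swing: right motor - retrosplenial stays high
    set_pair(cond, "RO->RC", rmo[1], rsp[1], 0.80)
    set_pair(cond, "RO->RC", rmo[2], rss[1], 0.50)
  }
  # after right-paw contact: somatosensory involvement differs by terrain
  set_pair("FF", "RC->LO", lss[1], rsp[2], 0.30)
  set_pair("FU", "RC->LO", lss[1], rsp[2], 0.85)
  set_pair("UF", "RC->LO", lss[1], rsp[2], 0.55)
  for (cond in CONDITIONS)
    set_pair(cond, "RC->LO", rmo[1], rsp[1], 0.50)
  # left-limb swing: weak when the upcoming terrain is predictable (UF)
  set_pair("FF", "LO->LC", lss[2], rsp[1], 0.70)
  set_pair("FU", "LO->LC", lss[2], rsp[1], 0.50)
  set_pair("UF", "LO->LC", lss[2], rsp[1], 0.15)
  set_pair("FF", "LO->LC", rmo[1], rsp[2], 0.30)
  set_pair("FU", "LO->LC", rmo[1], rsp[2], 0.60)
  set_pair("UF", "LO->LC", rmo[1], rsp[2], 0.20)
  # visual area: faint constant coupling, identical across conditions
  for (cond in CONDITIONS) for (ph in GAIT_PHASES)
    set_pair(cond, ph, vis[1], vis[2], 0.20)
  cp
}

#' Build a simulation configuration
#'
#' @param nChannels number of channels (default 32).
#' @param samplingRate raw sampling rate, Hz (default 2000).
#' @param regions named channel -> region map.
#' @param nEpochsPerCondition gait cycles per condition (default 20).
#' @param carrierFreq oscillator carrier, Hz, strictly inside 3-50 (default 8).
#' @param coupling condition x phase x channel x channel strengths in [0, 1].
#' @param lag per-pair source time lag in seconds: either a single number
#'   applied to every coupled pair (default a quarter carrier cycle, the
#'   PLI-maximal lag) or a full channel x channel matrix. Must be nonzero
#'   for every coupled pair.
#' @param noiseSigma additive white-noise SD (default 0.15).
#' @param driftSD Wiener phase-drift SD, rad/sqrt(s) (default 3.5). Coupled
#'   pairs are immune to drift (shared between the two copies of their
#'   source), while independent sources decorrelate across windows.
#' @param backgroundAmp amplitude of each channel's private oscillator
#'   (default 0.3; set 0 for analytically clean two-channel tests).
#' @param backgroundBand band (Hz) from which each private background
#'   oscillator draws its carrier (default c(4, 30)): distinct carriers
#'   make the phase difference of uncoupled channels sweep several cycles
#'   per window, keeping the null PLI low, whereas every coupled pair
#'   shares the single fixed \code{carrierFreq} so its PLI target is
#'   unaffected.
#' @param lineAmp optional 50 Hz line-tone amplitude (default 0).
#' @param seed RNG seed (default 1).
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nChannels = 32L,
                      samplingRate = 2000,
                      regions = defaultRegionMap(nChannels),
                      nEpochsPerCondition = 20L,
                      carrierFreq = 8,
                      coupling = defaultCouplingProfiles(regions),
                      lag = 1 / (4 * carrierFreq),
                      noiseSigma = 0.15,
                      driftSD = 3.5,
                      backgroundAmp = 0.3,
                      backgroundBand = c(4, 30),
                      lineAmp = 0,
                      seed = 1L) {
  nChannels <- as.integer(nChannels)
  if (is.null(names(regions)))
    names(regions) <- sprintf("CH%02d", seq_len(nChannels))
  if (length(lag) == 1L)
    lag <- matrix(lag, nChannels, nChannels)
  dimnames(coupling) <- list(CONDITIONS, GAIT_PHASES,
                             names(regions), names(regions))
  new("SimConfig", nChannels = nChannels,
      samplingRate = as.numeric(samplingRate), regions = regions,
      nEpochsPerCondition = as.integer(nEpochsPerCondition),
      carrierFreq = as.numeric(carrierFreq), coupling = coupling,
      lag = lag, noiseSigma = as.numeric(noiseSigma),
      driftSD = as.numeric(driftSD),
      backgroundAmp = as.numeric(backgroundAmp),
      backgroundBand = as.numeric(backgroundBand),
      lineAmp = as.numeric(lineAmp), seed = as.integer(seed))
}

#' Generate an idealized gait schedule
#'
#' Produces the repeating event sequence LC, RO, RC, LO with the idealized
#' intervals 750, 250, 250 and 250 ms (preparation phase then three walking
#' sub-phases), one condition label per cycle. Only complete 1.5-s cycles
#' are emitted.
#'
#' @param config a \linkS4class{SimConfig} (supplies condition labels; the
#'   draw of random conditions uses the current RNG state).
#' @param duration_s schedule duration, seconds; must be positive.
#' @param conditions optional condition label per cycle (recycled); when
#'   NULL, conditions are drawn uniformly at random.
#' @param jitter_s optional uniform jitter (+/- jitter_s) added to the
#'   interior event times of each cycle (default 0, the idealized schedule).
#' @return A \linkS4class{GaitEvents}; empty (with a warning) when
#'   \code{duration_s} is below one full cycle.
#' @export
generateGaitSchedule <- function(config, duration_s, conditions = NULL,
                                 jitter_s = 0) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  nCycles <- floor(duration_s / .CYCLE_LEN + 1e-9)
  if (nCycles < 1) {
    warning("duration below one full gait cycle (1.5 s); empty schedule")
    return(GaitEvents(data.frame(time_s = numeric(), event = character(),
                                 condition = character())))
  }
  if (is.null(conditions)) {
    conditions <- sample(CONDITIONS, nCycles, replace = TRUE)
  } else {
    conditions <- rep_len(as.character(conditions), nCycles)
  }
  starts <- (seq_len(nCycles) - 1L) * .CYCLE_LEN
  offs <- cumsum(c(0, .PHASE_DUR[1:3]))   # LC, RO, RC, LO within a cycle
  time_s <- rep(starts, each = 4L) + rep(offs, nCycles)
  if (jitter_s > 0) {
    j <- stats::runif(length(time_s), -jitter_s, jitter_s)
    j[seq(1, length(time_s), by = 4L)] <- 0  # keep cycle anchors fixed
    time_s <- time_s + j
  }
  GaitEvents(data.frame(
    time_s = time_s,
    event = rep(GAIT_EVENTS, nCycles),
    condition = rep(conditions, each = 4L)))
}

# per-sample (phase index, condition index) from a schedule; samples beyond
# the last event continue as the preparation phase of a notional next cycle
.phaseAtSamples <- function(schedule, times, condTail = CONDITIONS[1]) {
  ev <- gaitEvents(schedule)
  phase <- integer(length(times))
  cond <- integer(length(times))
  phaseOfEvent <- match(ev$event, GAIT_EVENTS)  # event k opens phase k
  idx <- findInterval(times, ev$time_s)
  inside <- idx >= 1L
  phase[inside] <- phaseOfEvent[idx[inside]]
  cond[inside] <- match(ev$condition[idx[inside]], CONDITIONS)
  if (any(!inside)) {  # before the first LC: treat as preparation
    phase[!inside] <- 1L
    cond[!inside] <- match(ev$condition[1], CONDITIONS)
  }
  after <- times >= ev$time_s[nrow(ev)] + .PHASE_DUR[phaseOfEvent[nrow(ev)]]
  if (any(after)) {
    phase[after] <- 1L
    cond[after] <- match(condTail, CONDITIONS)
  }
  list(phase = phase, cond = cond)
}

# narrow-band oscillator: carrier + slow Wiener phase drift. The drift is a
# Wiener process on a coarse 25-Hz knot grid, linearly interpolated, so its
# slope (instantaneous-frequency deviation) stays well below the carrier
# and the analytic-signal phase remains a faithful estimate of the
# generative phase. The returned closure evaluates the source with an
# optional time lag applied to the carrier term only, with the drift common
# to every copy: a lagged copy is therefore locked to the original at a
# phase difference of exactly 2*pi*carrier*lag.
.DRIFT_KNOT_HZ <- 25

.makeSource <- function(times, carrier, driftSD, phi0) {
  kt <- seq(0, times[length(times)] + 1 / .DRIFT_KNOT_HZ,
            by = 1 / .DRIFT_KNOT_HZ)
  kd <- cumsum(stats::rnorm(length(kt), 0, driftSD / sqrt(.DRIFT_KNOT_HZ)))
  drift <- stats::approx(kt, kd, xout = times, rule = 2)$y
  function(lag = 0) cos(2 * pi * carrier * (times - lag) + phi0 + drift)
}

#' Simulate a phase-lag-coupled multichannel recording
#'
#' Generates a gait schedule, then synthesizes each channel as a mixture of
#' narrow-band sources: every coupled channel pair shares a source that the
#' first channel receives directly and the second with the configured time
#' lag applied to the carrier (drift common to both copies, so the pair is
#' phase-locked at exactly 2 pi * carrier * lag), scaled per sample by the
#' coupling strength of the current gait phase and condition. Each channel
#' additionally carries a private background oscillator (amplitude
#' \code{backgroundAmp}), optional 50 Hz line tone, and white Gaussian
#' noise. Fully reproducible under the config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param conditions optional condition label per cycle (recycled);
#'   default: a balanced, shuffled sequence with
#'   \code{nEpochsPerCondition} cycles per condition.
#' @return A list with elements \code{recording}
#'   (\linkS4class{EEGRecording}), \code{schedule}
#'   (\linkS4class{GaitEvents}) and \code{groundTruth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateRecording <- function(config, conditions = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nc <- config@nChannels
  rate <- config@samplingRate

  nCycles <- config@nEpochsPerCondition * length(CONDITIONS)
  if (is.null(conditions))
    conditions <- sample(rep(CONDITIONS, config@nEpochsPerCondition))
  conditions <- rep_len(conditions, nCycles)
  # lead-out of 1 s so the last cycle's RC epoch fits entirely
  duration <- nCycles * .CYCLE_LEN + 1.0
  n <- floor(duration * rate)
  times <- (seq_len(n) - 1L) / rate

  schedule <- generateGaitSchedule(config, nCycles * .CYCLE_LEN, conditions)
  pc <- .phaseAtSamples(schedule, times, condTail = conditions[1])

  data <- matrix(0, nc, n)
  cmax <- apply(config@coupling, c(3, 4), max)
  pairs <- which(upper.tri(cmax) & cmax > 0, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    src <- .makeSource(times, config@carrierFreq, config@driftSD,
                       stats::runif(1, 0, 2 * pi))
    # per-sample coupling strength from (condition, phase) at each sample
    m <- config@coupling[cbind(pc$cond, pc$phase,
                               rep(i, n), rep(j, n))]
    data[i, ] <- data[i, ] + m * src(0)
    data[j, ] <- data[j, ] + m * src(config@lag[i, j])
  }
  if (config@backgroundAmp > 0) {
    # background activity: sum of a few independently drifting tones with
    # carriers spread across the band, so uncoupled channel pairs have a
    # fast-moving phase difference and a low, stable null PLI
    nTones <- 3L
    for (ch in seq_len(nc)) {
      for (k in seq_len(nTones)) {
        bg <- .makeSource(times,
                          stats::runif(1, config@backgroundBand[1],
                                       config@backgroundBand[2]),
                          config@driftSD, stats::runif(1, 0, 2 * pi))
        data[ch, ] <- data[ch, ] +
          config@backgroundAmp / sqrt(nTones) * bg(0)
      }
    }
  }
  if (config@lineAmp > 0)
    data <- data + rep(config@lineAmp * sin(2 * pi * 50 * times),
                       each = nc)
  if (config@noiseSigma > 0)
    data <- data + matrix(stats::rnorm(nc * n, 0, config@noiseSigma), nc, n)

  rec <- EEGRecording(data, rate, names(config@regions), config@regions)
  list(recording = rec, schedule = schedule,
       groundTruth = new("GroundTruth", coupling = config@coupling,
                         schedule = schedule))
}
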