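# Fixture builders; everything is generated in code at test time.

# two channels sharing one source; coupling constant across phases and
# conditions so the signal is stationary
twoChannelConfig <- function(coupling = 0.9, noiseSigma = 0,
                             backgroundAmp = 0, driftSD = 0,
                             nEpochsPerCondition = 2L, seed = 3L,
                             lag = NULL) {
  cp <- array(0, dim = c(3, 4, 2, 2))
  cp[, , 1, 2] <- coupling
  cp[, , 2, 1] <- coupling
  args <- list(nChannels = 2L, samplingRate = 500,
               regions = c(CH01 = "LMO", CH02 = "RMO"),
               nEpochsPerCondition = as.integer(nEpochsPerCondition),
               coupling = cp, noiseSigma = noiseSigma,
               backgroundAmp = backgroundAmp, driftSD = driftSD,
               seed = as.integer(seed))
  if (!is.null(lag)) args$lag <- lag
  do.call(simConfig, args)
}

# eight channels with four designated pairs whose coupling is graded across
# the four gait phases (0.9 / 0.6 / 0.3 / 0 rotations), identical across
# conditions; used for parameter-recovery checks
gradedRecoveryConfig <- function(seed = 11L, nEpochsPerCondition = 6L,
                                 noiseSigma = 0.15) {
  grades <- rbind(c(0.9, 0.6, 0.3, 0.0),
                  c(0.0, 0.9, 0.6, 0.3),
                  c(0.3, 0.0, 0.9, 0.6),
                  c(0.6, 0.3, 0.0, 0.9))
  cp <- array(0, dim = c(3, 4, 8, 8))
  for (p in 1:4) for (ph in 1:4) {
    cp[, ph, p, p + 4] <- grades[p, ph]
    cp[, ph, p + 4, p] <- grades[p, ph]
  }
  simConfig(nChannels = 8L, samplingRate = 500,
            regions = stats::setNames(
              c("LMO", "RMO", "LSS", "RSS", "RSP", "VIS", "LMO", "RMO"),
              sprintf("CH%02d", 1:8)),
            nEpochsPerCondition = as.integer(nEpochsPerCondition),
            coupling = cp, noiseSigma = noiseSigma, seed = as.integer(seed))
}

designatedPairs <- function() cbind(i = 1:4, j = 5:8)

gradedCouplings <- function() rbind(c(0.9, 0.6, 0.3, 0.0),
                                    c(0.0, 0.9, 0.6, 0.3),
                                    c(0.3, 0.0, 0.9, 0.6),
                                    c(0.6, 0.3, 0.0, 0.9))

# simulate -> preprocess -> epoch -> windowed PLI -> phase collapse
runToPhases <- function(config) {
  sim <- simulateRecording(config)
  rec <- preprocessRecording(sim$recording,
                             target_hz = samplingRate(sim$recording))
  ep <- suppressMessages(extractEpochs(rec, sim$schedule))
  pc <- collapsePhases(slidingPLI(ep))
  list(sim = sim, epochs = ep, phases = pc,
       average = conditionAverage(pc))
}

# pooled recovery statistics for the graded config: Spearman rank agreement
# between generative coupling and estimated phase-collapsed PLI over the
# designated (pair, phase) grid, plus the coupled-vs-uncoupled margin
recoveryStats <- function(avg) {
  pairs <- designatedPairs()
  grades <- gradedCouplings()
  truth <- c(); est <- c()
  for (p in 1:4) for (ph in 1:4) {
    truth <- c(truth, grades[p, ph])
    est <- c(est, mean(avg[, ph, pairs[p, 1], pairs[p, 2]]))
  }
  coupled <- c(); uncoupled <- c()
  des <- matrix(FALSE, 8, 8)
  des[pairs] <- TRUE; des[pairs[, 2:1]] <- TRUE
  for (ph in 1:4) {
    M <- apply(avg[, ph, , , drop = FALSE], c(3, 4), mean)
    for (p in 1:4)
      if (grades[p, ph] >= 0.6)
        coupled <- c(coupled, M[pairs[p, 1], pairs[p, 2]])
    uncoupled <- c(uncoupled, M[upper.tri(M)][!des[upper.tri(des)]])
  }
  list(rho = stats::cor(truth, est, method = "spearman"),
       margin = mean(coupled) - mean(uncoupled))
}

# random, structurally valid PhaseConnectivity for shape/feature tests
randomPhaseConnectivity <- function(nEpochs = 6L, nCh = 32L,
                                    conditions = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(conditions))
    conditions <- rep_len(c("FF", "FU", "UF"), nEpochs)
  v <- array(0, dim = c(nEpochs, 4, nCh, nCh))
  for (e in seq_len(nEpochs)) for (p in 1:4) {
    M <- matrix(runif(nCh * nCh), nCh, nCh)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    v[e, p, , ] <- M
  }
  new("PhaseConnectivity", values = v,
      phases = c("LC->RO", "RO->RC", "RC->LO", "LO->LC"),
      condition = conditions, channelNames = sprintf("CH%02d", seq_len(nCh)))
}

# random EpochSet at 500 Hz with the standard 2.5-s epoch
randomEpochSet <- function(nEpochs = 6L, nCh = 32L, seed = 1L) {
  set.seed(seed)
  new("EpochSet",
      data = array(rnorm(nEpochs * nCh * 1250), c(nEpochs, nCh, 1250)),
      rate = 500, t0Offset = -1,
      condition = rep_len(c("FF", "FU", "UF"), nEpochs),
      channelNames = sprintf("CH%02d", seq_len(nCh)),
      regionMap = stats::setNames(
        rep_len(c("LMO", "RMO", "LSS", "RSS", "RSP", "VIS"), nCh),
        sprintf("CH%02d", seq_len(nCh))))
}

# three well-separated Gaussian blobs as a FeatureSet; every dimension is
# informative so the separation survives per-feature standardization
blobFeatures <- function(nPerClass = 20L, dim = 10L, sep = 3, seed = 9L) {
  set.seed(seed)
  centers <- rbind(rep(0, dim), rep(sep, dim),
                   rep(c(sep, -sep), length.out = dim))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(nPerClass * dim), nPerClass), 2, centers[k, ], "+")))
  new("FeatureSet", matrix = x,
      labels = rep(c("FF", "FU", "UF"), each = nPerClass),
      family = "blobs")
}
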