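test_that("gait schedule has the idealized cycle geometry", {
  cfg <- twoChannelConfig()
  set.seed(1)
  sch <- generateGaitSchedule(cfg, 3.0)
  ev <- gaitEvents(sch)
  expect_equal(nrow(ev), 8L)  # two complete cycles, four events each
  expect_equal(ev$event, rep(c("LC", "RO", "RC", "LO"), 2))
  # with LC at 0: RO at 0.75, RC at 1.00, LO at 1.25, next LC at 1.50
  expect_equal(ev$time_s[1:5], c(0, 0.75, 1.00, 1.25, 1.50))
  expect_equal(diff(ev$time_s), rep(c(0.75, 0.25, 0.25, 0.25), length.out = 7))
  # every event in a cycle shares the cycle's condition
  expect_true(all(tapply(ev$condition, rep(1:2, each = 4),
                         function(x) length(unique(x))) == 1))
})

test_that("schedules below one cycle are empty with a warning, bad durations error", {
  cfg <- twoChannelConfig()
  expect_warning(sch <- generateGaitSchedule(cfg, 1.4), "below one full")
  expect_equal(nrow(gaitEvents(sch)), 0L)
  expect_error(generateGaitSchedule(cfg, 0), "positive")
  expect_error(generateGaitSchedule(cfg, -2), "positive")
})

test_that("caller-given condition sequences are honoured", {
  cfg <- twoChannelConfig()
  sch <- generateGaitSchedule(cfg, 4.5, conditions = c("FF", "FU", "UF"))
  ev <- gaitEvents(sch)
  expect_equal(unique(ev$condition[1:4]), "FF")
  expect_equal(unique(ev$condition[5:8]), "FU")
  expect_equal(unique(ev$condition[9:12]), "UF")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- gradedRecoveryConfig(seed = 21L, nEpochsPerCondition = 2L)
  a <- simulateRecording(cfg)
  b <- simulateRecording(cfg)
  expect_identical(channelData(a$recording), channelData(b$recording))
  expect_identical(gaitEvents(a$schedule), gaitEvents(b$schedule))
  cfg2 <- gradedRecoveryConfig(seed = 22L, nEpochsPerCondition = 2L)
  expect_false(identical(channelData(a$recording),
                         channelData(simulateRecording(cfg2)$recording)))
})

test_that("a noiseless quarter-cycle-lagged pair is completely phase locked", {
  # drift 0: both channels are pure stationary cosines pi/2 apart
  cfg <- twoChannelConfig(coupling = 0.9, driftSD = 0)
  sim <- simulateRecording(cfg)
  ep <- suppressMessages(extractEpochs(sim$recording, sim$schedule))
  pli <- channelData(slidingPLI(ep))[, , 1, 2]
  expect_true(all(abs(pli - 1) < 1e-9))
  # with default drift (shared between the pair) the lock survives
  cfg2 <- twoChannelConfig(coupling = 0.9, driftSD = 3.5, seed = 3L)
  sim2 <- simulateRecording(cfg2)
  ep2 <- suppressMessages(extractEpochs(sim2$recording, sim2$schedule))
  pli2 <- channelData(slidingPLI(ep2))[, , 1, 2]
  expect_gt(min(pli2), 0.9)
  expect_gt(mean(pli2), 0.97)
})

test_that("uncoupled channels with independent sources sit at the null PLI level", {
  # Monte-Carlo-established null for 250-ms windows of independent
  # drifting multi-tone oscillators: ~0.25, far below the coupled level;
  # the window estimator's floor (~0.22 even for band-passed white noise)
  # keeps it above zero
  cfg <- twoChannelConfig(coupling = 0, noiseSigma = 0, backgroundAmp = 1,
                          driftSD = 3.5, nEpochsPerCondition = 12L,
                          seed = 0L)
  sim <- simulateRecording(cfg)
  ep <- suppressMessages(extractEpochs(sim$recording, sim$schedule))
  nullPLI <- mean(channelData(slidingPLI(ep))[, , 1, 2])
  expect_lt(nullPLI, 0.35)
  coupled <- twoChannelConfig(coupling = 0.9, driftSD = 3.5, seed = 0L)
  simC <- simulateRecording(coupled)
  epC <- suppressMessages(extractEpochs(simC$recording, simC$schedule))
  expect_gt(mean(channelData(slidingPLI(epC))[, , 1, 2]) - nullPLI, 0.5)
})

test_that("invalid simulation configurations are rejected", {
  cp <- array(0, dim = c(3, 4, 2, 2))
  cp[, , 1, 2] <- cp[, , 2, 1] <- 1.5
  expect_error(simConfig(nChannels = 2L, regions = c(CH01 = "LMO", CH02 = "RMO"),
                         coupling = cp), "\\[0, 1\\]")
  cp[, , 1, 2] <- cp[, , 2, 1] <- 0.5
  expect_error(simConfig(nChannels = 2L, regions = c(CH01 = "LMO", CH02 = "RMO"),
                         coupling = cp, lag = 0), "nonzero lag")
  expect_error(simConfig(nChannels = 2L, regions = c(CH01 = "LMO", CH02 = "RMO"),
                         coupling = cp, carrierFreq = 55), "3-50")
  asym <- cp; asym[1, 1, 1, 2] <- 0.9
  expect_error(simConfig(nChannels = 2L, regions = c(CH01 = "LMO", CH02 = "RMO"),
                         coupling = asym), "symmetric")
})

test_that("ground truth mirrors the generative configuration", {
  cfg <- gradedRecoveryConfig(nEpochsPerCondition = 2L)
  sim <- simulateRecording(cfg)
  gt <- sim$groundTruth
  expect_identical(couplingProfiles(gt), couplingProfiles(cfg))
  expect_identical(gaitEvents(gt), gaitEvents(sim$schedule))
  for (ci in 1:3) for (ph in 1:4) {
    M <- couplingProfiles(gt)[ci, ph, , ]
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 0))
  }
})

test_that("default coupling profiles vary with gait phase and condition", {
  cp <- defaultCouplingProfiles()
  # preparation coupling identical across conditions
  expect_equal(cp["FF", "LC->RO", , ], cp["FU", "LC->RO", , ])
  # somatosensory burst after unexpected uneven contact differs by terrain
  expect_false(isTRUE(all.equal(cp["FF", "RC->LO", , ], cp["FU", "RC->LO", , ])))
  expect_true(all(cp >= 0 & cp <= 1))
})
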