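test_that("instantaneous phase tracks an analytic cosine", {
  rate <- 500
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)  # integer number of 8 Hz cycles
  x <- cos(2 * pi * 8 * t)
  ph <- instantaneousPhase(x)
  # unwrapped phase advances at 2*pi*8 rad/s
  slope <- mean(gaitpli:::.wrapPhase(diff(ph))) * rate
  expect_equal(slope, 2 * pi * 8, tolerance = 1e-6)
  # quadrature pair: constant difference of pi/2 away from the edges
  y <- sin(2 * pi * 8 * t)
  d <- gaitpli:::.wrapPhase(ph[100:900] - instantaneousPhase(y)[100:900])
  expect_equal(d, rep(pi / 2, length(d)), tolerance = 1e-6)
  # amplitude scaling leaves phases unchanged
  expect_equal(instantaneousPhase(10 * x), ph, tolerance = 1e-9)
  expect_error(instantaneousPhase(c(1, NA, 3, 4, 5, 6, 7, 8)), "finite")
  expect_error(instantaneousPhase(1:4), "8 samples")
})

test_that("pliPair matches its defining formula", {
  expect_equal(pliPair(rep(1.3, 50), rep(1.3, 50)), 0)   # sign(0) = 0
  expect_equal(pliPair(rep(pi / 2, 50), rep(0, 50)), 1)  # constant lag
  expect_error(pliPair(1:5, 1:4), "equal length")
  # brute-force oracle equality on random windows
  set.seed(7)
  for (rep in 1:100) {
    px <- runif(125, -pi, pi)
    py <- runif(125, -pi, pi)
    expect_equal(pliPair(px, py), refPLI(px, py), tolerance = 1e-12)
  }
})

test_that("pliPair is symmetric and invariant to raw amplitude scaling", {
  set.seed(8)
  x <- rnorm(500); y <- rnorm(500)
  px <- instantaneousPhase(x); py <- instantaneousPhase(y)
  expect_equal(pliPair(px, py), pliPair(py, px))
  for (c in c(0.1, 3, 250)) {
    expect_equal(instantaneousPhase(c * x), px, tolerance = 1e-9)
    expect_equal(pliPair(instantaneousPhase(c * x),
                         instantaneousPhase(y / c)), pliPair(px, py),
                 tolerance = 1e-9)
  }
})

test_that("window grids reproduce the standard window counts", {
  expect_equal(nWindows(windowGrid(2.5)), 19L)    # full epoch
  expect_equal(nWindows(windowGrid(0.75)), 5L)    # preparation segment
  expect_equal(windowOffsets(windowGrid(2.5))[c(1, 3, 5)],
               c(0, 0.25, 0.5))  # non-overlapping preparation windows
  expect_error(windowGrid(0.2), "shorter than")
  expect_error(windowGrid(2.5, winLen = 0.25, step = 0.1), "half the window")
})

test_that("sliding PLI slices are symmetric, zero-diagonal and within [0, 1]", {
  ep <- randomEpochSet(nEpochs = 3L, nCh = 6L, seed = 2L)
  tensor <- slidingPLI(ep)
  v <- channelData(tensor)
  expect_equal(dim(v), c(3L, 19L, 6L, 6L))
  for (e in 1:3) for (w in c(1, 10, 19)) {
    M <- v[e, w, , ]
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 0))
    expect_true(all(M >= 0 & M <= 1))
  }
  shortEp <- new("EpochSet", data = ep@data[, , 1:100, drop = FALSE],
                 rate = 500, t0Offset = -1, condition = ep@condition,
                 channelNames = ep@channelNames, regionMap = ep@regionMap)
  expect_error(slidingPLI(shortEp, windowGrid(2.5)), "longer than epoch")
})

test_that("windowed PLI equals a direct per-window evaluation", {
  ep <- randomEpochSet(nEpochs = 2L, nCh = 4L, seed = 3L)
  tensor <- slidingPLI(ep)
  for (e in 1:2) {
    ph <- instantaneousPhase(ep@data[e, , ])
    for (w in c(2, 7, 13)) {
      start <- floor(windowOffsets(tensor)[w] * 500) + 1
      sl <- start:(start + 124)
      for (i in 1:3) for (j in (i + 1):4)
        expect_equal(channelData(tensor)[e, w, i, j],
                     refPLI(ph[i, sl], ph[j, sl]), tolerance = 1e-12)
    }
  }
})

test_that("phase collapse averages preparation windows 1, 3, 5 and picks walking windows", {
  nCh <- 4L
  v <- array(0, dim = c(1, 19, nCh, nCh))
  plane <- function(x) { M <- matrix(x, nCh, nCh); diag(M) <- 0; M }
  # preparation windows carry constant planes 0.1 .. 0.5
  for (w in 1:5) v[1, w, , ] <- plane(w / 10)
  for (w in 6:19) v[1, w, , ] <- plane(0.9)
  tensor <- new("ConnectivityTensor", values = v, grid = windowGrid(2.5),
                condition = "FF", channelNames = sprintf("CH%02d", 1:nCh))
  pc <- collapsePhases(tensor)
  expect_equal(dim(channelData(pc)), c(1L, 4L, nCh, nCh))
  # mean of windows 1, 3, 5 -> (0.1 + 0.3 + 0.5)/3 = 0.3
  expect_equal(channelData(pc)[1, 1, 1, 2], 0.3)
  expect_equal(channelData(pc)[1, 2, 1, 2], 0.9)
  # identical preparation windows collapse to that same matrix
  v2 <- v; for (w in 1:5) v2[1, w, , ] <- plane(0.4)
  t2 <- new("ConnectivityTensor", values = v2, grid = windowGrid(2.5),
            condition = "FF", channelNames = sprintf("CH%02d", 1:nCh))
  expect_equal(channelData(collapsePhases(t2))[1, 1, , ], v2[1, 1, , ])
  # nonstandard grids are refused by name
  t3 <- new("ConnectivityTensor", values = v[, 1:5, , , drop = FALSE],
            grid = windowGrid(0.75), condition = "FF",
            channelNames = sprintf("CH%02d", 1:nCh))
  expect_error(collapsePhases(t3), "standard grid")
})

test_that("condition averaging preserves structure and handles missing groups", {
  pc <- randomPhaseConnectivity(nEpochs = 6L, nCh = 5L)
  avg <- conditionAverage(pc)
  expect_equal(dim(avg), c(3L, 4L, 5L, 5L))
  expect_equal(dimnames(avg)[[1]], c("FF", "FU", "UF"))
  # single epoch per condition: averages equal the inputs
  pc1 <- randomPhaseConnectivity(nEpochs = 3L, nCh = 5L,
                                 conditions = c("FF", "FU", "UF"))
  avg1 <- conditionAverage(pc1)
  expect_equal(avg1["FU", , , ], channelData(pc1)[2, , , ],
               ignore_attr = TRUE)
  # averaging preserves symmetry and range
  for (ci in 1:3) for (p in 1:4) {
    M <- avg[ci, p, , ]
    expect_equal(M, t(M), ignore_attr = TRUE)
    expect_true(all(M >= 0 & M <= 1))
  }
  pc2 <- randomPhaseConnectivity(nEpochs = 4L, nCh = 5L,
                                 conditions = rep(c("FF", "FU"), 2))
  expect_warning(avg2 <- conditionAverage(pc2), "UF")
  expect_equal(dim(avg2)[1], 2L)
})

test_that("phase-collapsed PLI recovers the generative coupling ordering", {
  run <- runToPhases(gradedRecoveryConfig(seed = 11L,
                                          nEpochsPerCondition = 4L))
  st <- recoveryStats(run$average)
  expect_gt(st$rho, 0.8)
  expect_gt(st$margin, 0.2)
  # phase modulation: coupling 0.9 in one phase vs 0.0 in another is
  # strictly ordered in the estimate (pair 1: phases LC->RO vs LO->LC)
  est <- apply(run$average[, , 1, 5, drop = FALSE], 2, mean)
  expect_gt(est[1], est[4])
})
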