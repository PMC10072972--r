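K4 <- function() { W <- matrix(1, 4, 4); diag(W) <- 0; W }

star5 <- function() {
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 1; W
}

test_that("edge thresholding keeps only edges above half the strongest", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.41
  W[2, 3] <- W[3, 2] <- 0.4
  out <- thresholdEdges(W, 0.5)
  expect_equal(out[1, 2], 0.8)
  expect_equal(out[1, 3], 0.41)  # strictly above 0.4 survives
  expect_equal(out[2, 3], 0)     # exactly at the threshold is removed
  expect_equal(thresholdEdges(K4(), 0.5), K4())  # all equal weights kept
  expect_equal(thresholdEdges(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_error(thresholdEdges(W, 1), "\\[0, 1\\)")
  expect_error(thresholdEdges(W, -0.1), "\\[0, 1\\)")
})

test_that("complete and star graphs give textbook global metrics", {
  gm <- globalMetrics(K4())
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$char_path_length, 1)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$n_disconnected_pairs, 0L)
  expect_equal(globalMetrics(star5())$transitivity, 0)
  expect_error(globalMetrics(matrix(-1, 2, 2) + diag(2)), "negative")
  expect_error(globalMetrics(matrix(0, 1, 1)), "2 nodes")
})

test_that("random weighted graphs match Floyd-Warshall and dense-eigen oracles", {
  set.seed(12)
  for (rep in 1:20) {
    W <- randomWeightedGraph(8)
    gm <- globalMetrics(W)
    expect_equal(gm$global_efficiency, refGlobalEfficiency(W),
                 tolerance = 1e-10)
    expect_equal(gm$char_path_length, refPathLength(W), tolerance = 1e-10)
    lm <- localMetrics(W)
    ec <- lm$node$eigenvector
    expect_equal(ec, refEigenCentrality(W), tolerance = 1e-8)
    lambda <- max(eigen(W, symmetric = TRUE)$values)
    expect_lt(max(abs(W %*% ec - lambda * ec)), 1e-8)
  }
})

test_that("local metrics handle complete graphs and isolated nodes", {
  lm <- localMetrics(K4())$node
  expect_equal(lm$strength, rep(3, 4))
  expect_equal(lm$clustering, rep(1, 4))
  expect_equal(lm$local_efficiency, rep(1, 4))
  expect_equal(lm$eigenvector, rep(0.5, 4))
  # appending an isolated node zeroes its local metrics, no exception
  W <- rbind(cbind(K4(), 0), 0)
  lm5 <- localMetrics(W)$node
  expect_equal(lm5$strength[5], 0)
  expect_equal(lm5$clustering[5], 0)
  expect_equal(lm5$local_efficiency[5], 0)
  expect_equal(lm5$eigenvector[5], 0)
})

test_that("region averaging groups node metrics by brain area", {
  W <- K4()
  rownames(W) <- colnames(W) <- sprintf("CH%02d", 1:4)
  rm_ <- c(CH01 = "LMO", CH02 = "LMO", CH03 = "RSP", CH04 = "RSP")
  lm <- localMetrics(W, rm_)
  expect_equal(sort(lm$region$region), c("LMO", "RSP"))
  expect_equal(lm$region$strength, c(3, 3))
})

test_that("metric scaling behaves as the distance convention dictates", {
  set.seed(13)
  W <- randomWeightedGraph(8)
  c_ <- 0.37
  g1 <- globalMetrics(W); g2 <- globalMetrics(c_ * W)
  expect_equal(g2$global_efficiency, c_ * g1$global_efficiency,
               tolerance = 1e-10)
  expect_equal(g2$char_path_length, g1$char_path_length / c_,
               tolerance = 1e-10)
  expect_equal(g2$transitivity, g1$transitivity, tolerance = 1e-10)
  l1 <- localMetrics(W)$node; l2 <- localMetrics(c_ * W)$node
  expect_equal(l2$strength, c_ * l1$strength, tolerance = 1e-10)
  expect_equal(l2$clustering, l1$clustering, tolerance = 1e-10)
  expect_equal(l2$eigenvector, l1$eigenvector, tolerance = 1e-8)
})

test_that("permuting nodes permutes local metrics and fixes global ones", {
  set.seed(14)
  W <- randomWeightedGraph(7)
  p <- sample(7)
  Wp <- W[p, p]
  expect_equal(globalMetrics(Wp)[1:3], globalMetrics(W)[1:3],
               tolerance = 1e-10)
  l <- localMetrics(W)$node; lp <- localMetrics(Wp)$node
  expect_equal(lp$strength, l$strength[p], tolerance = 1e-10)
  expect_equal(lp$clustering, l$clustering[p], tolerance = 1e-10)
  expect_equal(lp$eigenvector, l$eigenvector[p], tolerance = 1e-7)
})

test_that("per-phase metrics are computed on the full (unthresholded) matrices", {
  pc <- randomPhaseConnectivity(nEpochs = 2L, nCh = 6L, seed = 6L)
  pm <- phaseMetrics(pc)
  expect_equal(dim(pm$global), c(2L, 4L, 3L))
  expect_equal(dim(pm$local), c(2L, 4L, 6L, 4L))
  W <- channelData(pc)[1, 2, , ]
  direct <- globalMetrics(W)
  expect_equal(pm$global[1, 2, "global_efficiency"],
               direct$global_efficiency, ignore_attr = TRUE)
  # thresholding would change the answer, proving the full matrix is used
  thr <- globalMetrics(thresholdEdges(W, 0.5))
  expect_false(isTRUE(all.equal(thr$global_efficiency,
                                direct$global_efficiency)))
})

test_that("global-metric time courses average within condition per window", {
  nCh <- 4L
  v <- array(0, dim = c(4, 19, nCh, nCh))
  M <- matrix(0.6, nCh, nCh); diag(M) <- 0
  for (e in 1:4) for (w in 1:19) v[e, w, , ] <- M
  tensor <- new("ConnectivityTensor", values = v, grid = windowGrid(2.5),
                condition = c("FF", "FF", "FU", "UF"),
                channelNames = sprintf("CH%02d", 1:nCh))
  tc <- timecourseGlobal(tensor)
  expect_equal(nrow(tc), 3 * 19 * 3)  # condition x window x metric
  # constant input gives flat curves
  eff <- tc[tc$metric == "global_efficiency" & tc$condition == "FF", ]
  expect_equal(length(unique(round(eff$mean, 12))), 1L)
  expect_equal(nrow(eff), 19L)
  # single-epoch conditions have undefined CIs, flagged as NA with n = 1
  fu <- tc[tc$condition == "FU", ]
  expect_true(all(is.na(fu$ci_lo)))
  expect_true(all(fu$n == 1))
  empty <- new("ConnectivityTensor",
               values = array(0, c(0, 19, nCh, nCh)),
               grid = windowGrid(2.5), condition = character(),
               channelNames = sprintf("CH%02d", 1:nCh))
  expect_error(timecourseGlobal(empty), "empty")
})
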