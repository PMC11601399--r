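mkNet <- function(...) {
  set.seed(1)
  createNetwork(networkConfig(...))
}

oneHot <- function(o, K = 8) { u <- numeric(K); u[o + 1] <- 1; u }

test_that("gate competition opens on positive Go-NoGo margin", {
  K <- 8; n <- 2
  go <- matrix(0, K, n); nogo <- matrix(0, K, n)
  r <- bgGateCompetition(oneHot(0), c(0, 0), go, nogo, rep(0, n),
                         rep(0, n), 0)
  expect_false(any(r$open))
  go[3, 1] <- 0.8; nogo[3, 1] <- 0.2
  r <- bgGateCompetition(oneHot(2), c(0, 0), go, nogo, rep(0, n),
                         rep(0, n), 0)
  expect_equal(r$open, c(TRUE, FALSE))
  ## a distributed drive recruits weights of similar orientations
  u <- oneHot(3); u[3] <- 0.5   # neighbor of the trained orientation
  r3 <- bgGateCompetition(u, c(0, 0), go, nogo, rep(0, n), rep(0, n), 0)
  expect_equal(r3$open, c(TRUE, FALSE))
  expect_equal(r3$record$go[1], 0.4)
  ## occupancy input contributes through its own weights
  r <- bgGateCompetition(oneHot(0), c(1, 1), go, nogo, rep(0.5, n),
                         rep(0, n), 0)
  expect_true(all(r$open))
  ## deterministic without noise
  r2 <- bgGateCompetition(oneHot(2), c(0, 0), go, nogo, rep(0, n),
                          rep(0, n), 0)
  expect_equal(r2$open, c(TRUE, FALSE))
})

test_that("input gating latches the source bump and holds it", {
  net <- mkNet(n_stripes = 2, chunk_enabled = FALSE, noise_sd = 0)
  x <- encodeColor(1.0)
  net <- applyInputGating(net, c(TRUE, FALSE), x, NULL)
  expect_true(net$occupied[1])
  expect_false(net$occupied[2])
  d1 <- net$deep[, 1]
  ## closed gates leave content bit-identical over many trials
  for (i in 1:10)
    net <- applyInputGating(net, c(FALSE, FALSE), encodeColor(runif(1)), NULL)
  expect_identical(net$deep[, 1], d1)
  ## re-gating overwrites
  net <- applyInputGating(net, c(TRUE, FALSE), encodeColor(4.0), NULL)
  expect_lt(abs(signedCircularError(decodePopulation(net$deep[, 1]), 4.0)), 10)
})

test_that("output gating averages opened occupied stripes", {
  net <- mkNet(n_stripes = 3, chunk_enabled = FALSE)
  a <- 0.9; b <- a + pi / 2
  net$deep[, 1] <- encodeColor(a); net$occupied[1] <- TRUE
  net$deep[, 2] <- encodeColor(b); net$occupied[2] <- TRUE
  r <- applyOutputGating(net, c(TRUE, FALSE, FALSE))
  expect_true(r$responded)
  expect_equal(r$n_output_gated, 1)
  expect_lt(abs(signedCircularError(decodePopulation(r$drive), a)), 10)
  ## two equally strong stripes decode to their circular mean
  r2 <- applyOutputGating(net, c(TRUE, TRUE, FALSE))
  expect_equal(r2$n_output_gated, 2)
  expect_lt(abs(signedCircularError(decodePopulation(r2$drive),
                                    (a + b) / 2)), 10)
  ## no opened occupied stripe is a non-response
  r3 <- applyOutputGating(net, c(FALSE, FALSE, TRUE))
  expect_false(r3$responded)
  expect_equal(r3$n_output_gated, 1)
})

test_that("chunk layer mirrors the input when PFC is empty or far", {
  net <- mkNet(n_stripes = 2, chunk_enabled = TRUE)
  x_ang <- pi
  y <- chunkLayerStep(net, encodeColor(x_ang))
  expect_lt(abs(signedCircularError(decodePopulation(y), x_ang)), 10)
  ## a stripe at 180 degrees does not drag the chunk representation
  net$deep[, 2] <- encodeColor(x_ang + pi); net$occupied[2] <- TRUE
  y2 <- chunkLayerStep(net, encodeColor(x_ang))
  expect_lt(abs(signedCircularError(decodePopulation(y2), x_ang)), 10)
})

test_that("a nearby PFC bump attracts the chunk representation", {
  net <- mkNet(n_stripes = 2, chunk_enabled = TRUE)
  x_ang <- pi
  net$deep[, 2] <- encodeColor(x_ang + 0.6); net$occupied[2] <- TRUE
  dev <- signedCircularError(
    decodePopulation(chunkLayerStep(net, encodeColor(x_ang))), x_ang)
  ## strictly between input and PFC angle, nearer the input
  expect_gt(dev, 2)
  expect_lt(dev, 0.6 * 180 / pi / 2)
})

test_that("chunk attraction rises then collapses and scales with top-down", {
  devProfile <- function(scale_pfc) {
    net <- mkNet(n_stripes = 2, chunk_enabled = TRUE,
                 scale_pfc = scale_pfc)
    vapply(seq(0.2, pi, length.out = 12), function(d) {
      net$deep[, 2] <- encodeColor(pi + d)
      net$occupied[2] <- TRUE
      y <- chunkLayerStep(net, encodeColor(pi))
      abs(signedCircularError(decodePopulation(y, floor = 0), pi))
    }, numeric(1))
  }
  base <- devProfile(networkConfig()$scale_pfc)
  expect_gt(max(base), 5)                 # attraction exists
  expect_lt(base[12], 2)                  # collapses near 180 degrees
  expect_lt(which.max(base), 12)          # peak at intermediate distance
  stronger <- devProfile(networkConfig()$scale_pfc + 0.15)
  expect_gt(mean(stronger[2:8]), mean(base[2:8]))  # monotone in scale
})

test_that("full episodes run end-to-end through the reference path", {
  set.seed(42)
  ## one-hot control inputs so the hand-wired policy is exact
  net <- createNetwork(networkConfig(n_stripes = 2, chunk_enabled = FALSE,
                                     noise_sd = 0, ori_overlap = 0))
  ## hand-wire a policy: orientation 0 -> stripe 1, orientation 1 -> stripe 2
  net$Wgo_in[] <- 0; net$Wnogo_in[] <- 0
  net$Wgo_out[] <- 0; net$Wnogo_out[] <- 0
  net$Wocc_go_in[] <- 0; net$Wocc_go_out[] <- 0; net$Wocc_nogo_out[] <- 0
  net$Wgo_in[1, 1] <- 1; net$Wgo_in[2, 2] <- 1
  net$Wgo_out[1, 1] <- 1; net$Wgo_out[2, 2] <- 1
  net$Wocc_nogo_in[] <- 0
  ## teach the PFC report mapping offline
  for (i in 1:300) {
    a <- runif(1, 0, 2 * pi)
    b <- encodeColor(a)
    net$Wrep_pfc <- reportMappingUpdate(net$Wrep_pfc, b,
                                        as.numeric(net$Wrep_pfc %*% b),
                                        b, 0.05)
  }
  ep <- list(set_size = 2L, orientations = c(0L, 1L),
             colors = c(1.0, 4.0), probe_index = 1L,
             probe_orientation = 0L, target_angle = 1.0, lag = 1L)
  class(ep) <- "episode_spec"
  out <- runEpisode(net, ep, learn = FALSE)
  expect_true(out$result$responded)
  expect_lt(abs(out$result$error_deg), 360 / 20)
  expect_equal(out$occupancy_final_store, c(TRUE, TRUE))
  ## probing an orientation whose stripe was never filled: non-response
  net2 <- net
  net2$Wgo_in[2, 2] <- 0   # orientation 1 no longer stored
  ep2 <- ep
  ep2$probe_index <- 2L; ep2$probe_orientation <- 1L
  ep2$target_angle <- 4.0; ep2$lag <- 0L
  set.seed(9)
  out2 <- runEpisode(net2, ep2, learn = FALSE)
  expect_false(out2$result$responded)
  ## reading out the wrong stripe produces a swap error
  net3 <- net
  net3$Wgo_out[1, ] <- c(0, 1)  # probe 0 reads stripe 2 (holds color 4.0)
  out3 <- runEpisode(net3, ep, learn = FALSE)
  expect_lt(abs(signedCircularError(out3$result$response_deg * pi / 180,
                                    4.0)), 20)
  ## malformed probe rejected
  ep3 <- ep; ep3$probe_orientation <- 5L
  expect_error(runEpisode(net, ep3), "malformed")
})
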