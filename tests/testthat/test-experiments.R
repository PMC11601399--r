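test_that("chance-recall formula matches brute-force enumeration", {
  ## enumerate every placement of N items into n stripes (overwriting) and
  ## every uniform readout choice; success = first item survives and its
  ## stripe is read out
  bruteChance <- function(n, N) {
    placements <- as.matrix(expand.grid(rep(list(seq_len(n)), N)))
    hits <- 0
    for (r in seq_len(nrow(placements))) {
      stripes <- rep(0L, n)
      for (k in seq_len(N)) stripes[placements[r, k]] <- k
      for (read in seq_len(n))
        if (stripes[read] == 1L) hits <- hits + 1
    }
    hits / (nrow(placements) * n)
  }
  expect_equal(chanceRecallProbability(2, 1), 0.5)
  expect_equal(chanceRecallProbability(3, 1), 1 / 3)
  expect_equal(chanceRecallProbability(2, 2), 0.25)
  for (n in 1:4) for (N in 1:4)
    expect_equal(chanceRecallProbability(n, N), bruteChance(n, N))
})

test_that("guess-rate estimator recovers known mixture weights", {
  set.seed(31)
  for (w in c(0, 0.25, 0.5, 0.75, 1)) {
    n <- 10000
    guess <- runif(n) < w
    errs <- ifelse(guess, runif(n, -180, 180),
                   pmax(-180, pmin(179.9, rnorm(n, 0, 12))))
    fit <- errorHistogramAndGuessRate(errs)
    expect_equal(fit$guess_rate, w, tolerance = 0.05)
  }
})

test_that("error histogram covers the circle and flags small samples", {
  set.seed(2)
  fit <- errorHistogramAndGuessRate(runif(500, -180, 180), 10)
  expect_equal(sum(fit$histogram$count), 500)
  expect_equal(nrow(fit$histogram), 36)
  expect_false(fit$low_confidence)
  expect_true(errorHistogramAndGuessRate(runif(50, -180, 180))$low_confidence)
  ## all-zero errors: essentially no guessing
  expect_lt(errorHistogramAndGuessRate(rnorm(2000, 0, 2))$guess_rate, 0.05)
})

test_that("stripe usage summarizes final-store occupancy", {
  occ <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))
  su <- stripeUsage(occ)
  expect_equal(su$per_stripe, c(0.75, 0.75))
  expect_equal(su$all_occupied, 0.5)
  expect_equal(su$any_empty, 0.5)
  expect_equal(stripeUsage(matrix(1, 5, 3))$all_occupied, 1)
})

test_that("OCV is a wraparound-safe circular dispersion in degrees", {
  expect_equal(ocv(c(100, 100)), 0, tolerance = 1e-5)
  expect_equal(ocv(c(90, 110)), 10, tolerance = 0.05)
  expect_equal(ocv(c(350, 10)), 10, tolerance = 0.05)
  expect_error(ocv(90), "at least 2")
})

test_that("OCV binning reports empty bins and preserves structure", {
  ocvv <- c(5, 10, 40, 50, 95)
  errs <- c(2, 4, 30, 34, 80)
  out <- ocvBinnedError(ocvv, errs, breaks = seq(0, 105, 15))
  expect_equal(nrow(out), 7)
  expect_equal(out$mean_abs_error[1], 3)
  expect_equal(out$n[2], 0)
  expect_true(is.na(out$mean_abs_error[2]))
  filled <- !is.na(out$mean_abs_error)
  expect_true(all(diff(out$mean_abs_error[filled]) > 0))
})

test_that("gating-policy alpha is rectified, normalized, scale-invariant", {
  go <- matrix(c(1, 1, 1, 0.5, 0.5, 0.5), 3, 2)
  nogo <- matrix(c(1, 1, 1, 0.1, 0.2, 0.2), 3, 2)
  a <- gatingPolicyAlpha(go, nogo)
  expect_equal(a[1], 0)                       # balanced opponency
  expect_equal(a[2], (1.5 - 0.5) / 2)
  expect_equal(gatingPolicyAlpha(go * 7, nogo * 7), a)  # ratio form
  expect_equal(gatingPolicyAlpha(matrix(1, 2, 1), matrix(3, 2, 1)), 0)
  expect_equal(gatingPolicyAlpha(matrix(3, 1, 1), matrix(1, 1, 1)), 0.5)
  expect_equal(gatingPolicyAlpha(matrix(0, 2, 1), matrix(0, 2, 1)), 0)
})

test_that("recency curve recovers an analytic overwrite mixture", {
  set.seed(17)
  p <- 0.35
  lags <- sample(0:3, 20000, replace = TRUE)
  lost <- runif(20000) < (1 - (1 - p)^lags)
  err <- ifelse(lost, runif(20000, -180, 180), rnorm(20000, 0, 3))
  rc <- recencyCurve(data.frame(error_deg = err, lag = lags))
  expect_equal(rc$lag, 0:3)
  expected <- 90 * (1 - (1 - p)^(0:3)) + mean(abs(rnorm(1000, 0, 3))) *
    (1 - p)^(0:3)
  expect_equal(rc$mean_abs_error, expected, tolerance = 0.08)
  expect_equal(which.min(rc$mean_abs_error), 1)  # lag 0 is best
  expect_true(all(diff(rc$mean_abs_error) > 0))
})

test_that("mean output gating is a plain arithmetic mean", {
  expect_equal(meanOutputGated(data.frame(n_output_gated = rep(1, 10))), 1)
  expect_equal(meanOutputGated(data.frame(n_output_gated = c(1, 2, 1, 2))),
               1.5)
})

test_that("training is seed-reproducible and beats the uniform baseline", {
  cfg <- experimentConfig(set_size = 2, n_stripes = 2,
                          chunk_enabled = FALSE, n_epochs = 120, seeds = 1,
                          n_eval_episodes = 150)
  ## untrained network: all recalls are guesses, E|error| = 90 degrees
  set.seed(2)
  net <- createNetwork(pbwmchunk:::buildNetworkConfig(cfg))
  ev0 <- evalNetwork(net, 400, set_size = 2, n_orientations = 8)
  expect_equal(mean(abs(ev0$recall$error_deg)), 90, tolerance = 8)
  tr <- trainNetwork(cfg, seed = 3)
  set.seed(101)
  ev1 <- evalNetwork(tr, 300)
  expect_lt(mean(abs(ev1$recall$error_deg)), 70)
})

test_that("a strictly dominant stripe wins the learned gating policy", {
  ## chunk layer disabled by zero gain: the chunk-linked stripe can never
  ## hold content, so the input-linked stripe is strictly reward-dominant
  wins <- 0
  for (s in 1:20) {
    cfg <- experimentConfig(set_size = 1, n_stripes = 2,
                            chunk_enabled = TRUE, n_epochs = 400,
                            trials_per_epoch = 60, n_orientations = 2,
                            seeds = 1, network = list(ge_gain = 0))
    tr <- trainNetwork(cfg, seed = s)
    if (tail(tr$alpha, 1)[2] > 0.5) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("dopamine sweep returns a full grid", {
  cfg <- experimentConfig(set_size = 1, n_stripes = 1,
                          chunk_enabled = FALSE, n_epochs = 15,
                          n_orientations = 2, seeds = 1,
                          n_eval_episodes = 50)
  m <- daGainSweep(cfg, burst_grid = c(0.3, 0.6), dip_grid = c(0.3, 0.6))
  expect_equal(dim(m), c(2, 2))
  expect_true(all(is.finite(m)))
  expect_true(all(m >= 0 & m <= 180))
})
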