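test_that("critic implements the delta rule and converges geometrically", {
  r <- criticRpe(0.4, 0.4, 0.1)
  expect_equal(r$delta, 0)
  expect_equal(r$v, 0.4)
  r <- criticRpe(1, 0, 0.1)
  expect_equal(r$delta, 1)
  expect_equal(r$v, 0.1)
  v <- 0
  for (i in 1:200) v <- criticRpe(0.7, v, 0.1)$v
  expect_equal(v, 0.7, tolerance = 1e-6)
  ## error shrinks by (1 - lr) per step
  expect_equal(0.7 - criticRpe(0.7, 0.3, 0.1)$v, (0.7 - 0.3) * 0.9)
})

test_that("dopamine signal scales bursts and dips separately", {
  expect_equal(dopamineSignal(0, 0.6, 0.6), 0)
  expect_equal(dopamineSignal(0.5, 0.6, 0.2), 0.3)
  expect_equal(dopamineSignal(-0.5, 0.2, 0.6), -0.3)
  expect_true(all(sign(dopamineSignal(c(-1, -0.1, 0.1, 1), 0.3, 0.9)) ==
                    c(-1, -1, 1, 1)))
})

test_that("tags decay multiplicatively and flag the decision taken", {
  K <- 4; n <- 2
  tg <- matrix(0.8, K, n); tn <- matrix(0.4, K, n)
  og <- rep(0.6, n); on_ <- rep(0.2, n)
  r <- updateTags(tg, tn, og, on_, decay = 0.5)
  expect_equal(r$tag_go, matrix(0.4, K, n))
  expect_equal(r$tag_nogo, matrix(0.2, K, n))
  ## closed-form decay over T silent trials
  tag <- 0.8
  r2 <- list(tag_go = matrix(tag, K, n), tag_nogo = tn,
             tag_occ_go = og, tag_occ_nogo = on_)
  for (t in 1:5)
    r2 <- updateTags(r2$tag_go, r2$tag_nogo, r2$tag_occ_go,
                     r2$tag_occ_nogo, 0.7)
  expect_equal(r2$tag_go[1, 1], tag * 0.7^5)
  ## increments land on the active drive row only, split by outcome
  z <- matrix(0, K, n)
  u <- c(0, 0, 1, 0)   # one-hot control input for orientation id 2
  r3 <- updateTags(z, z, rep(0, n), rep(0, n), 1, drive = u,
                   occupancy = c(1, 0), open = c(TRUE, FALSE),
                   nogo_scale = 0.5)
  expect_equal(r3$tag_go[3, ], c(1, 0))
  expect_equal(r3$tag_nogo[3, ], c(0, 0.5))
  expect_equal(sum(r3$tag_go[-3, ]) + sum(r3$tag_nogo[-3, ]), 0)
  expect_equal(r3$tag_occ_go, c(1, 0))
  expect_equal(r3$tag_occ_nogo, c(0, 0))  # stripe 2 unoccupied: pre = 0
})

test_that("three-factor update moves tagged opponent weights and clips", {
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 1, da = 0)
  expect_equal(up$go_w, 0.5); expect_equal(up$nogo_w, 0.5)
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 0, da = 0.9)
  expect_equal(up$go_w, 0.5); expect_equal(up$nogo_w, 0.5)
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 1, da = 0.3, lr_w = 0.1)
  expect_equal(up$go_w, 0.53); expect_equal(up$nogo_w, 0.47)
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 1, da = -0.3, lr_w = 0.1)
  expect_equal(up$go_w, 0.47); expect_equal(up$nogo_w, 0.53)
  ## NoGo-side tags learn with the opposite sign: a dip pushes the
  ## withheld gate toward opening, a burst reinforces staying closed
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 0, da = -0.3, lr_w = 0.1,
                                  tags_nogo = 1)
  expect_equal(up$go_w, 0.53); expect_equal(up$nogo_w, 0.47)
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 0, da = 0.3, lr_w = 0.1,
                                  tags_nogo = 1)
  expect_equal(up$go_w, 0.47); expect_equal(up$nogo_w, 0.53)
  ## with burst_credit 0 the non-action is never credited for successes
  up <- striatalThreeFactorUpdate(0.5, 0.5, tags = 0, da = 0.3, lr_w = 0.1,
                                  tags_nogo = 1, burst_credit = 0)
  expect_equal(up$go_w, 0.5); expect_equal(up$nogo_w, 0.5)
  up <- striatalThreeFactorUpdate(0.99, 0.01, tags = 1, da = 1, lr_w = 0.5)
  expect_equal(up$go_w, 1); expect_equal(up$nogo_w, 0)
})

test_that("weights stay inside [0, w_max] under arbitrary reward streams", {
  set.seed(8)
  go <- matrix(runif(8, 0, 1), 4, 2)
  nogo <- matrix(runif(8, 0, 1), 4, 2)
  for (i in 1:500) {
    tags <- matrix(rbinom(8, 1, 0.4), 4, 2)
    tn <- matrix(rbinom(8, 1, 0.4), 4, 2)
    up <- striatalThreeFactorUpdate(go, nogo, tags, runif(1, -1, 1),
                                    lr_w = 0.3, tags_nogo = tn)
    go <- up$go_w; nogo <- up$nogo_w
    expect_true(all(go >= 0 & go <= 1 & nogo >= 0 & nogo <= 1))
  }
})

test_that("critic converges to the mean of a stochastic reward stream", {
  set.seed(12)
  rewards <- runif(10000, -0.4, 0.9)
  v <- 0
  for (r in rewards) v <- criticRpe(r, v, 0.05)$v
  expect_lt(abs(v - mean(rewards)), 0.05)
})

test_that("consistent reward moves Go-NoGo apart; punishment reverses it", {
  ## a fixed gating decision, repeatedly rewarded, separates the opponent
  ## weights in its favor; repeated punishment drives the margin negative
  go <- 0.05; nogo <- 0.05
  for (i in 1:60) {
    up <- striatalThreeFactorUpdate(go, nogo, tags = 0.7, da = 0.3,
                                    lr_w = 0.1)
    go <- up$go_w; nogo <- up$nogo_w
  }
  expect_gt(go - nogo, 0.5)
  for (i in 1:120) {
    up <- striatalThreeFactorUpdate(go, nogo, tags = 0.7, da = -0.3,
                                    lr_w = 0.1)
    go <- up$go_w; nogo <- up$nogo_w
  }
  expect_lt(go - nogo, 0)
})

test_that("report mapping learns a fixed pair by the delta rule", {
  expect_equal(reportMappingUpdate(diag(3), c(1, 0, 0), c(1, 0, 0),
                                   c(1, 0, 0), 0.5), diag(3))
  expect_equal(reportMappingUpdate(diag(3), c(1, 0, 0), c(1, 0, 0),
                                   c(0, 1, 0), 0), diag(3))
  W <- matrix(0, 20, 20)
  x <- encodeColor(0.8)
  tgt <- encodeColor(0.8)
  for (i in 1:200)
    W <- reportMappingUpdate(W, x, as.numeric(W %*% x), tgt, 0.05)
  dec <- decodePopulation(pmax(as.numeric(W %*% x), 0))
  expect_lt(abs(signedCircularError(dec, 0.8)), 360 / 20)
})
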