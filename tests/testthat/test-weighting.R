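test_that("entropy weights follow the information-entropy definitions", {
  idx <- tiny_index(1L)
  # maximal-variation column: P = (0, 1), e = 0, all the weight
  m <- norm_matrix(matrix(c(0, 1), 2), "X1")
  res <- entropy_weights(m, "X1")
  expect_equal(unname(res$entropies), 0)
  expect_equal(unname(res$weights), 1)
  # uniform column: maximal entropy
  m2 <- norm_matrix(matrix(c(0.5, 0.5), 2), "X1")
  expect_equal(
    unname(suppressWarnings(entropy_weights(m2, "X1"))$entropies), 1)
  # block with e = (0, 1) -> weights (1, 0)
  m3 <- norm_matrix(cbind(c(0, 1), c(0.5, 0.5)), c("X1", "X2"))
  res3 <- entropy_weights(m3, c("X1", "X2"))
  expect_equal(unname(res3$weights), c(1, 0))
})

test_that("entropy handles degenerate blocks per the stated conventions", {
  # scale invariance: column (0, t) has e = 0 for any t > 0
  for (t in c(0.1, 0.5, 1)) {
    m <- norm_matrix(matrix(c(0, t), 2), "X1")
    expect_equal(unname(entropy_weights(m, "X1")$entropies), 0)
  }
  # all-zero column beside an informative one: e = 1, weight 0
  m <- norm_matrix(cbind(c(0, 0), c(0, 1)), c("X1", "X2"))
  res <- entropy_weights(m, c("X1", "X2"))
  expect_equal(unname(res$entropies), c(1, 0))
  expect_equal(unname(res$weights), c(0, 1))
  # fully uninformative block: equal weights with warning
  m2 <- norm_matrix(cbind(c(0.5, 0.5), c(0.3, 0.3)), c("X1", "X2"))
  expect_warning(res2 <- entropy_weights(m2, c("X1", "X2")),
                 "uninformative")
  expect_equal(unname(res2$weights), c(0.5, 0.5))
  # single plot: entropy undefined
  m3 <- norm_matrix(matrix(1, 1, 1), "X1", plots = "only")
  expect_error(entropy_weights(m3, "X1"), "at least 2 plots")
})

test_that("entropy matches a direct Shannon-formula oracle on random data", {
  set.seed(7)
  for (rep in 1:10) {
    m_plots <- sample(3:9, 1)
    vals <- matrix(runif(m_plots * 3), m_plots)
    nm <- norm_matrix(vals, paste0("X", 1:3))
    res <- entropy_weights(nm, paste0("X", 1:3))
    # oracle: plain-sum Shannon entropy over column shares
    e_oracle <- apply(vals, 2, function(col) {
      p <- col / sum(col)
      -sum(p * log(p)) / log(m_plots)
    })
    expect_equal(unname(res$entropies), e_oracle, tolerance = 1e-12)
    expect_equal(sum(res$weights), 1, tolerance = 1e-12)
    expect_true(all(res$entropies >= 0 & res$entropies <= 1))
  }
})

test_that("AHP priority vectors match closed forms on consistent matrices", {
  # symmetric all-ones matrix
  res <- ahp_priority(matrix(1, 3, 3))
  expect_equal(unname(res$weights), rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(res$lambda_max, 3, tolerance = 1e-10)
  expect_equal(res$CR, 0, tolerance = 1e-10)
  # built from w = (4, 2, 1)/7
  a <- rbind(c(1, 2, 4), c(1 / 2, 1, 2), c(1 / 4, 1 / 2, 1))
  res2 <- ahp_priority(a)
  expect_equal(unname(res2$weights), c(4, 2, 1) / 7, tolerance = 1e-10)
  expect_equal(res2$CR, 0, tolerance = 1e-10)
  # any 2x2 reciprocal matrix is consistent; w1/w2 = 3
  res3 <- ahp_priority(rbind(c(1, 3), c(1 / 3, 1)))
  expect_equal(unname(res3$weights), c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(res3$CR, 0)
})

test_that("AHP recovers arbitrary weight vectors from consistent matrices", {
  set.seed(11)
  for (k in 2:7) {
    w <- runif(k, 0.05, 1)
    w <- w / sum(w)
    res <- ahp_priority(consistent_pcm(w))
    expect_equal(unname(res$weights), w, tolerance = 1e-8)
    expect_equal(res$CR, 0, tolerance = 1e-8)
    # geometric-mean cross-check coincides on consistent matrices
    expect_equal(unname(ahp_geomean(consistent_pcm(w))), w,
                 tolerance = 1e-6)
  }
})

test_that("AHP agrees with base eigen() on an inconsistent matrix", {
  # Saaty-scale judgments that are not perfectly consistent
  a <- rbind(c(1, 3, 5), c(1 / 3, 1, 3), c(1 / 5, 1 / 3, 1))
  res <- ahp_priority(a)
  ev <- eigen(a)
  i <- which.max(Re(ev$values))
  w_oracle <- Re(ev$vectors[, i]); w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(unname(res$weights), w_oracle, tolerance = 1e-8)
  expect_equal(res$lambda_max, Re(ev$values[i]), tolerance = 1e-8)
  expect_equal(res$CI, (res$lambda_max - 3) / 2, tolerance = 1e-12)
  expect_equal(res$CR, res$CI / 0.58, tolerance = 1e-12)
  expect_lt(res$CR, 0.1)  # this judgment set is acceptably consistent
})

test_that("AHP validation and consistency policy fire as configured", {
  bad <- rbind(c(1, 2), c(0.4, 1))  # not reciprocal
  expect_error(ahp_priority(bad), "reciprocal")
  expect_error(ahp_priority(rbind(c(1, -2), c(-1 / 2, 1))), "positive")
  # strongly intransitive judgments: CR above threshold
  circ <- rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9), c(9, 1 / 9, 1))
  expect_warning(res <- ahp_priority(circ), "consistency ratio")
  expect_gt(res$CR, 0.1)
  expect_error(ahp_priority(circ, cr_action = "error"), "consistency ratio")
})

test_that("combined weights multiply the layers and sum to 1 per system", {
  set.seed(3)
  idx <- pingshuo_index()
  # random valid entropy weights per subsystem
  ew <- numeric(0)
  for (sys in idx$systems) for (sub in idx$subsystems[[sys]]) {
    ids <- subsystem_indicators(idx, sys, sub)
    w <- runif(length(ids)); w <- w / sum(w)
    ew <- c(ew, stats::setNames(w, ids))
  }
  sw <- subsystem_weights(pingshuo_ahp(), idx)$subsystem_weights
  cw <- combine_weights(sw, ew, idx)
  expect_true(all(cw >= 0))
  for (sys in idx$systems) {
    expect_equal(sum(cw[subsystem_indicators(idx, sys)]), 1,
                 tolerance = 1e-9)
  }
  # identity case: one subsystem with weight 1 leaves entropy weights as-is
  idx1 <- tiny_index(3L)
  ew1 <- stats::setNames(c(0.2, 0.3, 0.5), paste0("X", 1:3))
  cw1 <- combine_weights(list(s = c(a = 1)), ew1, idx1)
  expect_equal(cw1, ew1)
  # missing factor is named
  expect_error(combine_weights(list(s = c(a = 1)), ew1[-2], idx1), "X2")
})

test_that("the bundled subsystem weights reproduce the published blocks", {
  idx <- pingshuo_index()
  sw <- subsystem_weights(pingshuo_ahp(), idx)$subsystem_weights
  # published per-subsystem weight-block sums (within-system shares)
  expect_equal(unname(sw$vegetation),
               c(0.6739, 0.2255, 0.1007) / sum(c(0.6739, 0.2255, 0.1007)),
               tolerance = 1e-12)
  expect_equal(unname(sw$soil), c(0.2000, 0.8001) / 1.0001,
               tolerance = 1e-12)
  expect_equal(sum(sw$vegetation), 1, tolerance = 1e-12)
  expect_equal(sum(sw$soil), 1, tolerance = 1e-12)
})

test_that("subsystem weights accept pairwise matrices via config", {
  idx <- two_system_index(2L)
  cfg <- list(
    veg = list(direct_weights = list(a = 1)),
    soil = list(pairwise = list(c(1, 1), c(1, 1))))
  # one subsystem per system here, so both routes give weight 1
  sw <- subsystem_weights(list(
    veg = list(direct_weights = list(a = 1)),
    soil = list(direct_weights = list(b = 1))), idx)
  expect_equal(sw$subsystem_weights$veg, c(a = 1))
  # a real two-subsystem pairwise case
  idx2 <- index_system(
    c("veg", "soil"),
    list(veg = c("a", "b"), soil = "c"),
    data.frame(id = paste0("X", 1:3), name = "x",
               system = c("veg", "veg", "soil"),
               subsystem = c("a", "b", "c"), direction = "benefit"))
  sw2 <- subsystem_weights(list(
    veg = list(pairwise = list(c(1, 3), c(1 / 3, 1))),
    soil = list(direct_weights = list(c = 1))), idx2)
  expect_equal(unname(sw2$subsystem_weights$veg), c(0.75, 0.25),
               tolerance = 1e-9)
  expect_equal(sw2$consistency$veg$CR, 0)
  expect_error(subsystem_weights(list(veg = list()), idx2), "veg")
})
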