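# b-tensors, acquisition schemes, powder averaging, SNR estimation.

test_that("linear and planar b-tensors have the stated algebra", {
  z <- c(0, 0, 1)
  expect_equal(linear_btensor(1, z), diag(c(0, 0, 1)), ignore_attr = TRUE)
  expect_error(linear_btensor(1, c(0, 0, 2)), "unit")
  expect_error(planar_btensor(1, c(1, 1, 0)), "unit")

  set.seed(301)
  for (i in 1:5) {
    ax <- drop(random_directions(1))
    b <- runif(1, 0.5, 3)
    L <- linear_btensor(b, ax); P <- planar_btensor(b, ax)
    expect_equal(sum(diag(L)), b, tolerance = 1e-12)
    expect_equal(sum(diag(P)), b, tolerance = 1e-12)
    expect_equal(sort(eigen(P)$values), sort(c(0, b / 2, b / 2)),
                 tolerance = 1e-12)
    # contraction identities
    d <- runif(1, 0.1, 3)
    expect_equal(btensor_contract(L, d * diag(3)), b * d, tolerance = 1e-12)
    expect_equal(btensor_contract(P, d * diag(3)), b * d, tolerance = 1e-12)
    u <- drop(random_directions(1))
    cos2 <- sum(ax * u)^2
    expect_equal(btensor_contract(L, d * tcrossprod(u)), b * d * cos2,
                 tolerance = 1e-12)
    expect_equal(btensor_contract(P, d * tcrossprod(ax)), 0,
                 tolerance = 1e-12)
  }
})

test_that("bundled schemes have the protocol shell structure", {
  h <- hardi_scheme()
  expect_length(h$shells, 2L)
  expect_equal(h$n_meas, 120L)
  expect_equal(vapply(h$shells, function(s) s$b, 1), c(1, 2.2))
  ts <- tensor_scheme()
  expect_length(ts$shells, 8L)
  expect_equal(ts$n_meas, 138L)   # 12+12+20+20+30 linear + 12+12+20 planar
  expect_equal(sum(vapply(ts$shells, function(s) s$shape, "") == "planar"), 3L)
})

test_that("powder average: constants, permutations, SMT oracle", {
  sch <- hardi_scheme()
  const <- matrix(0.7, sch$n_meas, 1)
  expect_equal(drop(powder_average(const, sch)), c(0.7, 0.7),
               ignore_attr = TRUE)
  set.seed(302)
  b <- make_batch(8, sch, snr = Inf, rotate = TRUE, seed = 303)
  pa <- powder_average(b$clean, sch)
  pred <- rbind(smt_powder_signal(1, b$params$d, b$params$f),
                smt_powder_signal(2.2, b$params$d, b$params$f))
  expect_lt(max(abs(pa - pred) / pred), 0.002)
  # permutation of directions within a shell leaves the mean unchanged
  perm <- sch$shells[[1]]$rows[sample(60)]
  S2 <- b$clean; S2[sch$shells[[1]]$rows, ] <- b$clean[perm, ]
  expect_equal(powder_average(S2, sch), pa)
  expect_error(powder_average(b$clean[1:10, ], sch), "match")
})

test_that("SNR estimation follows the normalized-b0 rule", {
  expect_error(estimate_snr(c(1)), "two")
  expect_equal(estimate_snr(c(1, 1, 1)), Inf)
  set.seed(304)
  # 1/sd is biased upward at small n (~ +3/(4(n-1))); use enough b0s that
  # the estimator concentrates on the generating value
  b0 <- matrix(1 + rnorm(500 * 200, 0, 0.02), 500, 200)
  snr <- estimate_snr(b0)
  expect_equal(mean(snr), 50, tolerance = 0.02)
  expect_equal(estimate_snr(10 * b0), snr)   # scale invariance
})
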