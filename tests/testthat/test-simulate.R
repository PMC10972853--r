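# Synthetic voxels: ODF sampler, parameter priors, frequency-domain signal
# synthesis and Rician noise.

test_that("ODF sampler: normalization, non-negativity, reproducibility", {
  set.seed(501)
  iso <- sample_odf(odf_config(max_lobes = 0))
  expect_equal(iso[1], 1 / sqrt(4 * pi))
  expect_equal(iso[-1], numeric(44))

  grid <- healpix_directions(16)
  for (i in 1:10) {
    cf <- sample_odf()
    expect_equal(4 * pi * spherical_mean_sh(cf), 1, tolerance = 1e-9)
    v <- evaluate_sh(cf, grid, 8)
    expect_gte(min(v), -0.01 * max(v))
  }
  set.seed(42); a <- sample_odf()
  set.seed(42); b <- sample_odf()
  expect_identical(a, b)
  set.seed(43); expect_false(identical(sample_odf(), a))
})

test_that("parameter priors match the stated ranges and moments", {
  set.seed(502)
  p <- sample_two_comp(1e5)
  expect_true(all(p$d >= 0 & p$d <= 3 & p$f >= 0 & p$f <= 1))
  expect_equal(mean(p$d), 1.5, tolerance = 0.02)
  expect_equal(mean(p$f), 0.5, tolerance = 0.01)

  q <- sample_three_comp(1e4)
  expect_true(all(q$f_i + q$f_sph <= 1))
  expect_true(all(q$d_sph <= pmax(q$d_i, 0.5)))
  set.seed(7); a <- sample_three_comp(5)
  set.seed(7); expect_identical(sample_three_comp(5), a)
})

test_that("signal synthesis: isotropy, quadrature oracle, equivariance", {
  sch <- hardi_scheme()
  iso <- numeric(45); iso[1] <- 1 / sqrt(4 * pi)
  s <- simulate_signals(iso, list(d = 1.5, f = 0.6), sch)
  for (sh in sch$shells) {
    expect_lt(diff(range(s[sh$rows])), 1e-6)
    expect_equal(mean(s[sh$rows]), smt_powder_signal(sh$b, 1.5, 0.6),
                 tolerance = 1e-5)   # bandwidth-8 kernel truncation
  }

  # brute-force quadrature of the convolution integral
  set.seed(503)
  odf <- sample_odf()
  params <- data.frame(d = 2.1, f = 0.45)
  s <- simulate_signals(odf, params, sch)
  ctx <- sphmicro:::healpix_ctx(16)
  for (si in 1:2) {
    shell <- sch$shells[[si]]
    K <- two_comp_kernel(shell$b, ctx$dirs_half, params$d, params$f)
    h <- kernel_zonal_coeffs(K)
    oracle <- signal_quadrature_oracle(odf, h, shell$directions[1:10, ])
    expect_equal(s[shell$rows[1:10]], oracle, tolerance = 0.005 * max(oracle))
  }

  # rotating the ODF equals evaluating at rotated directions
  ang <- c(0.5, 1.2, 2.5)
  R <- sphmicro:::rotation_matrix_zyz(ang[1], ang[2], ang[3])
  s1 <- simulate_signals(rotate_sh(odf, 8, ang[1], ang[2], ang[3]), params, sch)
  sch2 <- sch
  for (si in seq_along(sch2$shells))
    sch2$shells[[si]]$directions <- sch$shells[[si]]$directions %*% R
  s2 <- simulate_signals(odf, params, sch2)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("Rician noise has the exact first and second moments", {
  set.seed(504)
  expect_identical(add_rician_noise(c(0.5, 0.9), Inf), c(0.5, 0.9))
  expect_error(add_rician_noise(1, 0), "positive")

  sigma <- 1 / 30
  n <- 1e6
  # Rayleigh limit at S = 0: mean = sigma sqrt(pi / 2)
  r0 <- add_rician_noise(numeric(n), 30)
  se0 <- sd(r0) / sqrt(n)
  expect_lt(abs(mean(r0) - sigma * sqrt(pi / 2)), 3 * se0)
  # second moment at any S: E[S_noisy^2] = S^2 + 2 sigma^2
  S <- 0.6
  r <- add_rician_noise(rep(S, n), 30)
  se2 <- sd(r^2) / sqrt(n)
  expect_lt(abs(mean(r^2) - (S^2 + 2 * sigma^2)), 3 * se2)
})

test_that("batches are reproducible and SMT-consistent before noise", {
  sch <- hardi_scheme()
  b1 <- make_batch(16, sch, snr = 50, rotate = FALSE, seed = 9, noise_seed = 10)
  b2 <- make_batch(16, sch, snr = 50, rotate = FALSE, seed = 9, noise_seed = 10)
  expect_identical(b1$noisy, b2$noisy)
  # clean signals do not depend on the noise seed
  b3 <- make_batch(16, sch, snr = 50, rotate = FALSE, seed = 9, noise_seed = 77)
  expect_identical(b1$clean, b3$clean)
  # rotation only changes the ODFs, not the parameter draws
  b4 <- make_batch(16, sch, snr = 50, rotate = TRUE, seed = 9, noise_seed = 10)
  expect_identical(b1$params, b4$params)
  expect_false(identical(b1$odf, b4$odf))
  # SMT identity per voxel
  pa <- powder_average(b4$clean, sch)
  pred <- rbind(smt_powder_signal(1, b4$params$d, b4$params$f),
                smt_powder_signal(2.2, b4$params$d, b4$params$f))
  expect_lt(max(abs(pa - pred) / pred), 0.002)
  expect_true(all(b4$clean > 0 & b4$clean <= 1 + 1e-12))
})
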