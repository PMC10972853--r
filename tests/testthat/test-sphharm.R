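# Real even-degree spherical harmonics: basis, transforms, convolution,
# rotation, truncation.

test_that("basis dimensions, constant column and orthonormality", {
  grid <- healpix_directions(16)
  expect_equal(dim(build_basis(grid, 8)), c(3072L, 45L))
  expect_error(build_basis(grid, 7), "even")

  # bandwidth 0: single column, Y00 = 1/sqrt(4 pi) everywhere
  B0 <- build_basis(grid[1:10, ], 0)
  expect_equal(dim(B0), c(10L, 1L))
  expect_equal(B0[, 1], rep(1 / sqrt(4 * pi), 10), tolerance = 1e-12)

  # Gram matrix on a dense equal-area grid approximates the identity
  dense <- healpix_directions(32)
  B <- build_basis(dense, 8)
  G <- (4 * pi / nrow(dense)) * crossprod(B)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-3)
})

test_that("least-squares fit: constant, band-limited round trip, ridge path", {
  grid <- healpix_directions(16)
  cf <- fit_coefficients(rep(1, nrow(grid)), grid, 8)
  expect_equal(cf[1], sqrt(4 * pi), tolerance = 1e-10)
  expect_lt(max(abs(cf[-1])), 1e-10)

  set.seed(101)
  for (bw in c(8L, 16L)) {
    truth <- random_coeffs(bw)
    v <- evaluate_sh(truth, grid, bw)
    expect_lt(max(abs(fit_coefficients(v, grid, bw) - truth)), 1e-9)
  }

  # 12 directions cannot support an unregularized bandwidth-8 fit
  set.seed(102)
  d12 <- random_directions(12)
  vals <- evaluate_sh(random_coeffs(8), d12, 8)
  expect_error(fit_coefficients(vals, d12, 8), "ill-conditioned")
  ridge <- fit_coefficients(vals, d12, 8, lambda = 0.006)
  # independent normal-equations oracle
  B <- build_basis(d12, 8)
  idx <- sh_index(8)
  L <- diag((idx$l * (idx$l + 1))^2)
  oracle <- solve(crossprod(B) + 0.006 * L, crossprod(B, vals))
  expect_equal(ridge, drop(oracle), tolerance = 1e-10)
})

test_that("evaluation basics and antipodal symmetry", {
  set.seed(103)
  x <- random_directions(50)
  expect_equal(evaluate_sh(numeric(45), x, 8), rep(0, 50))
  c0 <- numeric(45); c0[1] <- sqrt(4 * pi)
  expect_equal(evaluate_sh(c0, x, 8), rep(1, 50), tolerance = 1e-12)
  cf <- random_coeffs(8)
  expect_equal(evaluate_sh(cf, x, 8), evaluate_sh(cf, -x, 8),
               tolerance = 1e-12)
})

test_that("zonal convolution matches the identity filter and quadrature", {
  set.seed(104)
  lset <- seq(0, 8, 2)
  f <- random_coeffs(8)
  h_id <- sqrt((2 * lset + 1) / (4 * pi)) / (2 * pi)
  expect_equal(convolve_zonal(f, h_id, 8), f, tolerance = 1e-12)
  expect_equal(convolve_zonal(f, numeric(5), 8), numeric(45))
  expect_error(convolve_zonal(f, numeric(4), 8), "degree|coefficient")

  # brute-force S^2 quadrature of the convolution integral (the SO(3)
  # definition contributes an extra 2 pi from the gamma integral)
  h <- rnorm(3)
  f4 <- random_coeffs(4)
  x <- random_directions(6)
  direct <- 2 * pi * convolution_quadrature_oracle(f4, h, 4, x)
  spectral <- evaluate_sh(convolve_zonal(f4, h, 4), x, 4)
  # equal-weight HEALPix quadrature is accurate to ~1e-4 relative
  expect_equal(spectral, direct, tolerance = 1e-3)
})

test_that("rotation: identity, zonal invariance, oracle agreement, norm", {
  set.seed(105)
  cf <- random_coeffs(8)
  expect_equal(rotate_sh(cf, 8, 0, 0, 0), cf, tolerance = 1e-12)

  # zonal functions are invariant under rotations about z
  zl <- numeric(45); zl[sphmicro:::sh_zonal_rows(8)] <- rnorm(5)
  expect_equal(rotate_sh(zl, 8, 1.3, 0, 0), zl, tolerance = 1e-10)

  for (i in 1:5) {
    ang <- runif(3, 0, 2 * pi); ang[2] <- ang[2] / 2
    r <- rotate_sh(cf, 8, ang[1], ang[2], ang[3])
    expect_equal(r, rotation_point_oracle(cf, 8, ang[1], ang[2], ang[3]),
                 tolerance = 1e-8)
    expect_equal(sum(r^2), sum(cf^2), tolerance = 1e-10)
    # composing with the inverse rotation restores the coefficients
    back <- rotate_sh(r, 8, -ang[3], -ang[2], -ang[1])
    expect_equal(back, cf, tolerance = 1e-10)
  }
})

test_that("spectral truncation copies low degrees verbatim", {
  set.seed(106)
  cf <- random_coeffs(16)
  expect_equal(truncate_sh(cf, 16, 16), cf)
  expect_equal(truncate_sh(cf, 16, 0), cf[1])
  tr <- truncate_sh(cf, 16, 8)
  expect_length(tr, 45L)
  expect_equal(tr, cf[1:45])
  expect_error(truncate_sh(cf[1:45], 8, 16), "exceeds")
})

test_that("spherical mean: constant, pure harmonics, grid average", {
  c1 <- numeric(45); c1[1] <- sqrt(4 * pi)
  expect_equal(spherical_mean_sh(c1), 1)
  pure <- numeric(45); pure[7] <- 2.3   # an l = 2 harmonic
  expect_equal(spherical_mean_sh(pure), 0)
  set.seed(107)
  cf <- random_coeffs(8)
  grid <- healpix_directions(16)
  # grid means of l > 0 harmonics vanish only to quadrature accuracy (~1e-4)
  expect_lt(abs(spherical_mean_sh(cf) - mean(evaluate_sh(cf, grid, 8))),
            1e-3)
})

test_that("convolution is equivariant to rotations (property sweep)", {
  set.seed(108)
  worst <- 0
  for (i in 1:100) {
    f <- random_coeffs(8)
    h <- rnorm(5)
    ang <- c(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
    a <- rotate_sh(convolve_zonal(f, h, 8), 8, ang[1], ang[2], ang[3])
    b <- convolve_zonal(rotate_sh(f, 8, ang[1], ang[2], ang[3]), h, 8)
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-8)
})

test_that("Parseval holds on a dense uniform grid", {
  set.seed(109)
  grid <- healpix_directions(32)
  for (i in 1:5) {
    cf <- random_coeffs(8)
    v <- evaluate_sh(cf, grid, 8)
    expect_equal(sum(cf^2), (4 * pi / nrow(grid)) * sum(v^2),
                 tolerance = 1e-3)
  }
})
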