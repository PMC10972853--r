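# Compartment kernels, their zonal spectra and the SMT closed form.

test_that("compartment attenuation reduces to its closed forms", {
  expect_equal(compartment_attenuation(matrix(0, 3, 3), diag(c(1, 1, 2))), 1)
  set.seed(401)
  for (i in 1:5) {
    ax <- drop(random_directions(1)); b <- runif(1, 0.5, 4)
    d <- runif(1, 0.1, 3)
    expect_equal(compartment_attenuation(linear_btensor(b, ax), d * diag(3)),
                 exp(-b * d), tolerance = 1e-12)
    # stick along z seen by a linear tensor at polar angle theta
    D <- diag(c(0, 0, d))
    expect_equal(compartment_attenuation(linear_btensor(b, ax), D),
                 exp(-b * d * ax[3]^2), tolerance = 1e-12)
  }
})

test_that("two-compartment kernel limits and spherical mean", {
  grid <- healpix_directions(8)
  expect_equal(two_comp_kernel(0, grid, 1.5, 0.6), rep(1, nrow(grid)),
               tolerance = 1e-12)
  # f = 0 collapses to an isotropic Gaussian for linear encoding
  expect_equal(two_comp_kernel(2, grid, 1.2, 0),
               rep(exp(-2 * 1.2), nrow(grid)), tolerance = 1e-12)
  # spherical mean over the dense grid matches the closed form
  dense <- healpix_directions(16)
  set.seed(402)
  for (i in 1:5) {
    b <- runif(1, 0.5, 5); d <- runif(1, 0.1, 3); f <- runif(1, 0.05, 0.95)
    expect_equal(mean(two_comp_kernel(b, dense, d, f)),
                 smt_powder_signal(b, d, f),
                 tolerance = 0.002 * smt_powder_signal(b, d, f))
  }
  expect_error(two_comp_kernel(1, grid, 3.5, 0.5), "0, 3")
  expect_error(two_comp_kernel(1, grid, 1, 1.5), "0, 1")
})

test_that("three-compartment kernel: reduction, isotropic and planar limits", {
  grid <- healpix_directions(8)
  # f_sph -> 0 reduces exactly to the two-compartment kernel
  expect_equal(three_comp_kernel(2.2, grid, 1.7, 0.4, 0.3, 0),
               two_comp_kernel(2.2, grid, 1.7, 0.4), tolerance = 1e-12)
  # pure sphere compartment is isotropic for every encoding shape
  for (shape in c("linear", "planar")) {
    expect_equal(three_comp_kernel(2, grid, 1, 0, 0.4, 1, shape = shape),
                 rep(exp(-2 * 0.4), nrow(grid)), tolerance = 1e-12)
  }
  # pure stick under planar encoding: exp(-(b d / 2)(1 - cos^2 theta))
  mu <- grid[, 3]
  expect_equal(three_comp_kernel(3, grid, 2, 1, 0.2, 0, shape = "planar"),
               exp(-(3 * 2 / 2) * (1 - mu^2)), tolerance = 1e-12)
  expect_error(three_comp_kernel(1, grid, 1, 0.7, 0.2, 0.5), "fractions")
  expect_error(three_comp_kernel(1, grid, 1, 0.2, 2.5, 0.2), "d_sph")
})

test_that("zonal spectra: constants, isotropy, Legendre-projection oracle", {
  grid <- healpix_directions(16)
  h0 <- kernel_zonal_coeffs(rep(1, nrow(grid)))
  expect_equal(h0[1], sqrt(4 * pi), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(h0[-1])), 1e-9)
  hiso <- kernel_zonal_coeffs(two_comp_kernel(2, grid, 1.3, 0))
  expect_lt(max(abs(hiso[-1])), 1e-9)

  # stick kernel at b = 3, d = 2 against direct Gauss-Legendre projection
  h <- kernel_zonal_coeffs(two_comp_kernel(3, grid, 2, 1))
  q <- gauss_legendre(64)
  P <- sphmicro:::normalized_legendre(8, q$x)
  for (l in seq(0, 8, 2)) {
    oracle <- 2 * pi * sum(q$w * exp(-3 * 2 * q$x^2) * P[[l + 1]][, 1])
    expect_equal(h[l / 2 + 1], oracle, tolerance = 1e-3, ignore_attr = TRUE)
  }

  # a non-axially-symmetric field is rejected
  bad <- evaluate_sh(c(numeric(44), 1), grid, 8)   # an l=8, m=8 harmonic
  expect_error(kernel_zonal_coeffs(bad), "symmetric")
})

test_that("SMT closed form: limits, stability and quadrature agreement", {
  expect_equal(smt_powder_signal(0, 1.5, 0.5), 1)
  expect_equal(smt_powder_signal(2, 1.3, 0), exp(-2 * 1.3), tolerance = 1e-9)
  bd <- 2 * 1.3
  expect_equal(smt_powder_signal(2, 1.3, 1),
               sqrt(pi) * erf_pnorm(sqrt(bd)) / (2 * sqrt(bd)),
               tolerance = 1e-12)
  # smooth at tiny arguments
  expect_equal(smt_powder_signal(1e-9, 1e-9, 0.5), 1, tolerance = 1e-6)

  # numerical powder average of the kernel over a dense uniform grid
  set.seed(403)
  dense <- healpix_directions(32)   # 12288 points
  for (b in c(0.5, 2.2, 5)) for (d in c(0.1, 1.5, 3)) for (f in c(0.05, 0.5, 0.95)) {
    expect_equal(mean(two_comp_kernel(b, dense, d, f)),
                 smt_powder_signal(b, d, f),
                 tolerance = 1e-3 * smt_powder_signal(b, d, f))
  }

  # kernels decrease monotonically in b
  bs <- seq(0, 5, by = 0.5)
  vals <- smt_powder_signal(bs, 1.5, 0.6)
  expect_true(all(diff(vals) < 0))
})
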