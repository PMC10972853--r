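# Independent numerical oracles used across the suite. These deliberately
# avoid the package's fast paths: quadrature instead of spectral identities,
# point rotation instead of Wigner matrices.

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# error function via the normal CDF
erf_pnorm <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# random unit vectors
random_directions <- function(n) {
  x <- matrix(rnorm(3 * n), n, 3)
  x / sqrt(rowSums(x^2))
}

# random even-degree SH coefficient vector
random_coeffs <- function(bandwidth, sd = 1) {
  rnorm(sh_ncoef(bandwidth), 0, sd)
}

# Brute-force spherical convolution by S^2 quadrature:
# (f * h)(x) = int_{S^2} f(u) h_z(x . u) du, where h_z is the zonal filter
# with even-degree zonal coefficients h_l0. Checks the frequency-domain
# product against direct integration on a dense equal-area grid.
convolution_quadrature_oracle <- function(f_coeffs, h_l0, bandwidth, x) {
  grid <- healpix_directions(32)
  fu <- evaluate_sh(f_coeffs, grid, bandwidth)
  lset <- seq(0, bandwidth, 2)
  # zonal filter value at polar cosine t: sum_l h_l0 * Nl * P_l(t)
  hz <- function(t) {
    P <- sphmicro:::normalized_legendre(bandwidth, t)
    v <- 0
    for (l in lset) v <- v + h_l0[l / 2 + 1] * P[[l + 1]][, 1]
    v
  }
  vapply(seq_len(nrow(x)), function(i) {
    t <- pmin(1, pmax(-1, grid %*% x[i, ]))
    (4 * pi / nrow(grid)) * sum(fu * hz(drop(t)))
  }, numeric(1))
}

# point-rotation oracle for SH rotation: evaluate f at R^{-1} x on a dense
# grid and refit.
rotation_point_oracle <- function(coeffs, bandwidth, alpha, beta, gamma) {
  grid <- healpix_directions(16)
  R <- sphmicro:::rotation_matrix_zyz(alpha, beta, gamma)
  vals <- evaluate_sh(coeffs, grid %*% R, bandwidth)
  fit_coefficients(vals, grid, bandwidth)
}

# dense-grid spherical quadrature of the compartment-signal convolution:
# S(n) = int ODF(u) K_z(n . u) du with the band-limited zonal kernel.
signal_quadrature_oracle <- function(odf_coeffs, h_l0, directions) {
  convolution_quadrature_oracle(odf_coeffs, h_l0, 8, directions)
}
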