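#' Real even-degree spherical harmonics
#'
#' The whole package speaks one spectral language: real spherical harmonics
#' restricted to even degrees, the natural basis for antipodally symmetric
#' functions such as diffusion MRI signals and fibre ODFs. For bandwidth `b`
#' (maximum even degree), coefficients are stored as a single vector ordered
#' by degree l = 0, 2, ..., b and, within each degree, by order
#' m = -l, ..., l. The basis functions are
#' \deqn{S_l^m = Y_l^0 (m = 0),\quad \sqrt{2}\,\mathrm{Re}(Y_l^m) (m > 0),
#'   \quad \sqrt{2}\,\mathrm{Im}(Y_l^{|m|}) (m < 0),}
#' with \eqn{Y_l^m} the orthonormal complex harmonics (Condon--Shortley
#' phase). The basis is orthonormal on the sphere.
#'
#' @name sphharm
#' @keywords internal
NULL

#' Number of even-degree real SH coefficients at a given bandwidth
#'
#' @param bandwidth Even integer maximum degree (>= 0).
#' @return Integer, \eqn{(b/2 + 1)(b + 1)}: 45 at bandwidth 8, 153 at 16.
#' @export
sh_ncoef <- function(bandwidth) {
  check_bandwidth(bandwidth)
  as.integer((bandwidth / 2 + 1) * (bandwidth + 1))
}

check_bandwidth <- function(bandwidth) {
  if (length(bandwidth) != 1 || is.na(bandwidth) || bandwidth < 0 ||
      bandwidth != as.integer(bandwidth) || bandwidth %% 2 != 0) {
    stop("bandwidth must be a single even non-negative integer, got: ",
         paste(bandwidth, collapse = ","), call. = FALSE)
  }
  invisible(as.integer(bandwidth))
}

#' Degree and order labels for the even-degree coefficient vector
#'
#' @inheritParams sh_ncoef
#' @return A data.frame with columns `l` and `m`, one row per coefficient,
#'   in storage order.
#' @export
sh_index <- function(bandwidth) {
  check_bandwidth(bandwidth)
  l <- unlist(lapply(seq(0L, bandwidth, by = 2L), function(l) rep(l, 2L * l + 1L)))
  m <- unlist(lapply(seq(0L, bandwidth, by = 2L), function(l) seq(-l, l)))
  data.frame(l = as.integer(l), m = as.integer(m))
}

# Rows of the coefficient vector holding m = 0 entries (one per even degree).
sh_zonal_rows <- function(bandwidth) {
  idx <- sh_index(bandwidth)
  which(idx$m == 0L)
}

#' Validate a direction grid
#'
#' @param directions Numeric n x 3 matrix of unit vectors.
#' @param tol Tolerance on the Euclidean norm of each row.
#' @return The matrix, invisibly, after validation.
#' @export
check_directions <- function(directions, tol = 1e-9) {
  if (!is.matrix(directions) || ncol(directions) != 3 || nrow(directions) < 1)
    stop("directions must be an n x 3 matrix with n >= 1", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > tol))
    stop("directions must be unit vectors (max |norm - 1| = ",
         format(max(abs(nrm - 1))), ")", call. = FALSE)
  invisible(directions)
}

# Fully normalized associated Legendre functions \bar{P}_l^m(x) including the
# Condon-Shortley phase, for all l <= lmax, m = 0..l, via the standard stable
# three-term recursion. x may be a vector; returns a list indexed [[l+1]] of
# matrices (length(x) x (l+1)) with columns m = 0..l.
normalized_legendre <- function(lmax, x) {
  nx <- length(x)
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- matrix(0, nx, l + 1L)
  P[[1L]][, 1L] <- 1 / sqrt(4 * pi)
  if (lmax == 0L) return(P)
  # diagonal terms \bar{P}_m^m
  pmm <- P[[1L]][, 1L]
  if (lmax >= 1) {
    for (m in 1:lmax) {
      pmm <- -sqrt((2 * m + 1) / (2 * m)) * s * pmm
      P[[m + 1L]][, m + 1L] <- pmm
    }
  }
  # off-diagonal recursion upward in l for each m
  for (m in 0:(lmax - 1L)) {
    p_prev <- P[[m + 1L]][, m + 1L]                    # \bar{P}_m^m
    p_curr <- x * sqrt(2 * m + 3) * p_prev             # \bar{P}_{m+1}^m
    if (m + 1L <= lmax) P[[m + 2L]][, m + 1L] <- p_curr
    if (m + 2L <= lmax) {
      for (l in (m + 2L):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        p_next <- a * (x * p_curr - b * p_prev)
        P[[l + 1L]][, m + 1L] <- p_next
        p_prev <- p_curr
        p_curr <- p_next
      }
    }
  }
  P
}

#' Build the real even-degree SH basis matrix on a direction grid
#'
#' Column j evaluates basis function j (in storage order) at each direction,
#' so a least-squares fit of sampled values is `solve(crossprod(B), crossprod
#' (B, X))`.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param bandwidth Even integer maximum degree.
#' @return n x `sh_ncoef(bandwidth)` numeric matrix.
#' @export
build_basis <- function(directions, bandwidth) {
  check_bandwidth(bandwidth)
  check_directions(directions)
  n <- nrow(directions)
  z <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  P <- normalized_legendre(bandwidth, z)
  B <- matrix(0, n, sh_ncoef(bandwidth))
  j <- 0L
  for (l in seq(0L, bandwidth, by = 2L)) {
    Pl <- P[[l + 1L]]
    for (m in seq(-l, l)) {
      j <- j + 1L
      if (m == 0L) {
        B[, j] <- Pl[, 1L]
      } else if (m > 0L) {
        B[, j] <- sqrt(2) * Pl[, m + 1L] * cos(m * phi)
      } else {
        B[, j] <- sqrt(2) * Pl[, -m + 1L] * sin(-m * phi)
      }
    }
  }
  B
}

#' Least-squares spherical-harmonic fit
#'
#' Computes even-degree expansion coefficients from per-direction samples by
#' (optionally Laplace--Beltrami regularized) least squares
#' \eqn{(B^T B + \lambda L)^{-1} B^T X} with \eqn{L = \mathrm{diag}(l^2(l+1)^2)}.
#' The unregularized path requires at least as many directions as
#' coefficients and a well-conditioned Gram matrix.
#'
#' @param values Numeric vector (length n) or n x k matrix of samples.
#' @param directions n x 3 unit vectors where the samples were taken.
#' @param bandwidth Even integer maximum degree of the fit.
#' @param lambda Non-negative ridge weight on the Laplace--Beltrami penalty;
#'   0 (default) is plain least squares.
#' @return Coefficient vector (or `sh_ncoef(bandwidth)` x k matrix).
#' @export
fit_coefficients <- function(values, directions, bandwidth, lambda = 0) {
  B <- build_basis(directions, bandwidth)
  fit_coefficients_basis(values, B, bandwidth, lambda,
                         grid_label = paste0(nrow(directions), " directions"))
}

# Fit with a precomputed basis matrix (hot path).
fit_coefficients_basis <- function(values, B, bandwidth, lambda = 0,
                                   grid_label = "grid") {
  X <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(X) != nrow(B))
    stop("number of samples (", nrow(X), ") does not match grid size (",
         nrow(B), ")", call. = FALSE)
  G <- crossprod(B)
  if (lambda > 0) {
    idx <- sh_index(bandwidth)
    diag(G) <- diag(G) + lambda * (idx$l * (idx$l + 1))^2
  } else {
    if (nrow(B) < ncol(B) || rcond(G) < 1e-10)
      stop("ill-conditioned SH fit on ", grid_label, " at bandwidth ",
           bandwidth, " (", ncol(B), " coefficients); supply lambda > 0 ",
           "or a denser grid", call. = FALSE)
  }
  cf <- solve(G, crossprod(B, X))
  if (is.matrix(values)) cf else drop(cf)
}

#' Evaluate an even-degree SH expansion on a direction grid
#'
#' @param coeffs Coefficient vector (or ncoef x k matrix) in storage order.
#' @param directions n x 3 unit vectors.
#' @param bandwidth Even integer maximum degree matching `coeffs`.
#' @return Numeric vector of length n (or n x k matrix).
#' @export
evaluate_sh <- function(coeffs, directions, bandwidth) {
  B <- build_basis(directions, bandwidth)
  cf <- if (is.matrix(coeffs)) coeffs else matrix(coeffs, ncol = 1)
  if (nrow(cf) != ncol(B))
    stop("coefficient length ", nrow(cf), " does not match bandwidth ",
         bandwidth, " (expected ", ncol(B), ")", call. = FALSE)
  out <- B %*% cf
  if (is.matrix(coeffs)) out else drop(out)
}

# Per-degree gain of zonal spherical convolution: y_lm = factor(l) f_lm h_l0.
zonal_conv_factor <- function(l) 2 * pi * sqrt(4 * pi / (2 * l + 1))

#' Zonal spherical convolution in the frequency domain
#'
#' Convolution of a function `f` by a zonal (axially symmetric) filter `h` is
#' a pointwise product per degree:
#' \deqn{\hat{y}_{lm} = 2\pi\sqrt{4\pi/(2l+1)}\,\hat{f}_{lm}\,\hat{h}_{l0}.}
#'
#' @param f Coefficient vector of the input function.
#' @param h_zonal One zonal coefficient \eqn{\hat{h}_{l0}} per even degree
#'   0, 2, ..., bandwidth (length bandwidth/2 + 1).
#' @param bandwidth Even integer bandwidth of `f`.
#' @return Coefficient vector of the convolved function, same bandwidth.
#' @export
convolve_zonal <- function(f, h_zonal, bandwidth) {
  check_bandwidth(bandwidth)
  ndeg <- bandwidth / 2 + 1
  if (length(h_zonal) != ndeg)
    stop("h_zonal must supply one coefficient per even degree <= ", bandwidth,
         " (expected ", ndeg, ", got ", length(h_zonal), ")", call. = FALSE)
  if (length(f) != sh_ncoef(bandwidth))
    stop("coefficient length ", length(f), " does not match bandwidth ",
         bandwidth, call. = FALSE)
  idx <- sh_index(bandwidth)
  gain <- zonal_conv_factor(idx$l) * h_zonal[idx$l / 2 + 1]
  f * gain
}

#' Truncate an SH expansion to a lower bandwidth (spectral pooling)
#'
#' @param coeffs Coefficient vector (or matrix, coefficients in rows).
#' @param bandwidth Current even bandwidth.
#' @param new_bandwidth Target even bandwidth, at most `bandwidth`.
#' @return Coefficients of degrees <= `new_bandwidth`, copied verbatim.
#' @export
truncate_sh <- function(coeffs, bandwidth, new_bandwidth) {
  check_bandwidth(bandwidth)
  check_bandwidth(new_bandwidth)
  if (new_bandwidth > bandwidth)
    stop("new_bandwidth (", new_bandwidth, ") exceeds bandwidth (",
         bandwidth, ")", call. = FALSE)
  keep <- seq_len(sh_ncoef(new_bandwidth))
  if (is.matrix(coeffs)) coeffs[keep, , drop = FALSE] else coeffs[keep]
}

#' Spherical mean of an SH expansion
#'
#' The average of the function over the sphere, \eqn{c_{00}/\sqrt{4\pi}};
#' for noiseless Gaussian-compartment signals this is the powder average and
#' does not depend on the ODF.
#'
#' @param coeffs Coefficient vector (or matrix with coefficients in rows).
#' @return Scalar (or vector, one per column).
#' @export
spherical_mean_sh <- function(coeffs) {
  if (is.matrix(coeffs)) coeffs[1, ] / sqrt(4 * pi) else coeffs[1] / sqrt(4 * pi)
}
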