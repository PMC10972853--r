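#' Gaussian compartment kernels and the SMT closed form
#'
#' A microstructural kernel is the signal of a single coherently oriented
#' tissue environment, a sum of Gaussian compartment attenuations
#' \eqn{K(\hat{n}) = S_0 \sum_i f_i \exp(-b\!:\!D_i)} with axially symmetric
#' diffusion tensors aligned with the z-axis. Measured signals are the
#' spherical convolution of the ODF with this kernel; its zonal
#' spherical-harmonic spectrum is therefore all the simulator and the
#' deconvolution baseline need.
#'
#' @name models
#' @keywords internal
NULL

#' Gaussian attenuation of one compartment under a b-tensor
#'
#' @param btensor 3x3 symmetric b-tensor (ms/um^2).
#' @param D 3x3 symmetric PSD diffusion tensor (um^2/ms).
#' @return `exp(-b:D)`.
#' @export
compartment_attenuation <- function(btensor, D) {
  exp(-btensor_contract(btensor, D))
}

# exp(-b:D) for axially symmetric D = diag(dr, dr, da) (aligned with z) and a
# b-tensor of the given shape whose symmetry axis has polar cosine mu.
# Vectorized over mu and over (da, dr) via outer structure: returns
# length(mu) x length(da) matrix.
axisym_attenuation <- function(b, shape, mu, da, dr) {
  mu2 <- mu^2
  if (shape == "linear") {
    ex <- -b * (outer(rep(1, length(mu)), dr) + outer(mu2, da - dr))
  } else if (shape == "planar") {
    # b:D = (b/2) (tr D - n^T D n), tr D = 2 dr + da
    ex <- -(b / 2) * (outer(rep(1, length(mu)), dr + da) - outer(mu2, da - dr))
  } else {
    stop("unsupported b-tensor shape: ", shape, call. = FALSE)
  }
  exp(ex)
}

check_two_comp <- function(d, f) {
  if (any(d < 0 | d > 3)) stop("d must lie in [0, 3] um^2/ms", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  invisible(NULL)
}

check_three_comp <- function(d_i, f_i, d_sph, f_sph) {
  if (any(d_i < 0 | d_i > 3)) stop("d_i must lie in [0, 3] um^2/ms", call. = FALSE)
  if (any(f_i < 0 | f_sph < 0 | f_i + f_sph > 1 + 1e-12))
    stop("signal fractions must satisfy f_i, f_sph >= 0 and f_i + f_sph <= 1",
         call. = FALSE)
  if (any(d_sph < 0 | d_sph > pmax(d_i, 0.5) + 1e-12))
    stop("d_sph must lie in [0, max(d_i, 0.5)] um^2/ms", call. = FALSE)
  invisible(NULL)
}

#' Constrained two-compartment (stick + zeppelin) kernel
#'
#' Intra-neurite stick with diffusivity `d` and signal fraction `f`, plus an
#' extra-cellular zeppelin with axial diffusivity `d` and radial diffusivity
#' `(1 - f) d` (tortuosity constraint), evaluated for measurements whose
#' b-tensor symmetry axis points along each supplied direction.
#'
#' @param b b-value (ms/um^2).
#' @param directions n x 3 unit vectors (b-tensor symmetry axes).
#' @param d Intra-neurite diffusivity, um^2/ms, in \[0, 3\].
#' @param f Intra-neurite signal fraction in \[0, 1\].
#' @param shape `"linear"` or `"planar"` encoding.
#' @param S0 Non-diffusion-weighted reference signal (1 for normalized data).
#' @return Numeric vector of kernel values, one per direction.
#' @export
two_comp_kernel <- function(b, directions, d, f, shape = "linear", S0 = 1) {
  check_two_comp(d, f)
  check_directions(directions)
  mu <- directions[, 3]
  stick <- axisym_attenuation(b, shape, mu, da = d, dr = 0)
  zepp <- axisym_attenuation(b, shape, mu, da = d, dr = (1 - f) * d)
  S0 * drop(f * stick + (1 - f) * zepp)
}

# Extra-cellular axial diffusivity of the three-compartment model:
# d_i (f_i + f_sph/2) / (f_i + f_sph), bounded in [d_i/2, d_i]; the radial
# diffusivity is (1 - f_i - f_sph) times it. The factor tends to 1 (free
# diffusion at d_i) in the degenerate limit f_i + f_sph -> 0.
three_comp_dax <- function(d_i, f_i, f_sph) {
  tot <- f_i + f_sph
  fac <- ifelse(tot < 1e-9, 1, (f_i + 0.5 * f_sph) / pmax(tot, 1e-30))
  d_i * fac
}

#' Constrained three-compartment (stick + ball + zeppelin) kernel
#'
#' Adds an isotropic ball (apparent neural soma) compartment with diffusivity
#' `d_sph` and fraction `f_sph` to the stick + zeppelin model. The
#' extra-cellular zeppelin has axial diffusivity
#' \eqn{d_i (f_i + f_{sph}/2)/(f_i + f_{sph})} and radial diffusivity
#' \eqn{(1 - f_i - f_{sph})} times that, which reduces exactly to the
#' two-compartment constraint as \eqn{f_{sph} \to 0}.
#'
#' @inheritParams two_comp_kernel
#' @param d_i Intra-neurite diffusivity, um^2/ms, in \[0, 3\].
#' @param f_i Intra-neurite signal fraction.
#' @param d_sph Spherical-compartment diffusivity, um^2/ms, at most
#'   `max(d_i, 0.5)`.
#' @param f_sph Spherical-compartment signal fraction (`f_i + f_sph <= 1`).
#' @return Numeric vector of kernel values, one per direction.
#' @export
three_comp_kernel <- function(b, directions, d_i, f_i, d_sph, f_sph,
                              shape = "linear", S0 = 1) {
  check_three_comp(d_i, f_i, d_sph, f_sph)
  check_directions(directions)
  mu <- directions[, 3]
  f_ec <- 1 - f_i - f_sph
  dax <- three_comp_dax(d_i, f_i, f_sph)
  stick <- axisym_attenuation(b, shape, mu, da = d_i, dr = 0)
  ball <- axisym_attenuation(b, shape, mu, da = d_sph, dr = d_sph)
  zepp <- axisym_attenuation(b, shape, mu, da = dax, dr = f_ec * dax)
  S0 * drop(f_i * stick + f_sph * ball + f_ec * zepp)
}

#' Zonal spherical-harmonic spectrum of a kernel
#'
#' Least-squares even-degree fit of kernel values sampled on a sphere grid,
#' keeping only the m = 0 coefficients. Kernels are axially symmetric, so the
#' discarded m != 0 content must be numerically negligible; exceeding
#' `leak_tol` of total energy raises an error.
#'
#' @param values Kernel values sampled at `directions`.
#' @param directions n x 3 unit vectors (default: the HEALPix nside-16 grid).
#' @param bandwidth Even maximum degree of the fit (default 8, matching the
#'   ODF bandwidth; higher-degree kernel content at large b is truncated).
#' @param leak_tol Maximum tolerated relative m != 0 energy.
#' @return Numeric vector of zonal coefficients \eqn{\hat{h}_{l0}}, one per
#'   even degree, with attribute `m_nonzero_energy` (relative).
#' @export
kernel_zonal_coeffs <- function(values, directions = NULL, bandwidth = 8,
                                leak_tol = 1e-4) {
  if (is.null(directions)) {
    ctx <- healpix_ctx(16)
    if (length(values) == ctx$npix) values <- values[ctx$half]
    if (length(values) != ctx$nhalf)
      stop("values must be sampled on the nside-16 grid when directions ",
           "are not supplied", call. = FALSE)
    cf <- if (bandwidth == 8) drop(ctx$P8 %*% values)
          else fit_coefficients_basis(values, build_basis(ctx$dirs_half, bandwidth),
                                      bandwidth)
  } else {
    cf <- fit_coefficients(values, directions, bandwidth)
  }
  zr <- sh_zonal_rows(bandwidth)
  tot <- sum(cf^2)
  leak <- if (tot == 0) 0 else (tot - sum(cf[zr]^2)) / tot
  if (leak > leak_tol)
    stop("kernel is not axially symmetric: m != 0 energy fraction ",
         format(leak), " exceeds ", leak_tol, call. = FALSE)
  structure(cf[zr], m_nonzero_energy = leak)
}

# sqrt(pi) * erf(sqrt(x)) / (2 sqrt(x)), the powder average of exp(-x mu^2),
# with a series expansion for small x (1 - x/3 + x^2/10 - x^3/42).
erf_mean <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10
  xs <- x[!small]
  out[!small] <- sqrt(pi) * (2 * stats::pnorm(sqrt(2 * xs)) - 1) / (2 * sqrt(xs))
  out
}

#' Closed-form powder-averaged two-compartment signal (SMT equation)
#'
#' The spherical mean of the stick + zeppelin kernel over orientations, which
#' does not depend on the ODF:
#' \deqn{S_{PA} = S_0\left[f\,\frac{\sqrt{\pi}\,\mathrm{erf}(\sqrt{bd})}{2\sqrt{bd}}
#'  + (1-f)\,e^{-b(1-f)d}\,\frac{\sqrt{\pi}\,\mathrm{erf}(\sqrt{bfd})}{2\sqrt{bfd}}\right].}
#' Numerically stable as \eqn{bd \to 0} or \eqn{bfd \to 0}.
#'
#' @param b b-value (ms/um^2), >= 0 (vectorized).
#' @param d Intra-neurite diffusivity (um^2/ms), >= 0 (vectorized).
#' @param f Intra-neurite signal fraction in \[0, 1\] (vectorized).
#' @param S0 Reference signal.
#' @return Powder-averaged signal (vectorized over the longest argument).
#' @export
smt_powder_signal <- function(b, d, f, S0 = 1) {
  n <- max(length(b), length(d), length(f))
  b <- rep_len(b, n); d <- rep_len(d, n); f <- rep_len(f, n)
  if (any(b < 0) || any(d < 0)) stop("b and d must be non-negative", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  S0 * (f * erf_mean(b * d) + (1 - f) * exp(-b * (1 - f) * d) * erf_mean(b * f * d))
}
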