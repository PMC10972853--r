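#' Synthetic voxels: ODF sampling, signal synthesis and Rician noise
#'
#' Training and evaluation data are generated on the fly. A voxel is an
#' (ODF, kernel-parameter) pair: the ODF is a random antipodally symmetric
#' Watson-lobe mixture expanded at bandwidth 8, parameters are drawn from
#' the model priors, noiseless signals come from frequency-domain spherical
#' convolution of the ODF with the kernel, and Rician noise at a stated SNR
#' is added to the normalized signals.
#'
#' All sampling functions draw from R's current RNG stream; callers control
#' reproducibility with `set.seed()` or the `seed` arguments of the batch
#' helpers.
#'
#' @name simulate
#' @keywords internal
NULL

#' Configuration of the synthetic ODF sampler
#'
#' @param max_lobes Maximum number of Watson lobes (1 to 3); the draw is
#'   uniform over `1:max_lobes`.
#' @param kappa_range Concentration range; kappa is log-uniform over it.
#' @param iso_range Range of the isotropic volume fraction (uniform).
#' @return A list of class `odf_config`.
#' @export
odf_config <- function(max_lobes = 3, kappa_range = c(1, 64),
                       iso_range = c(0.05, 0.5)) {
  stopifnot(max_lobes %in% 0:3, kappa_range[1] > 0,
            kappa_range[2] >= kappa_range[1],
            iso_range[1] >= 0, iso_range[2] <= 1)
  structure(list(max_lobes = max_lobes, kappa_range = kappa_range,
                 iso_range = iso_range), class = "odf_config")
}

#' Sample a synthetic fibre ODF
#'
#' Mixture of up to three antipodally symmetric Watson lobes (Haar-uniform
#' orientations, Dirichlet(1) weights, log-uniform concentration) on an
#' isotropic floor, projected to bandwidth 8 by least squares on the HEALPix
#' grid and normalized to integrate to 1. Draws violating the mild
#' non-negativity invariant (grid minimum >= -0.01 x maximum) are resampled.
#'
#' @param config An [odf_config()].
#' @return Coefficient vector (length 45, bandwidth 8) with
#'   `c00 = 1/sqrt(4 pi)`.
#' @export
sample_odf <- function(config = odf_config()) {
  ctx <- healpix_ctx(16)
  if (config$max_lobes == 0) {
    cf <- numeric(sh_ncoef(8)); cf[1] <- 1 / sqrt(4 * pi)
    return(cf)
  }
  for (attempt in 1:200) {
    K <- sample.int(config$max_lobes, 1)
    w <- stats::rexp(K); w <- w / sum(w)
    w0 <- stats::runif(1, config$iso_range[1], config$iso_range[2])
    kap <- exp(stats::runif(K, log(config$kappa_range[1]),
                            log(config$kappa_range[2])))
    mu <- matrix(stats::rnorm(3 * K), K, 3)
    mu <- mu / sqrt(rowSums(mu^2))
    V <- rep(w0 / (4 * pi), ctx$nhalf)
    t2 <- (ctx$dirs_half %*% t(mu))^2
    for (k in seq_len(K)) {
      U <- exp(kap[k] * (t2[, k] - 1))
      V <- V + (1 - w0) * w[k] * U / (mean(U) * 4 * pi)
    }
    cf <- drop(ctx$P8 %*% V)
    cf <- cf * (1 / sqrt(4 * pi)) / cf[1]
    vals <- drop(ctx$B8 %*% cf)
    if (min(vals) >= -0.01 * max(vals)) return(cf)
  }
  stop("failed to sample a non-negative band-limited ODF in 200 attempts",
       call. = FALSE)
}

#' Sample two-compartment parameters from the training prior
#'
#' `d ~ U(0, 3)` um^2/ms and `f ~ U(0, 1)`, independently.
#'
#' @param n Number of draws.
#' @return data.frame with columns `d` and `f`.
#' @export
sample_two_comp <- function(n = 1) {
  data.frame(d = stats::runif(n, 0, 3), f = stats::runif(n, 0, 1))
}

#' Sample three-compartment parameters from the training prior
#'
#' `d_i ~ U(0, 3)`, `f_i ~ U(0, 1)`, `d_sph ~ U(0, max(d_i, 0.5))` (the upper
#' bound corresponding to a 25-um sphere), `f_sph ~ U(0, 1 - f_i)`.
#'
#' @param n Number of draws.
#' @return data.frame with columns `d_i`, `f_i`, `d_sph`, `f_sph`.
#' @export
sample_three_comp <- function(n = 1) {
  d_i <- stats::runif(n, 0, 3)
  f_i <- stats::runif(n, 0, 1)
  d_sph <- stats::runif(n, 0, pmax(d_i, 0.5))
  f_sph <- stats::runif(n, 0, 1 - f_i)
  data.frame(d_i = d_i, f_i = f_i, d_sph = d_sph, f_sph = f_sph)
}

# Kernel values on the half grid for a batch of parameter draws:
# length(mu) x n matrix. params is the data.frame of the matching sampler.
kernel_values_batch <- function(b, shape, mu, params, model) {
  n <- nrow(params)
  mu2 <- mu^2
  if (model == "two") {
    d <- params$d; f <- params$f
    stick <- exp(-b * outer(mu2, d))
    if (shape == "planar")
      stick <- exp(-(b / 2) * (outer(rep(1, length(mu)), d) - outer(mu2, d)))
    # zeppelin: da = d, dr = (1 - f) d
    da <- d; dr <- (1 - f) * d
  } else {
    d_i <- params$d_i; f_i <- params$f_i
    d_sph <- params$d_sph; f_sph <- params$f_sph
    f_ec <- 1 - f_i - f_sph
    dax <- three_comp_dax(d_i, f_i, f_sph)
    stick <- axisym_attenuation(b, shape, mu, da = d_i, dr = rep(0, n))
    ball <- axisym_attenuation(b, shape, mu, da = d_sph, dr = d_sph)
    zepp <- axisym_attenuation(b, shape, mu, da = dax, dr = f_ec * dax)
    return(stick %*% diag(f_i, n) + ball %*% diag(f_sph, n) +
             zepp %*% diag(f_ec, n))
  }
  zepp <- axisym_attenuation(b, shape, mu, da = da, dr = dr)
  sweep(stick, 2, f, "*") + sweep(zepp, 2, 1 - f, "*")
}

# Vectorized noiseless signal synthesis for a batch: odf (45 x n), params
# data.frame, scheme. Returns n_meas x n. b0 rows are 1.
simulate_batch_signals <- function(odf, params, scheme,
                                   model = if ("d" %in% names(params)) "two" else "three") {
  ctx <- healpix_ctx(16)
  sctx <- scheme_ctx(scheme)
  n <- ncol(odf)
  idx <- sh_index(8)
  # Funk-Hecke normalization: the SO(3) convolution theorem's 2 pi factor
  # belongs to the unnormalized Haar measure; physical signals from an ODF
  # integrating to 1 use sqrt(4 pi / (2l + 1)) so that the powder mean of the
  # simulated signal equals the closed-form SMT equation.
  fac <- zonal_conv_factor(idx$l) / (2 * pi)
  deg_row <- idx$l / 2 + 1
  S <- matrix(1, scheme$n_meas, n)
  for (s in seq_along(scheme$shells)) {
    sh <- scheme$shells[[s]]
    K <- kernel_values_batch(sh$b, sh$shape, ctx$dirs_half[, 3], params, model)
    h <- ctx$Z8 %*% K                            # 5 x n zonal spectra
    y <- odf * (fac * h[deg_row, , drop = FALSE])
    S[sh$rows, ] <- sctx$shells[[s]]$B %*% y
  }
  S
}

#' Simulate noiseless signals for one voxel
#'
#' Builds the kernel on the HEALPix nside-16 grid, extracts its zonal
#' spectrum, convolves with the ODF in the frequency domain, and evaluates at
#' each shell's encoding directions. b = 0 measurements return 1.
#'
#' @param odf Coefficient vector of the ODF (bandwidth 8).
#' @param params Named list or one-row data.frame: `d`, `f` for the
#'   two-compartment model or `d_i`, `f_i`, `d_sph`, `f_sph` for the
#'   three-compartment model.
#' @param scheme An `acq_scheme`.
#' @return Numeric vector of length `scheme$n_meas`, values in (0, 1].
#' @export
simulate_signals <- function(odf, params, scheme) {
  params <- as.data.frame(params)
  model <- if ("d" %in% names(params)) "two" else "three"
  if (model == "two") check_two_comp(params$d, params$f)
  else check_three_comp(params$d_i, params$f_i, params$d_sph, params$f_sph)
  drop(simulate_batch_signals(matrix(odf, ncol = 1), params, scheme, model))
}

#' Add Rician noise to signals
#'
#' \eqn{S_{noisy} = \sqrt{(S + X)^2 + Y^2}} with X, Y i.i.d. zero-mean
#' Gaussians of standard deviation 1/SNR, the noise law of magnitude MR
#' images on b0-normalized data.
#'
#' @param clean Numeric vector or matrix of noiseless signals.
#' @param snr Signal-to-noise ratio (> 0, may be `Inf` for no noise).
#' @return Noisy signals, same shape.
#' @export
add_rician_noise <- function(clean, snr) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (!is.finite(snr)) return(clean)
  sigma <- 1 / snr
  X <- stats::rnorm(length(clean), 0, sigma)
  Y <- stats::rnorm(length(clean), 0, sigma)
  out <- sqrt((clean + X)^2 + Y^2)
  if (is.matrix(clean)) matrix(out, nrow(clean), ncol(clean)) else out
}

# Haar-uniform ZYZ Euler angles.
sample_haar_rotation <- function(n = 1) {
  cbind(alpha = stats::runif(n, 0, 2 * pi),
        beta = acos(stats::runif(n, -1, 1)),
        gamma = stats::runif(n, 0, 2 * pi))
}

#' Generate a batch of synthetic voxels with training targets
#'
#' @param n Number of voxels.
#' @param scheme An `acq_scheme`.
#' @param snr SNR of the Rician noise (default 50, the HARDI protocol level;
#'   use 29 for the tensor-valued protocol, `Inf` for noiseless data).
#' @param rotate If `TRUE`, each ODF is rotated by a Haar-uniform random
#'   rotation before simulation (data augmentation).
#' @param model `"two"` or `"three"` compartment kernel.
#' @param config ODF sampler configuration.
#' @param seed Optional seed for ODFs, parameters and rotations.
#' @param noise_seed Optional separate seed for the Rician noise, so clean
#'   signals are invariant to it.
#' @return List with `odf` (45 x n coefficients, after rotation), `params`
#'   (data.frame), `clean` and `noisy` (n_meas x n signal matrices), `snr`,
#'   and `targets = list(odf_grid, scalars)` where `odf_grid` holds ODF
#'   values on the antipodal half of the HEALPix nside-16 grid and `scalars`
#'   is an n x n_param matrix in physical units.
#' @export
make_batch <- function(n, scheme, snr = 50, rotate = TRUE, model = "two",
                       config = odf_config(), seed = NULL, noise_seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ctx <- healpix_ctx(16)
  params <- if (model == "two") sample_two_comp(n) else sample_three_comp(n)
  odf <- vapply(seq_len(n), function(i) sample_odf(config),
                numeric(sh_ncoef(8)))
  if (rotate) {
    ang <- sample_haar_rotation(n)
    for (i in seq_len(n))
      odf[, i] <- rotate_sh(odf[, i], 8, ang[i, 1], ang[i, 2], ang[i, 3])
  }
  clean <- simulate_batch_signals(odf, params, scheme, model)
  if (!is.null(noise_seed)) set.seed(noise_seed)
  noisy <- add_rician_noise(clean, snr)
  list(odf = odf, params = params, clean = clean, noisy = noisy, snr = snr,
       targets = list(odf_grid = ctx$B8 %*% odf,
                      scalars = as.matrix(params)))
}
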