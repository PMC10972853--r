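#' Spherical mean technique fit and constrained spherical deconvolution
#'
#' The SMT baseline estimates (d, f) by fitting the closed-form
#' powder-average equation to per-shell spherical means -- by construction
#' exactly rotation invariant, since powder means do not depend on
#' orientation. The ODF is then recovered by deconvolving the measured
#' signals with the fitted kernel: a regularized least-squares solve in the
#' spherical-harmonic domain with iterative suppression of negative ODF
#' values on the sphere grid.
#'
#' @name baselines
#' @keywords internal
NULL

#' Fit the two-compartment SMT model to powder-averaged data
#'
#' Bounded least squares over d in \[1e-4, 4\] um^2/ms and f in \[0, 1\],
#' multi-started at f = 0.1, 0.5, 0.9 (best objective wins, ties broken by
#' smaller f).
#'
#' @param means Per-shell powder-averaged signals (b0-normalized).
#' @param bvals Matching b-values (ms/um^2); at least two distinct non-zero
#'   values are required for identifiability.
#' @return Named vector `c(d, f)` with attributes `objective` and
#'   `degenerate` (TRUE when the fit hit the lower d bound, e.g. for
#'   unattenuated signals).
#' @export
smt_fit <- function(means, bvals) {
  if (any(!is.finite(means)) || any(!is.finite(bvals)))
    stop("non-finite inputs to smt_fit", call. = FALSE)
  nz <- bvals > 0.05
  if (length(unique(round(bvals[nz], 6))) < 2)
    stop("smt_fit needs at least two distinct non-zero b-values ",
         "(single-shell data is unidentifiable)", call. = FALSE)
  obj <- function(p) {
    # guard tiny boundary transgressions of the box-constrained optimizer
    d <- min(max(p[1], 0), 4); f <- min(max(p[2], 0), 1)
    sum((means - smt_powder_signal(bvals, d, f))^2)
  }
  best <- NULL
  for (f0 in c(0.1, 0.5, 0.9)) {
    fit <- stats::optim(c(1, f0), obj, method = "L-BFGS-B",
                        lower = c(1e-4, 0), upper = c(4, 1),
                        control = list(factr = 1, pgtol = 1e-12,
                                       maxit = 200,
                                       ndeps = c(1e-7, 1e-7)))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[2] < best$par[2]))
      best <- fit
  }
  structure(c(d = best$par[1], f = best$par[2]),
            objective = best$value,
            degenerate = best$par[1] <= 1e-4 + 1e-9)
}

# vectorized smt fit over voxels: means (nshell x n) -> data.frame(d, f)
smt_fit_many <- function(means, bvals) {
  out <- apply(means, 2, smt_fit, bvals = bvals)
  data.frame(d = out[1, ], f = out[2, ])
}

#' ODF by constrained spherical deconvolution with a known kernel
#'
#' Solves the stacked per-shell deconvolution problem for the bandwidth-8 ODF
#' coefficients by regularized least squares, iteratively adding soft
#' penalties on HEALPix grid points where the current ODF estimate is
#' negative (hard-threshold reweighting, at most `max_iter` iterations), and
#' normalizes the result to integrate to 1.
#'
#' @param signals Measured signals for one voxel (length n_meas) or matrix
#'   (n_meas x n).
#' @param h_shells Matrix of kernel zonal coefficients (n_degrees x
#'   n_shells), e.g. from [kernel_zonal_coeffs()] per shell.
#' @param scheme The `acq_scheme`.
#' @param lambda Small Tikhonov weight keeping unobservable degrees at zero.
#' @param tau Weight of the negativity penalty rows.
#' @param max_iter Maximum constraint iterations.
#' @return Coefficient vector (or matrix) of the ODF, bandwidth 8,
#'   `c00 = 1/sqrt(4 pi)`.
#' @export
csd_odf <- function(signals, h_shells, scheme, lambda = 1e-6, tau = 1,
                    max_iter = 50) {
  S <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  ctx <- healpix_ctx(16)
  idx <- sh_index(8)
  fac <- zonal_conv_factor(idx$l) / (2 * pi)   # physical convolution gain
  sctx <- scheme_ctx(scheme)
  n <- ncol(S)
  out <- matrix(0, sh_ncoef(8), n)
  for (v in seq_len(n)) {
    A <- do.call(rbind, lapply(seq_along(scheme$shells), function(s) {
      g <- fac * h_shells[idx$l / 2 + 1, s]
      sweep(sctx$shells[[s]]$B, 2, g, "*")
    }))
    y <- unlist(lapply(scheme$shells, function(s) S[s$rows, v]))
    AtA <- crossprod(A); Aty <- crossprod(A, y)
    diag(AtA) <- diag(AtA) + lambda
    x <- solve(AtA, Aty)
    for (it in seq_len(max_iter)) {
      vals <- ctx$B8 %*% x
      neg <- which(vals < 0)
      if (length(neg) == 0 || min(vals) >= -0.01 * max(vals)) break
      Bn <- ctx$B8[neg, , drop = FALSE]
      x <- solve(AtA + tau * crossprod(Bn), Aty)
    }
    if (abs(x[1]) > 1e-12) x <- x * (1 / sqrt(4 * pi)) / x[1]
    out[, v] <- x
  }
  if (is.matrix(signals)) out else drop(out)
}

# --- estimator closures -----------------------------------------------------

# canonical scalar-output names by model dimensionality
scalar_names <- function(k) {
  if (k == 2) c("d", "f") else if (k == 4) c("d_i", "f_i", "d_sph", "f_sph")
  else paste0("par", seq_len(k))
}

#' Estimator interfaces for the benchmark procedures
#'
#' Each returns a function mapping a b0-normalized signal matrix
#' (n_meas x n) to `list(odf = 45 x n coefficients, scalars = n x k)`.
#' `smt_estimator` fits powder means per voxel and deconvolves the ODF with
#' the fitted kernel; the network estimators run the trained model in
#' evaluation mode.
#'
#' @param model Trained model (`scnn` or `mlp`).
#' @param scheme The `acq_scheme` the signals follow.
#' @param with_odf For `smt_estimator`: also run the CSD step (slower).
#' @return A function of one argument (the signal matrix).
#' @export
scnn_estimator <- function(model, scheme) {
  force(model); force(scheme)
  function(signals) {
    X <- signal_features(signals, scheme, "scnn")
    fwd <- scnn_forward(model, X)
    colnames(fwd$scalars) <- scalar_names(ncol(fwd$scalars))
    list(odf = fwd$odf, scalars = fwd$scalars)
  }
}

#' @rdname scnn_estimator
#' @export
mlp_estimator <- function(model, scheme) {
  force(model); force(scheme)
  function(signals) {
    X <- signal_features(signals, scheme, "mlp")
    fwd <- mlp_forward(model, X)
    colnames(fwd$scalars) <- scalar_names(ncol(fwd$scalars))
    list(odf = fwd$odf, scalars = fwd$scalars)
  }
}

#' @rdname scnn_estimator
#' @export
smt_estimator <- function(scheme, with_odf = TRUE) {
  force(scheme); force(with_odf)
  bvals <- vapply(scheme$shells, function(s) s$b, 1)
  function(signals) {
    S <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
    pa <- powder_average(S, scheme)
    est <- smt_fit_many(pa, bvals)
    odf <- NULL
    if (with_odf) {
      ctx <- healpix_ctx(16)
      odf <- matrix(0, sh_ncoef(8), ncol(S))
      for (v in seq_len(ncol(S))) {
        h <- vapply(seq_along(scheme$shells), function(s) {
          K <- kernel_values_batch(scheme$shells[[s]]$b,
                                   scheme$shells[[s]]$shape,
                                   ctx$dirs_half[, 3], est[v, , drop = FALSE],
                                   "two")
          drop(ctx$Z8 %*% K)
        }, numeric(5))
        odf[, v] <- csd_odf(S[, v], h, scheme)
      }
    }
    list(odf = odf, scalars = as.matrix(est))
  }
}
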