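#' Benchmark procedures: test-set accuracy and rotational variance
#'
#' Two complementary evaluations. Test-set MSE measures how well an
#' estimator recovers the ODF (spatial-domain MSE over the HEALPix grid) and
#' the scalar parameters (MSE in physical units) on freshly simulated noisy
#' voxels. Rotational variance measures how much the scalar estimates change
#' when the same microstructural configuration is presented at many
#' orientations -- the headline property of the rotationally equivariant
#' network. No noise is used there, so any variation is attributable to the
#' estimator.
#'
#' @name evaluate
#' @keywords internal
NULL

#' Test-set mean squared error of an estimator
#'
#' @param estimator Function from a signal matrix to
#'   `list(odf, scalars)` (see [scnn_estimator()]).
#' @param batch A test batch from [make_batch()].
#' @param bins Optional number of uniform bins per parameter; when given,
#'   scalar MSEs are additionally binned over the first two parameters
#'   (the layout of per-(d, f) error maps).
#' @return List with `odf_mse` (NA if the estimator returns no ODF),
#'   `scalar_mse` (named per-parameter vector) and optionally `binned`
#'   (list of matrices).
#' @export
test_mse <- function(estimator, batch, bins = NULL) {
  pred <- estimator(batch$noisy)
  ctx <- healpix_ctx(16)
  odf_mse <- NA_real_
  if (!is.null(pred$odf))
    odf_mse <- mean((ctx$B8 %*% pred$odf - batch$targets$odf_grid)^2)
  tg <- batch$targets$scalars
  err2 <- (pred$scalars - tg)^2
  scalar_mse <- colMeans(err2)
  names(scalar_mse) <- colnames(tg)
  out <- list(odf_mse = odf_mse, scalar_mse = scalar_mse,
              n = nrow(tg))
  if (!is.null(bins)) {
    p1 <- tg[, 1]; p2 <- tg[, 2]
    b1 <- pmin(bins, 1L + floor(bins * p1 / max(p1 + 1e-12)))
    b2 <- pmin(bins, 1L + floor(bins * p2 / max(p2 + 1e-12)))
    out$binned <- lapply(seq_len(ncol(tg)), function(j)
      tapply(err2[, j], list(b1, b2), mean))
    names(out$binned) <- colnames(tg)
  }
  out
}

#' Rotational variance of an estimator
#'
#' For each of `n_configs` random microstructural configurations, noiseless
#' signals are simulated with the configuration's ODF rotated to every
#' orientation in `rotations`; the estimator runs on each, and the sample
#' standard deviation (n - 1 normalization) of each scalar estimate over the
#' rotations is recorded. Reported is the mean standard deviation over
#' configurations.
#'
#' @param estimator Estimator function (see [scnn_estimator()]).
#' @param scheme The `acq_scheme`.
#' @param n_configs Number of random configurations.
#' @param rotations Matrix of ZYZ Euler angles (n_rot x 3), e.g.
#'   [so3_grid()].
#' @param model `"two"` or `"three"`.
#' @param config ODF sampler configuration.
#' @param seed Seed for the configurations.
#' @return List with `mean_std` (named per-parameter vector) and `per_config`
#'   (n_configs x n_param matrix of standard deviations).
#' @export
rotational_variance <- function(estimator, scheme, n_configs = 24,
                                rotations = so3_grid(5), model = "two",
                                config = odf_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nrot <- nrow(rotations)
  Rmats <- lapply(seq_len(nrot), function(i)
    sh_rotation_matrix(8, rotations[i, 1], rotations[i, 2], rotations[i, 3]))
  per <- NULL
  for (cidx in seq_len(n_configs)) {
    params <- if (model == "two") sample_two_comp(1) else sample_three_comp(1)
    odf0 <- sample_odf(config)
    odfs <- vapply(Rmats, function(R) drop(R %*% odf0), numeric(length(odf0)))
    clean <- simulate_batch_signals(odfs, params[rep(1, nrot), , drop = FALSE],
                                    scheme, model)
    est <- estimator(clean)
    sds <- apply(est$scalars, 2, stats::sd)
    if (is.null(per)) per <- matrix(0, n_configs, length(sds),
                                    dimnames = list(NULL, names(params)))
    per[cidx, ] <- sds
  }
  list(mean_std = colMeans(per), per_config = per)
}
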