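#' Diffusion-encoding b-tensors and acquisition schemes
#'
#' A measurement is described by a 3x3 symmetric positive semi-definite
#' b-tensor (units ms/um^2) whose trace is the b-value and whose shape
#' (linear, planar) selects the encoding geometry. Measurements sharing a
#' (b-value, shape) form a shell; an acquisition scheme is an ordered list of
#' measurements with a stable shell structure that also defines the network
#' input layout.
#'
#' @name encoding
#' @keywords internal
NULL

check_unit_axis <- function(axis, tol = 1e-9) {
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > tol)
    stop("axis must be a 3-vector of unit norm", call. = FALSE)
  invisible(axis)
}

#' Linear (stick-like) b-tensor
#'
#' @param b b-value in ms/um^2 (>= 0).
#' @param axis Unit 3-vector along the encoding direction.
#' @return 3x3 matrix `b * axis axis^T` with attribute `shape_tag = "linear"`.
#' @export
linear_btensor <- function(b, axis) {
  if (b < 0) stop("b must be non-negative", call. = FALSE)
  check_unit_axis(axis)
  M <- b * tcrossprod(axis)
  attr(M, "shape_tag") <- "linear"
  M
}

#' Planar (disc-like) b-tensor
#'
#' @param b b-value in ms/um^2 (>= 0).
#' @param axis Unit 3-vector along the symmetry axis (normal of the
#'   encoding plane).
#' @return 3x3 matrix `(b/2) (I - axis axis^T)` with attribute
#'   `shape_tag = "planar"`.
#' @export
planar_btensor <- function(b, axis) {
  if (b < 0) stop("b must be non-negative", call. = FALSE)
  check_unit_axis(axis)
  M <- (b / 2) * (diag(3) - tcrossprod(axis))
  attr(M, "shape_tag") <- "planar"
  M
}

#' Generalized scalar product of a b-tensor and a diffusion tensor
#'
#' \eqn{b\!:\!D = \sum_{ij} b_{ij} D_{ij}}, the exponent of the Gaussian
#' signal attenuation \eqn{\exp(-b\!:\!D)}.
#'
#' @param btensor,D 3x3 symmetric matrices.
#' @return Scalar.
#' @export
btensor_contract <- function(btensor, D) sum(btensor * D)

#' Construct an acquisition scheme from per-measurement descriptions
#'
#' @param bvals Numeric vector of b-values (ms/um^2), one per measurement.
#' @param axes n x 3 matrix of symmetry axes (rows may be NA for b = 0).
#' @param shapes Character vector, `"linear"` or `"planar"` per measurement
#'   (ignored for b = 0).
#' @param b0_threshold Measurements with b below this are grouped as b0.
#' @param shell_tol Measurements within this b-value distance (and with equal
#'   shape) share a shell.
#' @return An object of class `acq_scheme`: list with elements `bvals`,
#'   `shape`, `axes`, `shell_id` (NA for b0), `shells` (list of
#'   `list(b, shape, directions, rows)`), `n_b0`, `n_meas`, `dwi_rows`.
#' @export
acquisition_scheme <- function(bvals, axes, shapes = "linear",
                               b0_threshold = 0.05, shell_tol = 0.05) {
  n <- length(bvals)
  if (length(shapes) == 1) shapes <- rep(shapes, n)
  if (!is.matrix(axes) || nrow(axes) != n || ncol(axes) != 3)
    stop("axes must be an n x 3 matrix matching bvals", call. = FALSE)
  is_b0 <- bvals <= b0_threshold
  shape <- ifelse(is_b0, "b0", shapes)
  shell_id <- rep(NA_integer_, n)
  shells <- list()
  for (i in which(!is_b0)) {
    placed <- FALSE
    for (s in seq_along(shells)) {
      if (shells[[s]]$shape == shape[i] &&
          abs(shells[[s]]$b - bvals[i]) <= shell_tol) {
        shell_id[i] <- s
        shells[[s]]$rows <- c(shells[[s]]$rows, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      shells[[length(shells) + 1L]] <- list(b = bvals[i], shape = shape[i],
                                            rows = i)
      shell_id[i] <- length(shells)
    }
  }
  for (s in seq_along(shells)) {
    rows <- shells[[s]]$rows
    d <- axes[rows, , drop = FALSE]
    nrm <- sqrt(rowSums(d^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      if (any(abs(nrm - 1) > 0.01) || any(nrm == 0))
        stop("non-unit encoding axis in shell ", s,
             " (max |norm - 1| > 1%)", call. = FALSE)
      warning("normalizing encoding axes with norms within 1% of 1")
    }
    shells[[s]]$directions <- d / nrm
    shells[[s]]$b <- mean(bvals[rows])
  }
  structure(list(bvals = bvals, shape = shape, axes = axes,
                 shell_id = shell_id, shells = shells,
                 n_b0 = sum(is_b0), n_meas = n, dwi_rows = which(!is_b0)),
            class = "acq_scheme")
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("Acquisition scheme:", x$n_meas, "measurements,", x$n_b0, "b0,",
      length(x$shells), "shells\n")
  for (s in seq_along(x$shells))
    cat(sprintf("  shell %d: b = %.3g ms/um^2, %s, %d directions\n",
                s, x$shells[[s]]$b, x$shells[[s]]$shape,
                nrow(x$shells[[s]]$directions)))
  invisible(x)
}

# 3x3 b-tensor for measurement i of a scheme.
scheme_btensor <- function(scheme, i) {
  if (scheme$shape[i] == "b0") return(matrix(0, 3, 3))
  ax <- scheme$axes[i, ] / sqrt(sum(scheme$axes[i, ]^2))
  if (scheme$shape[i] == "planar") planar_btensor(scheme$bvals[i], ax)
  else linear_btensor(scheme$bvals[i], ax)
}

#' Two-shell HARDI acquisition scheme
#'
#' The clinical protocol emulated by the simulator: linear encoding at
#' b = 1 and 2.2 ms/um^2 with 60 electrostatic-repulsion directions over half
#' a sphere per shell (antipodal symmetry is carried by the even basis, so
#' directions are not duplicated).
#'
#' @param n_b0 Number of b = 0 measurements to prepend (default 0; real
#'   acquisitions carry them, simulated normalized data does not need them).
#' @return An `acq_scheme`.
#' @export
hardi_scheme <- function(n_b0 = 0) {
  d1 <- repulsion_directions(60)
  # decorrelate the two shells with a fixed rotation
  d2 <- d1 %*% t(rotation_matrix_zyz(0.41, 0.77, 1.93))
  bvals <- c(rep(0, n_b0), rep(1, 60), rep(2.2, 60))
  axes <- rbind(matrix(NA_real_, n_b0, 3), d1, d2)
  acquisition_scheme(bvals, axes, "linear")
}

#' Tensor-valued (linear + planar) acquisition scheme
#'
#' Linear b-tensors at b = 0.5, 1, 2, 3.5, 5 ms/um^2 with 12, 12, 20, 20, 30
#' directions and planar b-tensors at b = 0.5, 1, 2 ms/um^2 with 12, 12, 20
#' directions (half-sphere electrostatic-repulsion sets), the protocol used
#' for the three-compartment model.
#'
#' @inheritParams hardi_scheme
#' @return An `acq_scheme` with 8 shells.
#' @export
tensor_scheme <- function(n_b0 = 0) {
  spec <- list(list(0.5, 12, "linear"), list(1, 12, "linear"),
               list(2, 20, "linear"), list(3.5, 20, "linear"),
               list(5, 30, "linear"), list(0.5, 12, "planar"),
               list(1, 12, "planar"), list(2, 20, "planar"))
  bvals <- rep(0, n_b0); axes <- matrix(NA_real_, n_b0, 3); shapes <- character(n_b0)
  for (k in seq_along(spec)) {
    n <- spec[[k]][[2]]
    d <- repulsion_directions(n) %*%
      t(rotation_matrix_zyz(0.31 * k, 0.57 * k, 1.13 * k))
    bvals <- c(bvals, rep(spec[[k]][[1]], n))
    axes <- rbind(axes, d)
    shapes <- c(shapes, rep(spec[[k]][[3]], n))
  }
  shapes[seq_len(n_b0)] <- "linear"
  acquisition_scheme(bvals, axes, shapes)
}

#' Powder average (spherical mean) of signals per shell
#'
#' @param signals Numeric vector (one measurement each) or matrix
#'   (n_meas x n_voxels).
#' @param scheme An `acq_scheme`.
#' @return Matrix n_shells x n_voxels of per-shell arithmetic means, with
#'   attributes `bvals` and `shapes` describing the shells.
#' @export
powder_average <- function(signals, scheme) {
  S <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  if (nrow(S) != scheme$n_meas)
    stop("signal count (", nrow(S), ") does not match scheme (",
         scheme$n_meas, ")", call. = FALSE)
  if (any(vapply(scheme$shells, function(s) length(s$rows), 1L) == 0))
    stop("empty shell in scheme", call. = FALSE)
  out <- do.call(rbind, lapply(scheme$shells, function(s)
    colMeans(S[s$rows, , drop = FALSE])))
  attr(out, "bvals") <- vapply(scheme$shells, function(s) s$b, 1)
  attr(out, "shapes") <- vapply(scheme$shells, function(s) s$shape, "")
  out
}

#' Voxelwise SNR from repeated b = 0 measurements
#'
#' SNR is the reciprocal of the standard deviation of the b0 signals after
#' dividing by their mean, the rule used to match simulation noise to
#' acquired data. Voxels with identical b0s get `Inf`.
#'
#' @param b0_signals Numeric vector (one voxel) or matrix
#'   (n_voxels x n_b0).
#' @return Numeric vector of per-voxel SNR estimates.
#' @export
estimate_snr <- function(b0_signals) {
  X <- if (is.matrix(b0_signals)) b0_signals else matrix(b0_signals, nrow = 1)
  if (ncol(X) < 2)
    stop("at least two b0 measurements are required to estimate SNR",
         call. = FALSE)
  mu <- rowMeans(X)
  sd_norm <- apply(X / mu, 1, stats::sd)
  ifelse(sd_norm == 0, Inf, 1 / sd_norm)
}
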