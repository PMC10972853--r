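#' Volume I/O, gradient tables and voxelwise map generation
#'
#' Real acquisitions arrive as 4-D NIfTI volumes with FSL-dialect bval/bvec
#' text files (and, for tensor-valued schemes, a six-column b-tensor sidecar
#' in ms/um^2). These readers build an `acq_scheme` from the files;
#' [predict_volume()] runs any estimator voxelwise inside a brain mask and
#' writes parameter maps and an ODF coefficient volume that preserve the
#' input affine.
#'
#' @name io_cli
#' @keywords internal
NULL

#' Read FSL-dialect bval/bvec files (and optional b-tensor sidecar)
#'
#' bval: one row of b-values. bvec: three rows of direction components.
#' b-values are interpreted in ms/um^2 if their maximum is below 50,
#' otherwise s/mm^2 (divided by 1000). The optional sidecar holds one row
#' per measurement with the six unique tensor elements
#' (xx yy zz xy xz yz) in ms/um^2; tensor shapes are classified from
#' eigenvalues (one dominant: linear; two equal nonzero: planar).
#'
#' @param bval_path,bvec_path Paths to the gradient table files.
#' @param btensor_path Optional path to the b-tensor sidecar.
#' @param b0_threshold b-values at or below this (ms/um^2) count as b0.
#' @return An `acq_scheme`.
#' @export
read_scheme <- function(bval_path, bvec_path, btensor_path = NULL,
                        b0_threshold = 0.05) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) == 3) bvec <- t(bvec)
  if (nrow(bvec) != length(bvals))
    stop("bval/bvec length mismatch: ", length(bvals), " b-values vs ",
         nrow(bvec), " vectors", call. = FALSE)
  if (max(bvals) > 50) bvals <- bvals / 1000   # s/mm^2 -> ms/um^2
  if (is.null(btensor_path)) {
    axes <- bvec
    nrm <- sqrt(rowSums(axes^2))
    dwi <- bvals > b0_threshold
    bad <- dwi & (abs(nrm - 1) > 0.01)
    if (any(bad))
      stop("non-unit bvec column(s) at measurement(s) ",
           paste(which(bad), collapse = ", "), " (norm off by > 1%)",
           call. = FALSE)
    if (any(dwi & abs(nrm - 1) > 1e-6)) {
      warning("normalizing bvec columns with norms within 1% of 1")
      axes[dwi, ] <- axes[dwi, ] / nrm[dwi]
    }
    return(acquisition_scheme(bvals, axes, "linear",
                              b0_threshold = b0_threshold))
  }
  bt <- as.matrix(utils::read.table(btensor_path))
  if (ncol(bt) != 6 || nrow(bt) != length(bvals))
    stop("b-tensor sidecar must have 6 columns and one row per measurement",
         call. = FALSE)
  axes <- matrix(NA_real_, nrow(bt), 3)
  shapes <- character(nrow(bt))
  bv <- numeric(nrow(bt))
  for (i in seq_len(nrow(bt))) {
    M <- matrix(c(bt[i, 1], bt[i, 4], bt[i, 5],
                  bt[i, 4], bt[i, 2], bt[i, 6],
                  bt[i, 5], bt[i, 6], bt[i, 3]), 3, 3)
    bv[i] <- sum(diag(M))
    if (bv[i] <= b0_threshold) { shapes[i] <- "linear"; next }
    e <- eigen(M, symmetric = TRUE)
    ev <- e$values / bv[i]
    if (ev[1] > 0.9) {                     # single dominant eigenvalue
      shapes[i] <- "linear"; axes[i, ] <- e$vectors[, 1]
    } else if (abs(ev[1] - 0.5) < 0.1 && ev[3] < 0.1) {
      shapes[i] <- "planar"; axes[i, ] <- e$vectors[, 3]   # symmetry axis
    } else {
      stop("unsupported general b-tensor shape at row ", i,
           " (normalized eigenvalues ", paste(round(ev, 3), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  acquisition_scheme(bv, axes, shapes, b0_threshold = b0_threshold)
}

#' Bundle a 4-D data array, affine and mask
#'
#' @param data 4-D numeric array (x, y, z, measurement).
#' @param affine 4x4 spatial transform.
#' @param mask 3-D logical array matching the spatial dimensions (default:
#'   voxels with positive mean signal).
#' @return List of class `volume_stack`.
#' @export
volume_stack <- function(data, affine = diag(4), mask = NULL) {
  stopifnot(length(dim(data)) == 4)
  if (is.null(mask)) mask <- apply(data, 1:3, mean) > 0
  stopifnot(all(dim(mask) == dim(data)[1:3]))
  structure(list(data = data, affine = affine, mask = mask),
            class = "volume_stack")
}

#' Read a 4-D NIfTI volume (plus optional mask) into a volume stack
#'
#' @param path Path to the 4-D NIfTI file.
#' @param mask_path Optional path to a 3-D mask NIfTI.
#' @return A `volume_stack`.
#' @export
read_volume <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  mask <- if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    array(as.numeric(m) > 0, dim(m))
  } else NULL
  vs <- volume_stack(arr, affine = RNifti::xform(img), mask = mask)
  vs$template <- img
  vs
}

#' Write a parameter map (or coefficient volume) as NIfTI
#'
#' @param arr 3-D or 4-D numeric array.
#' @param template Optional NIfTI object whose header/affine to reuse.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_map <- function(arr, template, path) {
  if (!is.null(template)) {
    img <- RNifti::asNifti(arr, reference = template)
    RNifti::writeNifti(img, path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  }
  invisible(path)
}

#' Voxelwise parameter and ODF maps from a 4-D volume
#'
#' Normalizes every masked voxel by its mean b0 signal, runs the estimator,
#' and returns scalar parameter maps plus a 4-D ODF coefficient volume.
#' Voxels with non-positive mean b0 are masked out (their count is
#' reported via a message).
#'
#' @param volumes A `volume_stack`; 4th dimension must match the scheme.
#' @param scheme The matching `acq_scheme` (with its b0 measurements).
#' @param estimator An estimator function (see [scnn_estimator()]), or a
#'   trained model object (its scheme fingerprint is then checked against
#'   `scheme`).
#' @param fill Value outside the mask.
#' @param block Number of voxels estimated per block.
#' @return List with `maps` (named list of 3-D arrays), `odf` (4-D array of
#'   45 coefficient volumes) and `n_dropped`.
#' @export
predict_volume <- function(volumes, scheme, estimator, fill = NA_real_,
                           block = 4096) {
  stopifnot(inherits(volumes, "volume_stack"))
  if (dim(volumes$data)[4] != scheme$n_meas)
    stop("volume has ", dim(volumes$data)[4], " measurements but the scheme ",
         "defines ", scheme$n_meas, call. = FALSE)
  if (inherits(estimator, "sphmicro_model")) {
    model <- estimator
    fp <- model$scheme_fingerprint
    if (!is.null(fp) && !is.na(fp) && !identical(fp, digest_scheme(scheme)))
      stop("checkpoint scheme fingerprint does not match the supplied ",
           "scheme:\n  checkpoint: ", fp, "\n  scheme:     ",
           digest_scheme(scheme), call. = FALSE)
    estimator <- if (model$kind == "scnn") scnn_estimator(model, scheme)
                 else mlp_estimator(model, scheme)
  }
  sp <- dim(volumes$data)[1:3]
  vox <- which(volumes$mask)
  M <- matrix(aperm(volumes$data, c(4, 1, 2, 3)),
              dim(volumes$data)[4], prod(sp))[, vox, drop = FALSE]
  b0_rows <- which(scheme$shape == "b0")
  if (length(b0_rows) > 0) {
    s0 <- colMeans(M[b0_rows, , drop = FALSE])
  } else s0 <- rep(1, ncol(M))
  ok <- is.finite(s0) & s0 > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " voxel(s) with non-positive mean b0 masked out")
  vox <- vox[ok]
  M <- sweep(M[, ok, drop = FALSE], 2, s0[ok], "/")
  scalars <- NULL; odfs <- NULL
  for (start in seq(1, length(vox), by = block)) {
    ii <- start:min(start + block - 1, length(vox))
    est <- estimator(M[, ii, drop = FALSE])
    scalars <- rbind(scalars, est$scalars)
    if (!is.null(est$odf)) odfs <- cbind(odfs, est$odf)
  }
  par_names <- colnames(scalars)
  if (is.null(par_names)) par_names <- paste0("par", seq_len(ncol(scalars)))
  maps <- lapply(seq_len(ncol(scalars)), function(j) {
    m <- array(fill, sp); m[vox] <- scalars[, j]; m
  })
  names(maps) <- par_names
  odf_vol <- NULL
  if (!is.null(odfs)) {
    odf_vol <- array(fill, c(sp, nrow(odfs)))
    for (j in seq_len(nrow(odfs))) {
      m <- array(fill, sp); m[vox] <- odfs[j, ]
      odf_vol[, , , j] <- m
    }
  }
  list(maps = maps, odf = odf_vol, n_dropped = n_dropped)
}
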