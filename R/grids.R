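#' HEALPix pixel-center directions (RING scheme)
#'
#' Unit vectors pointing at the pixel centers of the Hierarchical Equal Area
#' isoLatitude Pixelisation of the sphere. The tessellation has
#' \eqn{12\,n_{side}^2} equal-area pixels arranged on iso-latitude rings;
#' nside 16 gives the 3072-direction grid used for all frequency/spatial
#' conversions in this package.
#'
#' @param nside Resolution parameter, a power of 2.
#' @return A `12 * nside^2` x 3 matrix of unit vectors with attribute
#'   `scheme_tag` set to `"healpix-nside<nside>"`.
#' @export
healpix_directions <- function(nside) {
  if (length(nside) != 1 || is.na(nside) || nside < 1 ||
      nside != as.integer(nside) || bitwAnd(as.integer(nside), as.integer(nside) - 1L) != 0L)
    stop("nside must be a power of 2, got: ", nside, call. = FALSE)
  nside <- as.integer(nside)
  z <- numeric(0); phi <- numeric(0)
  # north polar cap: rings i = 1..nside-1 with 4i pixels
  if (nside > 1L) {
    for (i in seq_len(nside - 1L)) {
      zi <- 1 - i^2 / (3 * nside^2)
      j <- seq_len(4L * i)
      z <- c(z, rep(zi, 4L * i))
      phi <- c(phi, pi / (2 * i) * (j - 0.5))
    }
  }
  # equatorial belt: rings i = nside..3*nside with 4*nside pixels
  for (i in seq(nside, 3L * nside)) {
    zi <- 4 / 3 - 2 * i / (3 * nside)
    s <- (i - nside + 1L) %% 2L
    j <- seq_len(4L * nside)
    z <- c(z, rep(zi, 4L * nside))
    phi <- c(phi, pi / (2 * nside) * (j - s / 2))
  }
  # south polar cap mirrors the north cap
  if (nside > 1L) {
    for (i in rev(seq_len(nside - 1L))) {
      zi <- -(1 - i^2 / (3 * nside^2))
      j <- seq_len(4L * i)
      z <- c(z, rep(zi, 4L * i))
      phi <- c(phi, pi / (2 * i) * (j - 0.5))
    }
  }
  st <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(st * cos(phi), st * sin(phi), z)
  stopifnot(nrow(dirs) == 12L * nside^2)
  attr(dirs, "scheme_tag") <- paste0("healpix-nside", nside)
  dirs
}

# Indices selecting one pixel per antipodal pair of a HEALPix grid. The RING
# tessellation is exactly antipodally symmetric, and every basis function in
# the package is even, so least-squares fits, grid means and spatial losses
# over this half grid equal their full-grid counterparts (duplicate rows in a
# least-squares design act as a uniform weight of two).
healpix_half_indices <- function(dirs) {
  z <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1]) %% (2 * pi)
  keep <- which(z > 1e-12 | (abs(z) <= 1e-12 & phi < pi - 1e-12))
  if (2L * length(keep) != nrow(dirs))
    stop("grid is not antipodally symmetric", call. = FALSE)
  keep
}

#' Equiangular ZYZ Euler-angle grid on SO(3)
#'
#' `k` uniform samples of alpha and gamma on `[0, 2 pi)` and `k` interior
#' samples of beta at \eqn{\pi (2j+1)/(2k)}, giving \eqn{k^3} rotations;
#' k = 9 yields the 729-rotation set used by the rotational-variance
#' benchmark.
#'
#' @param samples_per_angle Integer k >= 1.
#' @return A `k^3` x 3 matrix with columns `alpha`, `beta`, `gamma` (radians).
#' @export
so3_grid <- function(samples_per_angle) {
  k <- samples_per_angle
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k))
    stop("samples_per_angle must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  ab <- 2 * pi * (seq_len(k) - 1L) / k
  be <- pi * (2 * seq_len(k) - 1) / (2 * k)
  g <- expand.grid(gamma = ab, beta = be, alpha = ab)
  out <- cbind(alpha = g$alpha, beta = g$beta, gamma = g$gamma)
  rownames(out) <- NULL
  out
}

# package-level cache for direction sets
.sphmicro_cache <- new.env(parent = emptyenv())

#' Approximately uniform half-sphere direction set by electrostatic repulsion
#'
#' Minimizes the antipodally symmetrized Coulomb energy
#' \eqn{\sum_{i<j} 1/|x_i - x_j| + 1/|x_i + x_j|} over n points, the standard
#' construction for diffusion-encoding direction tables. Deterministic: the
#' optimizer starts from a fixed-seed random configuration and results are
#' cached per n.
#'
#' @param n Number of directions (>= 1).
#' @return n x 3 matrix of unit vectors (one hemisphere representative per
#'   antipodal pair, flipped to z >= 0).
#' @export
repulsion_directions <- function(n) {
  key <- paste0("repdir_", n)
  if (!is.null(.sphmicro_cache[[key]])) return(.sphmicro_cache[[key]])
  if (n == 1) {
    out <- matrix(c(0, 0, 1), 1, 3)
    .sphmicro_cache[[key]] <- out
    return(out)
  }
  ang0 <- withr_seed_angles(n)
  energy <- function(p) {
    th <- p[seq_len(n)]; ph <- p[n + seq_len(n)]
    x <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    G <- x %*% t(x)
    dm <- sqrt(pmax(2 - 2 * G, 0)); dp <- sqrt(pmax(2 + 2 * G, 0))
    iu <- upper.tri(G)
    sum(1 / dm[iu]) + sum(1 / dp[iu])
  }
  grad <- function(p) {
    th <- p[seq_len(n)]; ph <- p[n + seq_len(n)]
    x <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    G <- x %*% t(x)
    dm <- sqrt(pmax(2 - 2 * G, 0)); dp <- sqrt(pmax(2 + 2 * G, 0))
    diag(dm) <- Inf; diag(dp) <- Inf
    # dE/dG_ij for i != j: +1/dm^3 - 1/dp^3 (each unordered pair appears twice)
    W <- 1 / dm^3 - 1 / dp^3
    dEdx <- W %*% x                       # dE/dx_i
    dxdth <- cbind(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
    dxdph <- cbind(-sin(th) * sin(ph), sin(th) * cos(ph), 0)
    c(rowSums(dEdx * dxdth), rowSums(dEdx * dxdph))
  }
  fit <- stats::optim(ang0, energy, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- fit$par[seq_len(n)]; ph <- fit$par[n + seq_len(n)]
  x <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  x <- x / sqrt(rowSums(x^2))
  flip <- x[, 3] < 0
  x[flip, ] <- -x[flip, ]
  attr(x, "scheme_tag") <- paste0("repulsion-", n)
  .sphmicro_cache[[key]] <- x
  x
}

# Fixed-seed starting angles without touching the caller's RNG stream.
withr_seed_angles <- function(n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20240811L + n)
  c(acos(stats::runif(n, -1, 1)), stats::runif(n, 0, 2 * pi))
}
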