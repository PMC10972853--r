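# Cached HEALPix spectral/spatial operators.
#
# Everything the simulator, the networks and the losses need on the nside-16
# grid is precomputed once: basis matrices and least-squares refit operators
# at bandwidths 8 and 16, on the half grid (one pixel per antipodal pair).
# Because the basis is even-degree only, every function handled here is
# antipodally symmetric, so fits, means and mean-squared errors over the half
# grid are mathematically identical to the full 3072-point versions.

healpix_ctx <- function(nside = 16) {
  key <- paste0("ctx_", nside)
  ctx <- .sphmicro_cache[[key]]
  if (!is.null(ctx)) return(ctx)
  dirs <- healpix_directions(nside)
  half <- healpix_half_indices(dirs)
  dh <- dirs[half, , drop = FALSE]
  ctx <- list(nside = nside, npix = nrow(dirs), dirs = dirs, half = half,
              dirs_half = dh, nhalf = nrow(dh))
  if (nrow(dh) >= sh_ncoef(8)) {
    B8 <- build_basis(dh, 8)
    P8 <- solve(crossprod(B8), t(B8))
    ctx$B8 <- B8; ctx$P8 <- P8
    ctx$Z8 <- P8[sh_zonal_rows(8), , drop = FALSE]
  }
  if (nrow(dh) >= sh_ncoef(16)) {
    B16 <- build_basis(dh, 16)
    P16 <- solve(crossprod(B16), t(B16))
    ctx$B16 <- B16; ctx$P16 <- P16
    ctx$P16to8 <- P16[seq_len(sh_ncoef(8)), , drop = FALSE]
  }
  .sphmicro_cache[[key]] <- ctx
  ctx
}

# Per-shell SH basis and least-squares/ridge fit operators for a scheme.
scheme_ctx <- function(scheme, bandwidth = 8, lambda = 0.006) {
  key <- paste0("scheme_", digest_scheme(scheme), "_", bandwidth)
  ctx <- .sphmicro_cache[[key]]
  if (!is.null(ctx)) return(ctx)
  nc <- sh_ncoef(bandwidth)
  idx <- sh_index(bandwidth)
  shells <- lapply(scheme$shells, function(s) {
    B <- build_basis(s$directions, bandwidth)
    G <- crossprod(B)
    if (nrow(B) < nc || rcond(G) < 1e-10)
      diag(G) <- diag(G) + lambda * (idx$l * (idx$l + 1))^2
    list(B = B, P = solve(G, t(B)), b = s$b, shape = s$shape, rows = s$rows)
  })
  ctx <- list(shells = shells, bandwidth = bandwidth)
  .sphmicro_cache[[key]] <- ctx
  ctx
}

# Cheap structural fingerprint of a scheme (also stored in checkpoints).
digest_scheme <- function(scheme) {
  parts <- vapply(scheme$shells, function(s)
    sprintf("%s:%.6f:%d:%.6f", s$shape, s$b, nrow(s$directions),
            sum(s$directions^3)), "")
  paste0("nb0=", scheme$n_b0, ";", paste(parts, collapse = ";"))
}
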