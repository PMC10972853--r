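# Rotation of real even-degree SH coefficients via complex Wigner-D matrices
# with a real<->complex change of basis, built per degree.

# Wigner small-d matrix d^l_{m', m}(beta), rows m' = -l..l, cols m = -l..l.
# Direct factorial sum with beta-independent coefficient tables cached per
# degree; exact (~1e-12) for the degrees used here (<= 16). Only powers of
# cos(beta/2) and sin(beta/2) are computed per call, which also handles the
# beta = 0 / pi poles exactly (x^0 = 1).
wigner_small_d <- function(l, beta) {
  key <- paste0("wigner_tab_", l)
  tab <- .sphmicro_cache[[key]]
  if (is.null(tab)) {
    n <- 2 * l + 1
    mseq <- seq(-l, l)
    MP <- matrix(mseq, n, n)        # m' varies along rows
    M <- matrix(mseq, n, n, byrow = TRUE)
    lf <- lfactorial(0:(2 * l))
    pref <- 0.5 * (lf[l + MP + 1] + lf[l - MP + 1] +
                   lf[l + M + 1] + lf[l - M + 1])
    tab <- list()
    for (s in 0:(2 * l)) {
      valid <- (s >= M - MP) & (s <= l + M) & (s <= l - MP)
      if (!any(valid)) next
      denom <- lf[pmax(l + M - s, 0) + 1] + lf[s + 1] +
               lf[pmax(MP - M + s, 0) + 1] + lf[pmax(l - MP - s, 0) + 1]
      C <- (-1)^((MP - M + s) %% 2) * exp(pref - denom)
      C[!valid] <- 0
      pwc <- 2 * l + M - MP - 2 * s; pwc[!valid] <- 0L
      pws <- MP - M + 2 * s; pws[!valid] <- 0L
      tab[[length(tab) + 1L]] <- list(C = C, pwc = pwc + 1L, pws = pws + 1L)
    }
    .sphmicro_cache[[key]] <- tab
  }
  n <- 2 * l + 1
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  cbp <- cb^(0:(2 * l)); sbp <- sb^(0:(2 * l))
  acc <- matrix(0, n, n)
  for (t in tab)
    acc <- acc + t$C * matrix(cbp[t$pwc] * sbp[t$pws], n, n)
  acc
}

# Real-from-complex change of basis W for degree l: S_m = sum_mu W[m, mu] Y_mu,
# rows/cols ordered m = -l..l. Unitary.
real_complex_change <- function(l) {
  n <- 2 * l + 1
  W <- matrix(0 + 0i, n, n)
  idx <- function(m) m + l + 1
  W[idx(0), idx(0)] <- 1
  if (l > 0) {
    for (m in 1:l) {
      cs <- (-1)^m
      W[idx(m), idx(m)] <- 1 / sqrt(2)
      W[idx(m), idx(-m)] <- cs / sqrt(2)
      W[idx(-m), idx(m)] <- -1i / sqrt(2)
      W[idx(-m), idx(-m)] <- 1i * cs / sqrt(2)
    }
  }
  W
}

# Real Wigner-D block for one degree: coefficients of g = R f (g(x) = f(R^-1 x))
# with R = Rz(alpha) Ry(beta) Rz(gamma), acting on real coefficients m = -l..l.
real_wigner_block <- function(l, alpha, beta, gamma) {
  key <- paste0("wigner_W_", l)
  Wc <- .sphmicro_cache[[key]]
  if (is.null(Wc)) {
    W <- real_complex_change(l)
    Wc <- list(conjW = Conj(W), tW = t(W))
    .sphmicro_cache[[key]] <- Wc
  }
  d <- wigner_small_d(l, beta)
  mseq <- seq(-l, l)
  D <- exp(-1i * mseq * alpha) * d * rep(exp(-1i * mseq * gamma),
                                         each = 2 * l + 1)
  M <- Wc$conjW %*% D %*% Wc$tW
  if (max(abs(Im(M))) > 1e-9)
    stop("real Wigner block has non-negligible imaginary part", call. = FALSE)
  Re(M)
}

#' Rotation matrix acting on real even-degree SH coefficients
#'
#' Block-diagonal orthogonal matrix `R` such that `R %*% coeffs` are the
#' coefficients of the rotated function \eqn{g(x) = f(R^{-1} x)}, where the
#' rotation is `Rz(alpha) Ry(beta) Rz(gamma)` (ZYZ convention, radians).
#'
#' @param bandwidth Even integer bandwidth.
#' @param alpha,beta,gamma Euler angles in radians (ZYZ).
#' @return `sh_ncoef(bandwidth)` square orthogonal matrix.
#' @export
sh_rotation_matrix <- function(bandwidth, alpha, beta, gamma) {
  check_bandwidth(bandwidth)
  n <- sh_ncoef(bandwidth)
  R <- matrix(0, n, n)
  off <- 0L
  for (l in seq(0L, bandwidth, by = 2L)) {
    nl <- 2L * l + 1L
    R[off + seq_len(nl), off + seq_len(nl)] <-
      real_wigner_block(l, alpha, beta, gamma)
    off <- off + nl
  }
  R
}

#' Rotate real even-degree SH coefficients
#'
#' @param coeffs Coefficient vector, or matrix with one coefficient vector
#'   per column.
#' @param bandwidth Even integer bandwidth.
#' @inheritParams sh_rotation_matrix
#' @return Rotated coefficients, same shape as the input.
#' @export
rotate_sh <- function(coeffs, bandwidth, alpha, beta, gamma) {
  R <- sh_rotation_matrix(bandwidth, alpha, beta, gamma)
  out <- R %*% (if (is.matrix(coeffs)) coeffs else matrix(coeffs, ncol = 1))
  if (is.matrix(coeffs)) out else drop(out)
}

# Cartesian ZYZ rotation matrix (active), matching sh_rotation_matrix.
rotation_matrix_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}
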