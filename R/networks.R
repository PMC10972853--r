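#' Spherical CNN and MLP estimators
#'
#' The spherical convolutional network (sCNN) operates on per-shell
#' spherical-harmonic coefficients. Each of its six layers performs a zonal
#' spectral convolution (a learnable per-degree gain per input/output channel
#' pair, no bias), followed by a leaky rectifier applied in the spatial
#' domain on the HEALPix nside-16 grid and a least-squares refit back to
#' coefficients. Spectral pooling truncates bandwidth 16 to 8 after the third
#' layer. The sixth layer's single output channel is the predicted ODF;
#' global mean pooling of the spatial representations after layers 1-3 feeds
#' a small fully connected head that predicts the scalar parameters. Spectral
#' convolutions are exactly SO(3)-equivariant; the grid nonlinearity is
#' equivariant up to grid discretization error, which makes the pooled scalar
#' pathway rotation-invariant to the same accuracy.
#'
#' The MLP baseline maps the normalized diffusion-weighted measurement vector
#' directly to ODF coefficients and scalars and has no rotational structure.
#'
#' Both networks are implemented as plain R forward/backward computations
#' (verified against finite differences) so they train on a single CPU.
#'
#' @name networks
#' @keywords internal
NULL

#' sCNN architecture description
#'
#' The canonical two-compartment configuration (2 input shells, channel
#' widths 32,32,32,32,48, one output channel, conv bandwidths
#' 16,16,16,8,8,8, a 96-256-... head) has 78,258 trainable parameters.
#'
#' @param n_shells Number of input channels (shells).
#' @param n_scalars Number of scalar outputs (2 two-compartment, 4
#'   three-compartment).
#' @param channels Hidden channel widths of conv layers 1-5 (layer 6 has one
#'   output channel).
#' @param conv_bw Even bandwidth of each of the six conv layers.
#' @param fcn_hidden Hidden widths of the fully connected head.
#' @param nside HEALPix resolution of the spatial grid.
#' @param input_bw Bandwidth of the input coefficients (8).
#' @param odf_bw Bandwidth of the predicted ODF (8).
#' @param leaky Negative slope of the conv-layer rectifier.
#' @param pool_layers Conv layers whose post-rectifier spatial means feed the
#'   head.
#' @return A list of class `scnn_config`.
#' @export
scnn_config <- function(n_shells = 2, n_scalars = 2,
                        channels = c(32, 32, 32, 32, 48),
                        conv_bw = c(16, 16, 16, 8, 8, 8),
                        fcn_hidden = c(128, 128, 128),
                        nside = 16, input_bw = 8, odf_bw = 8,
                        leaky = 0.1, pool_layers = seq_len(3)) {
  L <- length(conv_bw)
  stopifnot(length(channels) == L - 1, all(conv_bw %% 2 == 0),
            input_bw <= conv_bw[1], odf_bw <= conv_bw[L])
  chain <- c(n_shells, channels, 1L)
  out_bw <- c(conv_bw[-1], odf_bw)
  structure(list(n_shells = n_shells, n_scalars = n_scalars,
                 chain = chain, conv_bw = conv_bw, out_bw = out_bw,
                 fcn_hidden = fcn_hidden, nside = nside,
                 input_bw = input_bw, odf_bw = odf_bw, leaky = leaky,
                 pool_layers = pool_layers,
                 pool_dim = sum(chain[pool_layers + 1L])),
            class = "scnn_config")
}

#' MLP baseline architecture description
#'
#' The HARDI configuration (120 diffusion-weighted inputs, three hidden
#' layers of 512 with batch-norm + ReLU, 45 + 2 outputs) has 614,447
#' trainable parameters.
#'
#' @param n_input Number of diffusion-weighted measurements.
#' @param hidden Hidden widths.
#' @param n_odf Number of ODF coefficients output (45 at bandwidth 8).
#' @param n_scalars Number of scalar outputs.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(n_input = 120, hidden = c(512, 512, 512),
                       n_odf = sh_ncoef(8), n_scalars = 2) {
  structure(list(n_input = n_input, hidden = hidden, n_odf = n_odf,
                 n_scalars = n_scalars, n_output = n_odf + n_scalars),
            class = "mlp_config")
}

# spatial operators (basis + refit) for each conv layer of an sCNN config
scnn_ops <- function(config) {
  ctx <- healpix_ctx(config$nside)
  bws <- sort(unique(c(config$conv_bw, config$out_bw)))
  Bs <- list(); Ps <- list()
  for (bw in bws) {
    key <- as.character(bw)
    if (config$nside == 16 && bw == 8) { Bs[[key]] <- ctx$B8; Ps[[key]] <- ctx$P8 }
    else if (config$nside == 16 && bw == 16) { Bs[[key]] <- ctx$B16; Ps[[key]] <- ctx$P16 }
    else {
      B <- build_basis(ctx$dirs_half, bw)
      Bs[[key]] <- B
      Ps[[key]] <- solve(crossprod(B), t(B))
    }
  }
  layers <- lapply(seq_along(config$conv_bw), function(i) {
    bw_in <- config$conv_bw[i]; bw_out <- config$out_bw[i]
    list(bw_in = bw_in, bw_out = bw_out,
         B = Bs[[as.character(bw_in)]],
         # refit at bw_in, then spectral truncation to bw_out (verbatim rows)
         P = Ps[[as.character(bw_in)]][seq_len(sh_ncoef(bw_out)), , drop = FALSE])
  })
  list(ctx = ctx, layers = layers, npix_half = ctx$nhalf)
}

#' Initialize an sCNN with random weights
#'
#' @param config An [scnn_config()].
#' @param seed Optional RNG seed for the initialization.
#' @return A model object (list with `config`, `params`, `buffers`, `ops`).
#' @export
scnn_init <- function(config = scnn_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- list()
  for (i in seq_along(config$conv_bw)) {
    lset <- seq(0, config$conv_bw[i], 2)
    ndeg <- length(lset)
    cin <- config$chain[i]; cout <- config$chain[i + 1]
    sd_l <- 1 / (zonal_conv_factor(lset) * sqrt(cin))
    w <- array(stats::rnorm(ndeg * cin * cout), c(ndeg, cin, cout)) * sd_l
    params[[paste0("conv", i)]] <- w
  }
  dims <- c(config$pool_dim, config$fcn_hidden, config$n_scalars)
  nh <- length(config$fcn_hidden)
  for (j in seq_len(nh + 1)) {
    fan_in <- dims[j]
    params[[paste0("fcn_W", j)]] <-
      matrix(stats::rnorm(dims[j] * dims[j + 1], 0, sqrt(2 / fan_in)),
             dims[j], dims[j + 1])
    params[[paste0("fcn_b", j)]] <- numeric(dims[j + 1])
    if (j <= 2) {  # batch-norm after hidden layers 1-2 only
      params[[paste0("fcn_bn", j, "_gamma")]] <- rep(1, dims[j + 1])
      params[[paste0("fcn_bn", j, "_beta")]] <- numeric(dims[j + 1])
    }
  }
  buffers <- list()
  for (j in 1:2) {
    buffers[[paste0("fcn_bn", j, "_mean")]] <- numeric(dims[j + 1])
    buffers[[paste0("fcn_bn", j, "_var")]] <- rep(1, dims[j + 1])
  }
  structure(list(kind = "scnn", config = config, params = params,
                 buffers = buffers, ops = scnn_ops(config)),
            class = "sphmicro_model")
}

#' Initialize an MLP baseline with random weights
#'
#' @param config An [mlp_config()].
#' @param seed Optional RNG seed.
#' @return A model object.
#' @export
mlp_init <- function(config = mlp_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(config$n_input, config$hidden, config$n_output)
  params <- list(); buffers <- list()
  for (j in seq_len(length(dims) - 1)) {
    params[[paste0("W", j)]] <-
      matrix(stats::rnorm(dims[j] * dims[j + 1], 0, sqrt(2 / dims[j])),
             dims[j], dims[j + 1])
    params[[paste0("b", j)]] <- numeric(dims[j + 1])
    if (j <= length(config$hidden)) {
      params[[paste0("bn", j, "_gamma")]] <- rep(1, dims[j + 1])
      params[[paste0("bn", j, "_beta")]] <- numeric(dims[j + 1])
      buffers[[paste0("bn", j, "_mean")]] <- numeric(dims[j + 1])
      buffers[[paste0("bn", j, "_var")]] <- rep(1, dims[j + 1])
    }
  }
  structure(list(kind = "mlp", config = config, params = params,
                 buffers = buffers), class = "sphmicro_model")
}

#' Number of trainable parameters of a model
#'
#' Counts every weight, bias and batch-norm scale/shift (running statistics
#' are buffers, not parameters).
#'
#' @param model A model from [scnn_init()] or [mlp_init()].
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# --- low-level pieces -------------------------------------------------------

# zonal spectral convolution of a coefficient array A (ncoef, n, Cin) with
# weights w (ndeg, Cin, Cout); gains are factor(l) * w per degree.
conv_layer_forward <- function(A, w, bw) {
  idx <- sh_index(bw)
  nc <- dim(A)[1]; n <- dim(A)[2]; cin <- dim(A)[3]; cout <- dim(w)[3]
  stopifnot(nc == sh_ncoef(bw), dim(w)[2] == cin)
  out <- array(0, c(nc, n, cout))
  for (t in seq_len(dim(w)[1])) {
    l <- 2 * (t - 1)
    rows <- which(idx$l == l)
    G <- zonal_conv_factor(l) * matrix(w[t, , ], cin, cout)
    M <- matrix(A[rows, , , drop = FALSE], length(rows) * n, cin)
    out[rows, , ] <- M %*% G
  }
  out
}

conv_layer_backward <- function(A, w, bw, dOut) {
  idx <- sh_index(bw)
  n <- dim(A)[2]; cin <- dim(A)[3]; cout <- dim(w)[3]
  dA <- array(0, dim(A))
  dw <- array(0, dim(w))
  for (t in seq_len(dim(w)[1])) {
    l <- 2 * (t - 1)
    rows <- which(idx$l == l)
    fac <- zonal_conv_factor(l)
    G <- fac * matrix(w[t, , ], cin, cout)
    M <- matrix(A[rows, , , drop = FALSE], length(rows) * n, cin)
    D <- matrix(dOut[rows, , , drop = FALSE], length(rows) * n, cout)
    dA[rows, , ] <- D %*% t(G)
    dw[t, , ] <- fac * crossprod(M, D)
  }
  list(dA = dA, dw = dw)
}

leaky_relu <- function(x, slope) {
  neg <- !(x > 0)
  x - (1 - slope) * (x * neg)
}

# batch-norm forward over rows of H (n x d)
bn_forward <- function(H, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(H)
    v <- colMeans(H^2) - mu^2
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    n <- nrow(H)
    v_unb <- if (n > 1) v * n / (n - 1) else v
    new_var <- (1 - momentum) * run_var + momentum * v_unb
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(H, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd, mu = mu,
       new_mean = new_mean, new_var = new_var, training = training)
}

bn_backward <- function(cache, gamma, dOut) {
  xhat <- cache$xhat; inv_sd <- cache$inv_sd
  n <- nrow(xhat)
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, gamma, "*")
  if (cache$training) {
    dH <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), n, ncol(xhat),
                                byrow = TRUE),
                2, inv_sd, "*")
  } else {
    dH <- sweep(dxhat, 2, inv_sd, "*")
  }
  list(dH = dH, dgamma = dgamma, dbeta = dbeta)
}

# --- sCNN forward / backward ------------------------------------------------

#' sCNN forward pass
#'
#' @param model Model from [scnn_init()].
#' @param X Input coefficients: array (ncoef(input_bw), n, n_shells).
#' @param training Use batch statistics in batch-norm and update running
#'   statistics (returned in `model` element of the result).
#' @param keep_cache Keep intermediate activations for [scnn_backward()].
#' @return List with `odf` (ncoef(odf_bw) x n coefficient matrix), `scalars`
#'   (n x n_scalars), and (if requested) `cache`; `buffers` holds updated
#'   running statistics when training.
#' @export
scnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  if (length(dim(X)) != 3 || dim(X)[1] != sh_ncoef(cfg$input_bw) ||
      dim(X)[3] != cfg$n_shells)
    stop("input must be an array (", sh_ncoef(cfg$input_bw), ", n, ",
         cfg$n_shells, ")", call. = FALSE)
  n <- dim(X)[2]
  npix <- model$ops$npix_half
  # zero-pad input to the first conv bandwidth
  nc1 <- sh_ncoef(cfg$conv_bw[1])
  A <- array(0, c(nc1, n, cfg$n_shells))
  A[seq_len(dim(X)[1]), , ] <- X
  caches <- list(); pooled <- list()
  for (i in seq_along(cfg$conv_bw)) {
    op <- model$ops$layers[[i]]
    w <- model$params[[paste0("conv", i)]]
    Z <- conv_layer_forward(A, w, op$bw_in)
    cout <- dim(Z)[3]
    V <- op$B %*% matrix(Z, dim(Z)[1], n * cout)
    W <- leaky_relu(V, cfg$leaky)
    A2 <- model$ops$layers[[i]]$P %*% W
    if (i %in% cfg$pool_layers)
      pooled[[length(pooled) + 1L]] <- matrix(colMeans(W), n, cout)
    if (keep_cache)
      caches[[i]] <- list(A = A, Z = Z, mask = V > 0, cout = cout)
    A <- array(A2, c(nrow(A2), n, cout))
  }
  odf <- matrix(A, dim(A)[1], n)      # single channel
  Fp <- do.call(cbind, pooled)        # n x pool_dim
  # fully connected head
  fc <- list(); H <- Fp
  nh <- length(cfg$fcn_hidden)
  new_buffers <- model$buffers
  for (j in seq_len(nh + 1)) {
    Wj <- model$params[[paste0("fcn_W", j)]]
    bj <- model$params[[paste0("fcn_b", j)]]
    lin <- sweep(H %*% Wj, 2, bj, "+")
    if (j <= nh) {
      if (j <= 2) {
        bn <- bn_forward(lin, model$params[[paste0("fcn_bn", j, "_gamma")]],
                         model$params[[paste0("fcn_bn", j, "_beta")]],
                         model$buffers[[paste0("fcn_bn", j, "_mean")]],
                         model$buffers[[paste0("fcn_bn", j, "_var")]],
                         training)
        new_buffers[[paste0("fcn_bn", j, "_mean")]] <- bn$new_mean
        new_buffers[[paste0("fcn_bn", j, "_var")]] <- bn$new_var
        act_in <- bn$out
      } else {
        bn <- NULL
        act_in <- lin
      }
      out <- pmax(act_in, 0)          # plain ReLU in the head
      fc[[j]] <- list(H = H, lin = lin, bn = bn, act_in = act_in, out = out)
      H <- out
    } else {
      fc[[j]] <- list(H = H)
      H <- lin                        # linear output
    }
  }
  res <- list(odf = odf, scalars = H, buffers = new_buffers)
  if (keep_cache)
    res$cache <- list(caches = caches, pooled = pooled, Fp = Fp, fc = fc,
                      n = n, npix = npix)
  res
}

#' sCNN backward pass
#'
#' @param model Model object.
#' @param fwd Result of [scnn_forward()] with `keep_cache = TRUE`.
#' @param d_odf Gradient of the loss w.r.t. the ODF coefficients
#'   (ncoef x n).
#' @param d_scalars Gradient w.r.t. the scalars (n x n_scalars).
#' @return Named list of gradients matching `model$params`.
#' @export
scnn_backward <- function(model, fwd, d_odf, d_scalars) {
  cfg <- model$config
  cache <- fwd$cache
  n <- cache$n; npix <- cache$npix
  grads <- list()
  # head backward
  nh <- length(cfg$fcn_hidden)
  dH <- d_scalars
  for (j in rev(seq_len(nh + 1))) {
    Wj <- model$params[[paste0("fcn_W", j)]]
    st <- cache$fc[[j]]
    if (j <= nh) {
      dact <- dH * (st$act_in > 0)
      if (j <= 2) {
        bb <- bn_backward(st$bn, model$params[[paste0("fcn_bn", j, "_gamma")]],
                          dact)
        grads[[paste0("fcn_bn", j, "_gamma")]] <- bb$dgamma
        grads[[paste0("fcn_bn", j, "_beta")]] <- bb$dbeta
        dlin <- bb$dH
      } else dlin <- dact
    } else dlin <- dH
    grads[[paste0("fcn_W", j)]] <- crossprod(st$H, dlin)
    grads[[paste0("fcn_b", j)]] <- colSums(dlin)
    dH <- dlin %*% t(Wj)
  }
  dF <- dH                                 # n x pool_dim
  # split pooled gradient per pooled layer
  pool_grads <- list(); off <- 0L
  for (k in seq_along(cfg$pool_layers)) {
    cout <- cfg$chain[cfg$pool_layers[k] + 1L]
    pool_grads[[k]] <- dF[, off + seq_len(cout), drop = FALSE]
    off <- off + cout
  }
  # conv stack backward
  L <- length(cfg$conv_bw)
  dA_next <- array(d_odf, c(nrow(d_odf), n, 1))
  for (i in rev(seq_along(cfg$conv_bw))) {
    op <- model$ops$layers[[i]]
    st <- cache$caches[[i]]
    cout <- st$cout
    dW_spatial <- crossprod(op$P, matrix(dA_next, dim(dA_next)[1], n * cout))
    if (i %in% cfg$pool_layers) {
      k <- match(i, cfg$pool_layers)
      dpool <- matrix(pool_grads[[k]], n * cout) / npix
      dW_spatial <- dW_spatial + matrix(rep(dpool, each = npix), npix, n * cout)
    }
    dV <- dW_spatial - (1 - cfg$leaky) * (dW_spatial * !st$mask)
    dZ <- crossprod(op$B, dV)
    dZ <- array(dZ, c(nrow(dZ), n, cout))
    bk <- conv_layer_backward(st$A, model$params[[paste0("conv", i)]],
                              op$bw_in, dZ)
    grads[[paste0("conv", i)]] <- bk$dw
    dA_next <- bk$dA
  }
  grads
}

# --- MLP forward / backward -------------------------------------------------

#' MLP forward pass
#'
#' @param model Model from [mlp_init()].
#' @param X Input matrix (n x n_input) of normalized diffusion-weighted
#'   signals.
#' @param training Batch-norm mode, as in [scnn_forward()].
#' @param keep_cache Keep activations for [mlp_backward()].
#' @return List with `odf` (n_odf x n), `scalars` (n x n_scalars), updated
#'   `buffers`, and optionally `cache`.
#' @export
mlp_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  if (!is.matrix(X) || ncol(X) != cfg$n_input)
    stop("input must be a matrix with ", cfg$n_input, " columns", call. = FALSE)
  nh <- length(cfg$hidden)
  H <- X; fc <- list()
  new_buffers <- model$buffers
  for (j in seq_len(nh + 1)) {
    Wj <- model$params[[paste0("W", j)]]
    bj <- model$params[[paste0("b", j)]]
    lin <- sweep(H %*% Wj, 2, bj, "+")
    if (j <= nh) {
      bn <- bn_forward(lin, model$params[[paste0("bn", j, "_gamma")]],
                       model$params[[paste0("bn", j, "_beta")]],
                       model$buffers[[paste0("bn", j, "_mean")]],
                       model$buffers[[paste0("bn", j, "_var")]], training)
      new_buffers[[paste0("bn", j, "_mean")]] <- bn$new_mean
      new_buffers[[paste0("bn", j, "_var")]] <- bn$new_var
      out <- pmax(bn$out, 0)
      fc[[j]] <- list(H = H, bn = bn, act_in = bn$out)
      H <- out
    } else {
      fc[[j]] <- list(H = H)
      H <- lin
    }
  }
  odf <- t(H[, seq_len(cfg$n_odf), drop = FALSE])
  scalars <- H[, cfg$n_odf + seq_len(cfg$n_scalars), drop = FALSE]
  res <- list(odf = odf, scalars = scalars, buffers = new_buffers)
  if (keep_cache) res$cache <- fc
  res
}

#' MLP backward pass
#'
#' @param model Model object.
#' @param fwd Result of [mlp_forward()] with `keep_cache = TRUE`.
#' @param d_odf Gradient w.r.t. the ODF output (n_odf x n).
#' @param d_scalars Gradient w.r.t. the scalars (n x n_scalars).
#' @return Named list of gradients matching `model$params`.
#' @export
mlp_backward <- function(model, fwd, d_odf, d_scalars) {
  cfg <- model$config
  nh <- length(cfg$hidden)
  dH <- cbind(t(d_odf), d_scalars)
  grads <- list()
  for (j in rev(seq_len(nh + 1))) {
    st <- fwd$cache[[j]]
    if (j <= nh) {
      dact <- dH * (st$act_in > 0)
      bb <- bn_backward(st$bn, model$params[[paste0("bn", j, "_gamma")]], dact)
      grads[[paste0("bn", j, "_gamma")]] <- bb$dgamma
      grads[[paste0("bn", j, "_beta")]] <- bb$dbeta
      dlin <- bb$dH
    } else dlin <- dH
    grads[[paste0("W", j)]] <- crossprod(st$H, dlin)
    grads[[paste0("b", j)]] <- colSums(dlin)
    dH <- dlin %*% t(model$params[[paste0("W", j)]])
  }
  grads
}

# --- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes `<path>.rds` (weights and running statistics) and `<path>.json`
#' (self-describing architecture plus the fingerprint of the acquisition
#' scheme the model was trained for).
#'
#' @param model Model object.
#' @param path Path prefix (without extension).
#' @param scheme Optional `acq_scheme` whose fingerprint to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, scheme = NULL) {
  desc <- list(kind = model$kind,
               config = model$config[setdiff(names(model$config), "ops")],
               n_parameters = count_parameters(model),
               scheme_fingerprint = if (is.null(scheme)) NA_character_
                                    else digest_scheme(scheme))
  jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  saveRDS(list(kind = model$kind, config = unclass(model$config),
               params = model$params, buffers = model$buffers,
               scheme_fingerprint = desc$scheme_fingerprint),
          paste0(path, ".rds"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path prefix used in [save_model()].
#' @return A model object.
#' @export
load_model <- function(path) {
  x <- readRDS(paste0(path, ".rds"))
  if (x$kind == "scnn") {
    cfg <- structure(x$config, class = "scnn_config")
    m <- structure(list(kind = "scnn", config = cfg, params = x$params,
                        buffers = x$buffers, ops = scnn_ops(cfg),
                        scheme_fingerprint = x$scheme_fingerprint),
                   class = "sphmicro_model")
  } else {
    cfg <- structure(x$config, class = "mlp_config")
    m <- structure(list(kind = "mlp", config = cfg, params = x$params,
                        buffers = x$buffers,
                        scheme_fingerprint = x$scheme_fingerprint),
                   class = "sphmicro_model")
  }
  m
}
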