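#' Loss, optimizer and the on-the-fly training loop
#'
#' Training minimizes a mean-squared-error loss with two terms: the ODF term
#' is computed in the spatial domain (mean squared difference of ODF values
#' over the HEALPix grid) and the scalar term is the mean squared error of
#' the parameter predictions in physical units. Fresh batches are simulated
#' for every step; Adam with a step-wise learning-rate schedule (x0.1 after
#' 50% and 75% of the batches) does the optimization.
#'
#' @name training
#' @keywords internal
NULL

#' Training configuration
#'
#' @param n_batches Number of training batches (the reference protocol uses
#'   1e5; desk-scale benchmarks use far fewer).
#' @param batch_size Microstructural configurations per batch (reference
#'   500).
#' @param lr Initial Adam learning rate.
#' @param decay_at Fractions of training after which the learning rate is
#'   multiplied by `decay_factor`.
#' @param decay_factor Multiplicative learning-rate drop (0.1 = reduce by
#'   90%).
#' @param rotate Rotate each ODF by a Haar-uniform rotation before
#'   simulation (data augmentation).
#' @param snr Rician noise SNR of the simulated data.
#' @param model_kind `"two"` or `"three"` compartment model.
#' @param loss_weights Length-2 weights `(w_odf, w_scalars)`.
#' @param data_seed,noise_seed Base seeds; batch b uses `data_seed + b` /
#'   `noise_seed + b`, so clean signals are invariant to the noise seed.
#' @param val_size Validation voxels (held-out seed range), evaluated every
#'   `eval_every` batches.
#' @param eval_every Interval (in batches) of validation evaluations; 0
#'   disables them.
#' @param odf_sampler ODF sampler configuration (an [odf_config()]).
#' @param verbose Print progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_batches = 2000, batch_size = 500, lr = 1e-3,
                         decay_at = c(0.5, 0.75), decay_factor = 0.1,
                         rotate = TRUE, snr = 50, model_kind = "two",
                         loss_weights = c(1, 1), data_seed = 1L,
                         noise_seed = 100001L, val_size = 500,
                         eval_every = 0, odf_sampler = odf_config(),
                         verbose = FALSE) {
  stopifnot(n_batches >= 1, lr > 0, batch_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Training loss (spatial-domain ODF MSE + scalar MSE)
#'
#' @param pred_odf Predicted ODF coefficients (ncoef x n).
#' @param pred_scalars Predicted scalars (n x k).
#' @param target_grid Target ODF values on the spatial grid (npix x n).
#' @param target_scalars Target scalars (n x k).
#' @param weights `(w_odf, w_scalars)`.
#' @param B Basis matrix evaluating coefficients on the grid (default: the
#'   bandwidth-8 HEALPix nside-16 operator).
#' @return List with `loss`, `loss_odf`, `loss_scalars`, and gradients
#'   `d_odf`, `d_scalars`.
#' @export
mse_loss <- function(pred_odf, pred_scalars, target_grid, target_scalars,
                     weights = c(1, 1), B = NULL) {
  if (is.null(B)) B <- healpix_ctx(16)$B8
  r_odf <- B %*% pred_odf - target_grid
  r_s <- pred_scalars - target_scalars
  l_odf <- mean(r_odf^2)
  l_s <- mean(r_s^2)
  list(loss = weights[1] * l_odf + weights[2] * l_s,
       loss_odf = l_odf, loss_scalars = l_s,
       d_odf = weights[1] * 2 / length(r_odf) * crossprod(B, r_odf),
       d_scalars = weights[2] * 2 / length(r_s) * r_s)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- feature extraction -----------------------------------------------------

#' Network input features from measured signals
#'
#' For the sCNN: least-squares spherical-harmonic coefficients (bandwidth 8)
#' of each shell's signals, with ridge regularization on shells that have
#' fewer directions than coefficients. For the MLP: the raw normalized
#' diffusion-weighted measurement vector.
#'
#' @param signals Signal matrix (n_meas x n), b0-normalized.
#' @param scheme An `acq_scheme`.
#' @param kind `"scnn"` or `"mlp"`.
#' @return Array (45, n, n_shells) for the sCNN, matrix (n, n_dwi) for the
#'   MLP.
#' @export
signal_features <- function(signals, scheme, kind = c("scnn", "mlp")) {
  kind <- match.arg(kind)
  S <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  if (kind == "mlp") return(t(S[scheme$dwi_rows, , drop = FALSE]))
  sctx <- scheme_ctx(scheme)
  n <- ncol(S)
  X <- array(0, c(sh_ncoef(8), n, length(scheme$shells)))
  for (s in seq_along(scheme$shells))
    X[, , s] <- sctx$shells[[s]]$P %*% S[scheme$shells[[s]]$rows, , drop = FALSE]
  X
}

# --- training loop ----------------------------------------------------------

#' Train a model on simulated data generated on the fly
#'
#' @param model A model from [scnn_init()] or [mlp_init()].
#' @param scheme The `acq_scheme` to simulate.
#' @param config A [train_config()].
#' @return List with the trained `model` and a `history` data.frame (per-batch
#'   training loss and learning rate, plus periodic validation rows when
#'   `eval_every > 0`).
#' @export
train <- function(model, scheme, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  state <- adam_init(model$params)
  nb <- config$n_batches
  hist_loss <- numeric(nb); hist_odf <- numeric(nb); hist_s <- numeric(nb)
  hist_lr <- numeric(nb)
  val_rows <- list()
  ctx <- healpix_ctx(16)
  val <- NULL
  if (config$eval_every > 0) {
    val <- make_batch(config$val_size, scheme, snr = config$snr,
                      rotate = config$rotate, model = config$model_kind,
                      config = config$odf_sampler,
                      seed = config$data_seed + 900000L,
                      noise_seed = config$noise_seed + 900000L)
    val$X <- signal_features(val$noisy, scheme, model$kind)
  }
  for (b in seq_len(nb)) {
    lr <- config$lr *
      config$decay_factor^sum((b - 1) / nb >= config$decay_at)
    batch <- make_batch(config$batch_size, scheme, snr = config$snr,
                        rotate = config$rotate, model = config$model_kind,
                        config = config$odf_sampler,
                        seed = config$data_seed + b,
                        noise_seed = config$noise_seed + b)
    X <- signal_features(batch$noisy, scheme, model$kind)
    fwd <- if (model$kind == "scnn")
      scnn_forward(model, X, training = TRUE, keep_cache = TRUE)
    else mlp_forward(model, X, training = TRUE, keep_cache = TRUE)
    model$buffers <- fwd$buffers
    ls <- mse_loss(fwd$odf, fwd$scalars, batch$targets$odf_grid,
                   batch$targets$scalars, config$loss_weights, B = ctx$B8)
    if (!is.finite(ls$loss))
      stop("training diverged at batch ", b, ": loss = ", ls$loss,
           " (lr = ", lr, ")", call. = FALSE)
    grads <- if (model$kind == "scnn")
      scnn_backward(model, fwd, ls$d_odf, ls$d_scalars)
    else mlp_backward(model, fwd, ls$d_odf, ls$d_scalars)
    upd <- adam_step(model$params, grads, state, lr)
    model$params <- upd$params
    state <- upd$state
    hist_loss[b] <- ls$loss; hist_odf[b] <- ls$loss_odf
    hist_s[b] <- ls$loss_scalars; hist_lr[b] <- lr
    if (config$eval_every > 0 && b %% config$eval_every == 0) {
      vfwd <- if (model$kind == "scnn") scnn_forward(model, val$X)
              else mlp_forward(model, val$X)
      vls <- mse_loss(vfwd$odf, vfwd$scalars, val$targets$odf_grid,
                      val$targets$scalars, config$loss_weights, B = ctx$B8)
      val_rows[[length(val_rows) + 1L]] <-
        data.frame(batch = b, val_loss = vls$loss, val_odf = vls$loss_odf,
                   val_scalars = vls$loss_scalars)
      if (config$verbose)
        message(sprintf("batch %d/%d  train %.5f  val %.5f  lr %.1e",
                        b, nb, ls$loss, vls$loss, lr))
    } else if (config$verbose && b %% 50 == 0) {
      message(sprintf("batch %d/%d  train %.5f  lr %.1e", b, nb, ls$loss, lr))
    }
  }
  history <- data.frame(batch = seq_len(nb), loss = hist_loss,
                        loss_odf = hist_odf, loss_scalars = hist_s,
                        lr = hist_lr)
  list(model = model, history = history,
       validation = if (length(val_rows)) do.call(rbind, val_rows) else NULL)
}
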