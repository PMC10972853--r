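# Network architectures: parameter counts, layer semantics, equivariance,
# and hand-written gradients against finite differences.

tiny_scnn <- function(seed = 2) {
  scnn_init(scnn_config(n_shells = 2, n_scalars = 2, channels = c(3, 3, 3, 3, 4),
                        conv_bw = c(4, 4, 4, 2, 2, 2), fcn_hidden = c(6, 6, 6),
                        nside = 2, input_bw = 2, odf_bw = 2), seed = seed)
}

test_that("parameter counts match the canonical architectures", {
  m <- scnn_init(scnn_config(), seed = 1)
  expect_identical(count_parameters(m), 78258L)
  mm <- mlp_init(mlp_config(), seed = 1)
  expect_identical(count_parameters(mm), 614447L)
  # the fully connected head alone: 96->128->128->128->2, BN after hidden 1-2
  head_n <- sum(vapply(m$params[grep("^fcn_", names(m$params))], length, 1L))
  expect_identical(head_n, 46210L)
})

test_that("spectral convolution layers: identity, zero and equivariance", {
  set.seed(601)
  lset <- seq(0, 8, 2)
  id_filter <- sqrt((2 * lset + 1) / (4 * pi)) / (2 * pi)
  A <- array(random_coeffs(8), c(45, 1, 1))
  w_id <- array(id_filter, c(5, 1, 1))
  out <- sphmicro:::conv_layer_forward(A, w_id, 8)
  expect_equal(out, A, tolerance = 1e-12)
  w0 <- array(0, c(5, 1, 1))
  expect_equal(sphmicro:::conv_layer_forward(A, w0, 8),
               array(0, dim(A)))

  # rotation equivariance with random multi-channel weights
  w <- array(rnorm(5 * 3 * 2, 0, 0.1), c(5, 3, 2))
  X <- array(rnorm(45 * 4 * 3), c(45, 4, 3))
  ang <- c(1.1, 0.6, -2.0)
  R <- sh_rotation_matrix(8, ang[1], ang[2], ang[3])
  rot_arr <- function(A) {
    out <- A
    for (i in seq_len(dim(A)[2])) for (c in seq_len(dim(A)[3]))
      out[, i, c] <- R %*% A[, i, c]
    out
  }
  e1 <- rot_arr(sphmicro:::conv_layer_forward(X, w, 8))
  e2 <- sphmicro:::conv_layer_forward(rot_arr(X), w, 8)
  expect_lt(max(abs(e1 - e2)), 1e-8)
})

test_that("spatial nonlinearity acts as identity / slope on signed inputs", {
  # a positive band-8 function refit at 16 passes through unchanged;
  # its negation is scaled by the leaky slope
  ctx <- sphmicro:::healpix_ctx(16)
  set.seed(602)
  cf <- 0.05 * random_coeffs(8)
  cf[1] <- 2          # large positive mean keeps the function positive
  v <- drop(ctx$B8 %*% cf)
  expect_gt(min(v), 0)
  pad <- c(cf, numeric(sh_ncoef(16) - 45))
  relu_refit <- function(x) drop(ctx$P16 %*% sphmicro:::leaky_relu(ctx$B16 %*% x, 0.1))
  expect_equal(relu_refit(pad), pad, tolerance = 1e-9)
  expect_equal(relu_refit(-pad), -0.1 * pad, tolerance = 1e-9)

  # approximate rotational equivariance of rectify-and-refit
  ang <- c(0.8, 1.0, -0.4)
  R8 <- sh_rotation_matrix(8, ang[1], ang[2], ang[3])
  R16 <- sh_rotation_matrix(16, ang[1], ang[2], ang[3])
  g <- random_coeffs(8)
  gp <- c(g, numeric(sh_ncoef(16) - 45))
  a <- R16 %*% relu_refit(gp)
  b <- relu_refit(c(R8 %*% g, numeric(sh_ncoef(16) - 45)))
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-2)
})

test_that("global mean pooling is rotation invariant on the grid", {
  ctx <- sphmicro:::healpix_ctx(16)
  set.seed(603)
  cf <- random_coeffs(8)
  pool <- function(x) mean(sphmicro:::leaky_relu(ctx$B8 %*% x, 0.1))
  p0 <- pool(cf)
  for (i in 1:5) {
    ang <- c(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
    p1 <- pool(rotate_sh(cf, 8, ang[1], ang[2], ang[3]))
    expect_lt(abs(p1 - p0) / abs(p0), 5e-3)   # grid-quadrature floor
  }
  # pure high-degree harmonics have near-zero linear mean (quadrature floor)
  pure <- numeric(45); pure[10] <- 1
  expect_lt(abs(mean(ctx$B8 %*% pure)), 1e-3)
})

test_that("sCNN forward: determinism, zero input, wrong shapes", {
  m <- tiny_scnn()
  set.seed(604)
  X <- array(rnorm(sh_ncoef(2) * 3 * 2, 0, 0.3), c(sh_ncoef(2), 3, 2))
  f1 <- scnn_forward(m, X)
  f2 <- scnn_forward(m, X)
  expect_identical(f1$odf, f2$odf)
  expect_identical(f1$scalars, f2$scalars)
  # zero input: bias-free convolutions give a zero ODF
  z <- scnn_forward(m, array(0, dim(X)))
  expect_equal(z$odf, matrix(0, sh_ncoef(2), 3), tolerance = 1e-12)
  expect_true(all(is.finite(z$scalars)))
  expect_error(scnn_forward(m, X[, , 1, drop = FALSE]), "array")
})

test_that("hand-written sCNN gradients agree with finite differences", {
  m <- tiny_scnn()
  set.seed(605)
  n <- 4
  X <- array(rnorm(sh_ncoef(2) * n * 2, 0, 0.3), c(sh_ncoef(2), n, 2))
  Co <- matrix(rnorm(sh_ncoef(2) * n), sh_ncoef(2), n)
  Cs <- matrix(rnorm(n * 2), n, 2)
  lossf <- function(mod) {
    fw <- scnn_forward(mod, X, training = TRUE)
    sum(fw$odf * Co) + sum(fw$scalars * Cs)
  }
  fw <- scnn_forward(m, X, training = TRUE, keep_cache = TRUE)
  gr <- scnn_backward(m, fw, Co, Cs)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      fd <- (lossf(m2) - lossf(m3)) / (2 * eps)
      expect_lt(abs(fd - gr[[nm]][i]) / max(1, abs(fd) + abs(gr[[nm]][i])),
                1e-5)
    }
  }
})

test_that("hand-written MLP gradients agree with finite differences", {
  cfg <- mlp_config(n_input = 8, hidden = c(7, 7, 7), n_odf = 6, n_scalars = 2)
  m <- mlp_init(cfg, seed = 4)
  set.seed(606)
  X <- matrix(rnorm(5 * 8), 5, 8)
  Co <- matrix(rnorm(6 * 5), 6, 5); Cs <- matrix(rnorm(5 * 2), 5, 2)
  lossf <- function(mod) {
    fw <- mlp_forward(mod, X, training = TRUE)
    sum(fw$odf * Co) + sum(fw$scalars * Cs)
  }
  fw <- mlp_forward(m, X, training = TRUE, keep_cache = TRUE)
  gr <- mlp_backward(m, fw, Co, Cs)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      fd <- (lossf(m2) - lossf(m3)) / (2 * eps)
      expect_lt(abs(fd - gr[[nm]][i]) / max(1, abs(fd) + abs(gr[[nm]][i])),
                1e-5)
    }
  }
})

test_that("MLP is order sensitive where the sCNN input is structured", {
  m <- mlp_init(mlp_config(), seed = 5)
  set.seed(607)
  x <- matrix(runif(120, 0.2, 1), 1, 120)
  f1 <- mlp_forward(m, x)
  f2 <- mlp_forward(m, x[, sample(120), drop = FALSE])
  expect_gt(max(abs(f1$scalars - f2$scalars)), 1e-6)
  expect_identical(mlp_forward(m, x)$scalars, f1$scalars)
})

test_that("canonical forward pass handles a 500-voxel batch", {
  m <- scnn_init(scnn_config(), seed = 6)
  set.seed(608)
  X <- array(rnorm(45 * 500 * 2, 0, 0.2), c(45, 500, 2))
  fw <- scnn_forward(m, X)
  expect_equal(dim(fw$odf), c(45L, 500L))
  expect_equal(dim(fw$scalars), c(500L, 2L))
  expect_true(all(is.finite(fw$odf)) && all(is.finite(fw$scalars)))
})

test_that("the three-compartment configuration runs on tensor-valued data", {
  sch <- tensor_scheme()
  m <- scnn_init(scnn_config(n_shells = length(sch$shells), n_scalars = 4),
                 seed = 10)
  b <- make_batch(6, sch, snr = 29, model = "three", seed = 609,
                  noise_seed = 610)
  X <- signal_features(b$noisy, sch, "scnn")
  expect_equal(dim(X), c(45L, 6L, 8L))
  fw <- scnn_forward(m, X)
  expect_equal(dim(fw$scalars), c(6L, 4L))
  expect_true(all(is.finite(fw$odf)) && all(is.finite(fw$scalars)))
  # conv trunk size is shared; only conv1 and the head width change
  expect_identical(count_parameters(m),
                   78258L + (8L - 2L) * 32L * 9L + 2L * (128L + 1L))
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- tiny_scnn(seed = 9)
  sch <- hardi_scheme()
  path <- file.path(tempdir(), "ckpt_test")
  save_model(m, path, sch)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$scheme_fingerprint, sphmicro:::digest_scheme(sch))
  desc <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(desc$n_parameters, count_parameters(m))
})
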