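# A compact 1D convolutional network for multi-channel impedance spectra,
# implemented directly on base-R arrays (im2col convolutions, batch
# normalisation, ReLU, max-pooling, two dense layers with dropout, softmax,
# Adam). Architecture: three conv layers of 24/48/48 kernels with receptive
# field (5, 1) and same padding, each followed by batch norm + ReLU, with
# (2, 1) max-pooling of stride 2 after the first two; then a dense layer
# (default 128 units, ReLU, dropout 0.5) and a softmax output sized to the
# number of enrolled subjects. Adam, learning rate 1e-4, mini-batch 128.

conv1d_forward <- function(x, w, b) {
  dims <- dim(x)
  n <- dims[1]; l <- dims[2]; cin <- dims[3]
  xp <- array(0, c(n, l + 4, cin))
  xp[, 3:(l + 2), ] <- x
  m <- matrix(0, n * l, 5 * cin)
  for (k in 1:5) {
    sl <- xp[, k:(k + l - 1), , drop = FALSE]
    dim(sl) <- c(n * l, cin)
    m[, ((k - 1) * cin + 1):(k * cin)] <- sl
  }
  y <- m %*% w + rep(b, each = n * l)
  dim(y) <- c(n, l, ncol(w))
  list(y = y, m = m, dims = dims)
}

conv1d_backward <- function(dy, cache, w) {
  n <- cache$dims[1]; l <- cache$dims[2]; cin <- cache$dims[3]
  dim(dy) <- c(n * l, ncol(w))
  dw <- crossprod(cache$m, dy)
  db <- colSums(dy)
  dm <- tcrossprod(dy, w)
  dxp <- array(0, c(n, l + 4, cin))
  for (k in 1:5) {
    blk <- dm[, ((k - 1) * cin + 1):(k * cin), drop = FALSE]
    dim(blk) <- c(n, l, cin)
    dxp[, k:(k + l - 1), ] <- dxp[, k:(k + l - 1), , drop = FALSE] + blk
  }
  list(dx = dxp[, 3:(l + 2), , drop = FALSE], dw = dw, db = db)
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  dims <- dim(x)
  nl <- dims[1] * dims[2]
  xm <- x
  dim(xm) <- c(nl, dims[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = nl)) * rep(inv_sd, each = nl)
  y <- xhat * rep(gamma, each = nl) + rep(beta, each = nl)
  dim(y) <- dims
  list(y = y, xhat = xhat, inv_sd = inv_sd, dims = dims,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache, gamma) {
  dims <- cache$dims
  nl <- dims[1] * dims[2]
  dim(dy) <- c(nl, dims[3])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dx <- (nl * dy - rep(dbeta, each = nl) -
           cache$xhat * rep(dgamma, each = nl)) *
    rep(gamma * cache$inv_sd, each = nl) / nl
  dim(dx) <- dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool2_forward <- function(x) {
  dims <- dim(x)
  lo <- dims[2] %/% 2
  x1 <- x[, seq(1, 2 * lo, by = 2), , drop = FALSE]
  x2 <- x[, seq(2, 2 * lo, by = 2), , drop = FALSE]
  take1 <- x1 >= x2
  list(y = pmax(x1, x2), take1 = take1, dims = dims)
}

pool2_backward <- function(dy, cache) {
  lo <- dim(dy)[2]
  dx <- array(0, cache$dims)
  dx[, seq(1, 2 * lo, by = 2), ] <- dy * cache$take1
  dx[, seq(2, 2 * lo, by = 2), ] <- dy * !cache$take1
  dx
}

cnn_init_params <- function(l_in, c_in, n_classes, dense_units) {
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  l1 <- l_in %/% 2
  l2 <- l1 %/% 2
  flat <- l2 * 48
  list(
    w1 = he(5 * c_in, 24), b1 = numeric(24),
    g1 = rep(1, 24), be1 = numeric(24),
    w2 = he(5 * 24, 48), b2 = numeric(48),
    g2 = rep(1, 48), be2 = numeric(48),
    w3 = he(5 * 48, 48), b3 = numeric(48),
    g3 = rep(1, 48), be3 = numeric(48),
    wd1 = he(flat, dense_units), bd1 = numeric(dense_units),
    wd2 = he(dense_units, n_classes), bd2 = numeric(n_classes))
}

cnn_forward <- function(params, state, x, training = FALSE,
                        drop_mask = NULL) {
  c1 <- conv1d_forward(x, params$w1, params$b1)
  n1 <- bn_forward(c1$y, params$g1, params$be1, state$m1, state$v1, training)
  r1 <- pmax(n1$y, 0)
  p1 <- pool2_forward(r1)
  c2 <- conv1d_forward(p1$y, params$w2, params$b2)
  n2 <- bn_forward(c2$y, params$g2, params$be2, state$m2, state$v2, training)
  r2 <- pmax(n2$y, 0)
  p2 <- pool2_forward(r2)
  c3 <- conv1d_forward(p2$y, params$w3, params$b3)
  n3 <- bn_forward(c3$y, params$g3, params$be3, state$m3, state$v3, training)
  r3 <- pmax(n3$y, 0)
  n <- dim(r3)[1]
  flat <- r3
  dim(flat) <- c(n, dim(r3)[2] * dim(r3)[3])
  h <- flat %*% params$wd1 + rep(params$bd1, each = n)
  hr <- pmax(h, 0)
  hd <- if (training && !is.null(drop_mask)) hr * drop_mask else hr
  logits <- hd %*% params$wd2 + rep(params$bd2, each = n)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  list(probs = probs, caches = list(c1 = c1, n1 = n1, r1 = r1, p1 = p1,
                                    c2 = c2, n2 = n2, r2 = r2, p2 = p2,
                                    c3 = c3, n3 = n3, r3 = r3, flat = flat,
                                    hr = hr, hd = hd),
       state = list(m1 = n1$run_mean, v1 = n1$run_var,
                    m2 = n2$run_mean, v2 = n2$run_var,
                    m3 = n3$run_mean, v3 = n3$run_var))
}

cnn_backward <- function(params, fw, y_onehot, drop_mask) {
  ca <- fw$caches
  n <- nrow(fw$probs)
  dlogits <- (fw$probs - y_onehot) / n
  g <- list()
  g$wd2 <- crossprod(ca$hd, dlogits)
  g$bd2 <- colSums(dlogits)
  dhd <- tcrossprod(dlogits, params$wd2)
  dhr <- if (is.null(drop_mask)) dhd else dhd * drop_mask
  dh <- dhr * (ca$hr > 0)
  g$wd1 <- crossprod(ca$flat, dh)
  g$bd1 <- colSums(dh)
  dflat <- tcrossprod(dh, params$wd1)
  dr3 <- dflat
  dim(dr3) <- dim(ca$r3)
  dn3 <- dr3 * (ca$r3 > 0)
  b3 <- bn_backward(dn3, ca$n3, params$g3)
  g$g3 <- b3$dgamma; g$be3 <- b3$dbeta
  cb3 <- conv1d_backward(b3$dx, ca$c3, params$w3)
  g$w3 <- cb3$dw; g$b3 <- cb3$db
  dp2 <- pool2_backward(cb3$dx, ca$p2)
  dn2 <- dp2 * (ca$r2 > 0)
  b2 <- bn_backward(dn2, ca$n2, params$g2)
  g$g2 <- b2$dgamma; g$be2 <- b2$dbeta
  cb2 <- conv1d_backward(b2$dx, ca$c2, params$w2)
  g$w2 <- cb2$dw; g$b2 <- cb2$db
  dp1 <- pool2_backward(cb2$dx, ca$p1)
  dn1 <- dp1 * (ca$r1 > 0)
  b1 <- bn_backward(dn1, ca$n1, params$g1)
  g$g1 <- b1$dgamma; g$be1 <- b1$dbeta
  cb1 <- conv1d_backward(b1$dx, ca$c1, params$w1)
  g$w1 <- cb1$dw; g$b1 <- cb1$db
  g
}

#' Train the compact 1D CNN
#'
#' @param x numeric array `n x n_freq x n_channels` of feature spectra
#'   (one input channel per feature combo).
#' @param y factor of class labels.
#' @param spec a [classifier_spec()] of kind `"cnn"`; `epochs`,
#'   `batch_size`, `lr`, `dropout`, `dense_units` and `seed` are honoured.
#' @return a fitted model of class `limbid_cnn` for [cnn_predict()].
#'   Training is fully deterministic given `spec$seed` (weight
#'   initialisation, batch order and dropout masks all come from one
#'   seeded stream). Input channels are z-scored with training-set
#'   statistics before the first convolution.
#' @export
cnn_train <- function(x, y, spec = classifier_spec("cnn")) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == length(y))
  y <- droplevels(as.factor(y))
  n <- dim(x)[1]; l <- dim(x)[2]; cin <- dim(x)[3]
  k <- nlevels(y)
  # per-channel z-scoring from the training set
  mu <- apply(x, 3, mean)
  sdv <- pmax(apply(x, 3, sd), 1e-12)
  for (c in seq_len(cin)) x[, , c] <- (x[, , c] - mu[c]) / sdv[c]
  yi <- as.integer(y)
  onehot_all <- diag(k)[yi, , drop = FALSE]
  with_seed(spec$seed, {
    params <- cnn_init_params(l, cin, k, spec$dense_units)
    state <- list(m1 = numeric(24), v1 = rep(1, 24),
                  m2 = numeric(48), v2 = rep(1, 48),
                  m3 = numeric(48), v3 = rep(1, 48))
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    t <- 0
    b1c <- 0.9; b2c <- 0.999; eps <- 1e-8
    for (epoch in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      for (st in starts) {
        bi <- idx[st:min(st + spec$batch_size - 1, n)]
        xb <- x[bi, , , drop = FALSE]
        mask <- if (spec$dropout > 0) {
          matrix(rbinom(length(bi) * spec$dense_units, 1,
                        1 - spec$dropout) / (1 - spec$dropout),
                 length(bi), spec$dense_units)
        } else NULL
        fw <- cnn_forward(params, state, xb, training = TRUE,
                          drop_mask = mask)
        state <- fw$state
        grads <- cnn_backward(params, fw, onehot_all[bi, , drop = FALSE],
                              mask)
        t <- t + 1
        for (nm in names(params)) {
          adam_m[[nm]] <- b1c * adam_m[[nm]] + (1 - b1c) * grads[[nm]]
          adam_v[[nm]] <- b2c * adam_v[[nm]] + (1 - b2c) * grads[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - b1c^t)
          vhat <- adam_v[[nm]] / (1 - b2c^t)
          params[[nm]] <- params[[nm]] - spec$lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    structure(list(params = params, state = state, classes = levels(y),
                   mu = mu, sd = sdv, spec = spec),
              class = "limbid_cnn")
  })
}

#' Score samples with a fitted 1D CNN
#'
#' @param fit a [cnn_train()] model.
#' @param x array `n x n_freq x n_channels`, same layout as training.
#' @return matrix of softmax posteriors (n x n_classes), columns named by
#'   class. Inference uses the running batch-norm statistics and no
#'   dropout, so it is deterministic.
#' @export
cnn_predict <- function(fit, x) {
  stopifnot(inherits(fit, "limbid_cnn"), length(dim(x)) == 3)
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - fit$mu[c]) / fit$sd[c]
  }
  probs <- cnn_forward(fit$params, fit$state, x, training = FALSE)$probs
  colnames(probs) <- fit$classes
  probs
}
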