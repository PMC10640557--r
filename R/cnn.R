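# A compact 2-D convolutional network for 16 x 16 comodulogram inputs,
# implemented directly on BLAS matrix operations. Architecture:
#   conv(32, 3x3, stride 1, same) -> ReLU -> batch norm
#   conv(64, 3x3)                 -> ReLU -> batch norm -> maxpool 2x2
#   conv(128, 3x3)                -> ReLU -> batch norm -> maxpool 2x2
#   dense(128, ReLU) -> dropout(0.5) -> dense(1, sigmoid)
# He-uniform init in conv/ReLU layers, Adam optimizer, focal or
# class-balanced focal loss, early stopping on validation loss.
#
# Feature maps are stored as (B*P, C) matrices with P = H*W pixels in
# column-major order and rows grouped by sample; 3x3 convolution is nine
# shifted matrix products, which keeps everything vectorized.

# neighbour index of each pixel for offset (dy, dx); NA = zero padding
conv_neighbours <- function(H, W) {
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  lapply(seq_len(nrow(offs)), function(k) {
    rc <- expand.grid(r = seq_len(H), c = seq_len(W))
    r2 <- rc$r + offs$dy[k]
    c2 <- rc$c + offs$dx[k]
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    ifelse(ok, (c2 - 1) * H + r2, NA_integer_)
  })
}

# global row indices into an augmented (B*P + 1)-row matrix whose last row
# is zero (the padding row)
global_idx <- function(nb, B, P) {
  idx <- rep((0:(B - 1)) * P, each = P) + nb
  idx[is.na(idx)] <- B * P + 1      # rep() recycles nb across samples
  idx
}

conv_fwd <- function(Xm, layer, nbs, B, P) {
  Xaug <- rbind(Xm, 0)
  Z <- matrix(rep(layer$b, each = B * P), B * P)
  gidx <- vector("list", 9)
  for (k in 1:9) {
    gidx[[k]] <- global_idx(nbs[[k]], B, P)
    Z <- Z + Xaug[gidx[[k]], , drop = FALSE] %*% layer$W[[k]]
  }
  list(Z = Z, Xaug = Xaug, gidx = gidx)
}

conv_bwd <- function(dZ, cache, layer, B, P) {
  cin <- ncol(cache$Xaug)
  dX <- matrix(0, B * P + 1, cin)
  dW <- vector("list", 9)
  for (k in 1:9) {
    g <- cache$gidx[[k]]
    dW[[k]] <- crossprod(cache$Xaug[g, , drop = FALSE], dZ)
    dX[g, ] <- dX[g, ] + dZ %*% t(layer$W[[k]])
  }
  list(dX = dX[seq_len(B * P), , drop = FALSE], dW = dW, db = colSums(dZ))
}

bn_fwd <- function(Z, layer, stats, training, eps = 1e-3) {
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    stats$mean <- 0.99 * stats$mean + 0.01 * mu
    stats$var <- 0.99 * stats$var + 0.01 * v
  } else {
    mu <- stats$mean
    v <- stats$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Z, 2, mu), 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  list(out = out, xhat = xhat, istd = istd, stats = stats)
}

bn_bwd <- function(dY, cache, layer) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, layer$gamma, `*`)
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / m, `*`)
  dZ <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

pool_sources <- function(H, W) {
  H2 <- H / 2
  rc <- expand.grid(r = seq_len(H2), c = seq_len(W / 2))
  lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(o) {
    (2 * rc$c - 2 + o[2]) * H + (2 * rc$r - 1 + o[1])
  })
}

pool_fwd <- function(Xm, srcs, B, P) {
  P2 <- P / 4
  g <- lapply(srcs, function(s) rep((0:(B - 1)) * P, each = P2) + s)
  Y <- Xm[g[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(Y), ncol(Y))
  for (j in 2:4) {
    Mj <- Xm[g[[j]], , drop = FALSE]
    upd <- Mj > Y
    Y[upd] <- Mj[upd]
    arg[upd] <- j
  }
  list(Y = Y, arg = arg, g = g)
}

pool_bwd <- function(dY, cache, B, P) {
  dX <- matrix(0, B * P, ncol(dY))
  for (j in 1:4) {
    sel <- which(cache$arg == j, arr.ind = TRUE)
    if (nrow(sel)) {
      dX[cbind(cache$g[[j]][sel[, 1]], sel[, 2])] <- dY[sel]
    }
  }
  dX
}

# (B*P, C) grouped by sample -> (B, P*C) and back
flatten_fwd <- function(Xm, B, P) {
  C <- ncol(Xm)
  matrix(aperm(array(Xm, c(P, B, C)), c(2, 1, 3)), B, P * C)
}

flatten_bwd <- function(dF, B, P) {
  C <- length(dF) / (B * P)
  matrix(aperm(array(dF, c(B, P, C)), c(2, 1, 3)), B * P, C)
}

he_uniform <- function(fan_in, n) {
  stats::runif(n, -sqrt(6 / fan_in), sqrt(6 / fan_in))
}

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

init_conv <- function(cin, cout) {
  list(W = lapply(1:9, function(k) {
    matrix(he_uniform(9 * cin, cin * cout), cin, cout)
  }), b = numeric(cout))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

#' Build the 2-D CNN SOZ classifier
#'
#' Constructs (untrained) the two-block convolutional network described in
#' the file-level comment of the engine: 32- and 64-kernel 3 x 3 convolutions
#' with batch normalization and a 2 x 2 max-pool, a 128-kernel convolution
#' block with batch normalization and max-pool, then a 128-unit ReLU dense
#' layer with 0.5 dropout and a sigmoid output unit. Trained with
#' [focal_loss()] or [cb_focal_loss()] via [cnn_fit()].
#'
#' @param loss `"focal"` or `"cb_focal"`.
#' @param alpha,gamma Focal-loss parameters (used when `loss = "focal"`).
#' @param beta Class-balance saturation parameter (when `loss = "cb_focal"`;
#'   `gamma` is shared).
#' @param dense_units Width of the penultimate dense layer (default 128).
#' @param seed Seed for He-uniform weight initialization.
#' @return An object of class `soz_cnn`.
#' @export
build_cnn <- function(loss = c("focal", "cb_focal"), alpha = 0.75, gamma = 2,
                      beta = 0.999, dense_units = 128, seed = 1L) {
  loss <- match.arg(loss)
  set.seed(seed)
  flat <- 4 * 4 * 128
  w <- list(
    conv1 = init_conv(1, 32), bn1 = init_bn(32),
    conv2 = init_conv(32, 64), bn2 = init_bn(64),
    conv3 = init_conv(64, 128), bn3 = init_bn(128),
    fc1 = list(W = matrix(he_uniform(flat, flat * dense_units),
                          flat, dense_units),
               b = numeric(dense_units)),
    fc2 = list(W = matrix(glorot_uniform(dense_units, 1, dense_units),
                          dense_units, 1),
               b = 0)
  )
  stats <- list(bn1 = list(mean = numeric(32), var = rep(1, 32)),
                bn2 = list(mean = numeric(64), var = rep(1, 64)),
                bn3 = list(mean = numeric(128), var = rep(1, 128)))
  structure(list(w = w, stats = stats, loss = loss,
                 params = list(alpha = alpha, gamma = gamma, beta = beta),
                 nbs16 = conv_neighbours(16, 16), nbs8 = conv_neighbours(8, 8),
                 src16 = pool_sources(16, 16), src8 = pool_sources(8, 8),
                 trained = FALSE, seed = seed),
            class = "soz_cnn")
}

# X: matrix (B, 256) of flattened comodulograms
cnn_forward <- function(model, X, training = FALSE, dropout_mask = NULL) {
  B <- nrow(X)
  w <- model$w
  Xm <- matrix(as.vector(t(X)), ncol = 1)
  c1 <- conv_fwd(Xm, w$conv1, model$nbs16, B, 256)
  r1 <- pmax(c1$Z, 0)
  b1 <- bn_fwd(r1, w$bn1, model$stats$bn1, training)
  c2 <- conv_fwd(b1$out, w$conv2, model$nbs16, B, 256)
  r2 <- pmax(c2$Z, 0)
  b2 <- bn_fwd(r2, w$bn2, model$stats$bn2, training)
  p1 <- pool_fwd(b2$out, model$src16, B, 256)
  c3 <- conv_fwd(p1$Y, w$conv3, model$nbs8, B, 64)
  r3 <- pmax(c3$Z, 0)
  b3 <- bn_fwd(r3, w$bn3, model$stats$bn3, training)
  p2 <- pool_fwd(b3$out, model$src8, B, 64)
  f <- flatten_fwd(p2$Y, B, 16)
  h1 <- pmax(sweep(f %*% w$fc1$W, 2, w$fc1$b, `+`), 0)
  if (training) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::rbinom(length(h1), 1, 0.5) * 2,
                             nrow(h1), ncol(h1))
    }
    d1 <- h1 * dropout_mask
  } else {
    d1 <- h1
  }
  z <- as.vector(d1 %*% w$fc2$W) + w$fc2$b
  p <- 1 / (1 + exp(-z))
  list(p = p, cache = list(B = B, Xm = Xm, c1 = c1, r1 = r1, b1 = b1,
                           c2 = c2, r2 = r2, b2 = b2, p1 = p1, c3 = c3,
                           r3 = r3, b3 = b3, p2 = p2, f = f, h1 = h1,
                           mask = if (training) dropout_mask else NULL,
                           d1 = d1, z = z),
       stats = list(bn1 = b1$stats, bn2 = b2$stats, bn3 = b3$stats))
}

# d(loss)/dp for the mean focal / class-balanced focal loss over the batch
loss_grad_p <- function(model, p, y, n_pos, n_neg) {
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, pc, 1 - pc)
  g <- model$params$gamma
  wt <- if (model$loss == "focal") {
    ifelse(y == 1, model$params$alpha, 1 - model$params$alpha)
  } else {
    1 / effective_number(ifelse(y == 1, n_pos, n_neg), model$params$beta)
  }
  mod_term <- if (g == 0) 0 else -g * (1 - pt)^(g - 1) * log(pt)
  dl_dpt <- -wt * (mod_term + (1 - pt)^g / pt)
  s <- ifelse(y == 1, 1, -1)
  dl_dpt * s / length(p)
}

cnn_loss <- function(model, p, y, n_pos, n_neg) {
  if (model$loss == "focal") {
    focal_loss(p, y, model$params$alpha, model$params$gamma)
  } else {
    cb_focal_loss(p, y, ifelse(y == 1, n_pos, n_neg), model$params$beta,
                  model$params$gamma)
  }
}

cnn_backward <- function(model, fwd, y, n_pos, n_neg) {
  cc <- fwd$cache
  B <- cc$B
  w <- model$w
  p <- fwd$p
  dp <- loss_grad_p(model, p, y, n_pos, n_neg)
  dz <- dp * p * (1 - p)
  g <- list()
  g$fc2 <- list(W = crossprod(cc$d1, matrix(dz)), b = sum(dz))
  dd1 <- matrix(dz) %*% t(w$fc2$W)
  dh1 <- if (is.null(cc$mask)) dd1 else dd1 * cc$mask
  dh1 <- dh1 * (cc$h1 > 0)
  g$fc1 <- list(W = crossprod(cc$f, dh1), b = colSums(dh1))
  df <- dh1 %*% t(w$fc1$W)
  dp2 <- flatten_bwd(df, B, 16)
  db3 <- pool_bwd(dp2, cc$p2, B, 64)
  bb3 <- bn_bwd(db3, cc$b3, w$bn3)
  g$bn3 <- list(gamma = bb3$dgamma, beta = bb3$dbeta)
  dr3 <- bb3$dZ * (cc$c3$Z > 0)
  cb3 <- conv_bwd(dr3, cc$c3, w$conv3, B, 64)
  g$conv3 <- list(W = cb3$dW, b = cb3$db)
  dp1 <- pool_bwd(cb3$dX, cc$p1, B, 256)
  bb2 <- bn_bwd(dp1, cc$b2, w$bn2)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  dr2 <- bb2$dZ * (cc$c2$Z > 0)
  cb2 <- conv_bwd(dr2, cc$c2, w$conv2, B, 256)
  g$conv2 <- list(W = cb2$dW, b = cb2$db)
  bb1 <- bn_bwd(cb2$dX, cc$b1, w$bn1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  dr1 <- bb1$dZ * (cc$c1$Z > 0)
  cb1 <- conv_bwd(dr1, cc$c1, w$conv1, B, 256)
  g$conv1 <- list(W = cb1$dW, b = cb1$db)
  g
}

# Adam over the nested weight list; m/v mirror the structure of w
adam_step <- function(w, g, state, t, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-7) {
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      for (nm in names(w)) {
        res <- walk(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        w[[nm]] <- res$w; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      list(w = w, m = m, v = v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  walk(w, g, state$m, state$v)
}

zeros_like <- function(w) {
  if (is.list(w)) lapply(w, zeros_like) else w * 0
}

#' Train the 2-D CNN
#'
#' Mini-batch Adam training with the model's configured loss, optional
#' validation-based early stopping (the best-validation weights are
#' restored), and per-epoch shuffling. Defaults follow the published
#' training recipe: 100 epochs, batch size 128, early-stopping patience 10.
#'
#' @param model A [build_cnn()] object.
#' @param X Matrix (samples x 256) of flattened comodulograms, or an array
#'   (samples x 16 x 16).
#' @param y Labels in `{0, 1}` (1 = SOZ).
#' @param epochs,batch_size,patience Training-loop controls.
#' @param validation Optional `list(X = , y = )` monitored for early
#'   stopping; without it all epochs run.
#' @param lr Adam learning rate.
#' @param verbose Print per-epoch losses.
#' @return The trained `soz_cnn`.
#' @export
cnn_fit <- function(model, X, y, epochs = 100, batch_size = 128,
                    patience = 10, validation = NULL, lr = 1e-3,
                    verbose = FALSE) {
  X <- cnn_input(X)
  y <- as.numeric(y)
  n <- nrow(X)
  n_pos <- max(sum(y == 1), 1)
  n_neg <- max(sum(y == 0), 1)
  state <- list(m = zeros_like(model$w), v = zeros_like(model$w))
  set.seed(model$seed)
  best <- list(loss = Inf, w = model$w, stats = model$stats)
  wait <- 0
  t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      fwd <- cnn_forward(model, X[idx, , drop = FALSE], training = TRUE)
      model$stats <- fwd$stats
      grads <- cnn_backward(model, fwd, y[idx], n_pos, n_neg)
      t <- t + 1
      res <- adam_step(model$w, grads, state, t, lr)
      model$w <- res$w
      state$m <- res$m
      state$v <- res$v
    }
    if (!is.null(validation)) {
      vp <- cnn_forward(model, cnn_input(validation$X))$p
      vl <- cnn_loss(model, vp, as.numeric(validation$y), n_pos, n_neg)
      if (verbose) message("epoch ", ep, " val loss ", signif(vl, 4))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, w = model$w, stats = model$stats)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  }
  if (!is.null(validation) && is.finite(best$loss)) {
    model$w <- best$w
    model$stats <- best$stats
  }
  model$trained <- TRUE
  model
}

cnn_input <- function(X) {
  if (is.matrix(X) && ncol(X) == 256) return(X)
  if (length(dim(X)) == 3 && all(dim(X)[2:3] == 16)) {
    return(t(apply(X, 1, as.vector)))
  }
  stop("CNN input must be (samples x 256) or (samples x 16 x 16)",
       call. = FALSE)
}

#' Predict SOZ probabilities from a trained or untrained CNN
#'
#' @param object A `soz_cnn`.
#' @param newdata Matrix (samples x 256) or array (samples x 16 x 16).
#' @param ... Unused.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
predict.soz_cnn <- function(object, newdata, ...) {
  cnn_forward(object, cnn_input(newdata))$p
}

#' @export
print.soz_cnn <- function(x, ...) {
  cat("<soz_cnn> 2-D CNN (32-64 | pool | 128 | pool | dense ",
      ncol(x$w$fc1$W), " | sigmoid), loss = ", x$loss,
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}
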