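# Minimal dense-network machinery for the per-run learned validation stage:
# plain matrix forward/backward passes, inverted dropout, Adam updates.
# Deliberately small: the two models trained per run (retention-time
# regressor, PSM discriminant) have a few tens of thousands of parameters
# and train in seconds on a single core. All randomness (init, shuffling,
# dropout) flows from the R RNG, so training is reproducible given a seed.

nn_dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

# forward through a stack of dense layers; ReLU (+ dropout while training)
# on every layer except, optionally, the last
nn_seq_forward <- function(layers, X, final_linear = TRUE, dropout = 0,
                           train = FALSE) {
  caches <- vector("list", length(layers))
  A <- X
  for (l in seq_along(layers)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    last <- l == length(layers)
    if (last && final_linear) {
      caches[[l]] <- list(X = A, Z = Z, mask = NULL, relu = FALSE)
      A <- Z
    } else {
      out <- Z * (Z > 0)
      mask <- NULL
      if (train && dropout > 0) {
        mask <- matrix(stats::runif(length(out)) >= dropout, nrow(out), ncol(out))
        out <- out * mask / (1 - dropout)
      }
      caches[[l]] <- list(X = A, Z = Z, mask = mask, relu = TRUE)
      A <- out
    }
  }
  list(out = A, caches = caches)
}

# backward pass; returns per-layer gradients and the input gradient
nn_seq_backward <- function(layers, caches, dOut, dropout = 0) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    dZ <- if (cc$relu) {
      d <- dA
      if (!is.null(cc$mask)) d <- d * cc$mask / (1 - dropout)
      d * (cc$Z > 0)
    } else {
      dA
    }
    grads[[l]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

nn_adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

nn_adam_step <- function(layers, grads, state, t, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]; s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW <- s$mW / (1 - beta1^t); vW <- s$vW / (1 - beta2^t)
    mb <- s$mb / (1 - beta1^t); vb <- s$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mW / (sqrt(vW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mb / (sqrt(vb) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# ---- four-branch regression network -----------------------------------
# Parallel stacks of 1, 2 and 3 ReLU dense layers (64 units each) plus a
# linear shortcut, concatenated and reduced 256 -> 64 -> 1.

nn_branched_init <- function(n_in, width = 64L) {
  list(
    branches = list(
      list(layers = list(nn_dense_init(n_in, width)), relu = TRUE),
      list(layers = list(nn_dense_init(n_in, width),
                         nn_dense_init(width, width)), relu = TRUE),
      list(layers = list(nn_dense_init(n_in, width),
                         nn_dense_init(width, width),
                         nn_dense_init(width, width)), relu = TRUE),
      list(layers = list(nn_dense_init(n_in, width)), relu = FALSE)
    ),
    head = list(nn_dense_init(4L * width, width), nn_dense_init(width, 1L)),
    width = width
  )
}

nn_branched_forward <- function(net, X, dropout = 0, train = FALSE) {
  bf <- lapply(net$branches, function(br) {
    nn_seq_forward(br$layers, X, final_linear = !br$relu,
                   dropout = if (br$relu) dropout else 0, train = train)
  })
  H <- do.call(cbind, lapply(bf, `[[`, "out"))
  hf <- nn_seq_forward(net$head, H, final_linear = TRUE,
                       dropout = dropout, train = train)
  list(out = hf$out, bf = bf, hf = hf, H = H)
}

nn_branched_backward_step <- function(net, fw, dOut, dropout, state, t, lr) {
  hb <- nn_seq_backward(net$head, fw$hf$caches, dOut, dropout)
  upd <- nn_adam_step(net$head, hb$grads, state$head, t, lr)
  net$head <- upd$layers; state$head <- upd$state
  w <- net$width
  for (i in seq_along(net$branches)) {
    dH <- hb$dX[, ((i - 1L) * w + 1L):(i * w), drop = FALSE]
    bb <- nn_seq_backward(net$branches[[i]]$layers, fw$bf[[i]]$caches, dH,
                          dropout)
    upd <- nn_adam_step(net$branches[[i]]$layers, bb$grads,
                        state$branches[[i]], t, lr)
    net$branches[[i]]$layers <- upd$layers
    state$branches[[i]] <- upd$state
  }
  list(net = net, state = state)
}

# train the branched regressor with Adam + minibatches + early stopping on
# a validation split; X/y already normalized by the caller
nn_branched_train <- function(X, y, val_idx, epochs = 150L, batch = 64L,
                              lr = 1e-3, dropout = 0.2, patience = 25L) {
  net <- nn_branched_init(ncol(X))
  state <- list(head = nn_adam_init(net$head),
                branches = lapply(net$branches,
                                  function(b) nn_adam_init(b$layers)))
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
  best <- list(net = net, val = Inf, epoch = 0L)
  t <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, length(ord), by = batch)) {
      idx <- ord[s:min(s + batch - 1L, length(ord))]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      fw <- nn_branched_forward(net, Xb, dropout, train = TRUE)
      err <- drop(fw$out) - yb
      ep_loss <- ep_loss + sum(err^2)
      nb <- nb + length(idx)
      dOut <- matrix(2 * err / length(err), ncol = 1L)
      t <- t + 1L
      upd <- nn_branched_backward_step(net, fw, dOut, dropout, state, t, lr)
      net <- upd$net; state <- upd$state
    }
    val <- if (length(val_idx)) {
      mean((drop(nn_branched_forward(net, Xv)$out) - yv)^2)
    } else ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val))
    if (val < best$val) best <- list(net = net, val = val, epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  list(net = best$net, history = hist, best_epoch = best$epoch)
}

# ---- sequential binary classifier -------------------------------------

nn_mlp_train <- function(X, y, weights, sizes = c(32L, 16L), epochs = 200L,
                         batch = 64L, lr = 1e-3, dropout = 0.2,
                         patience = 25L, val_frac = 0.1) {
  dims <- c(ncol(X), sizes, 1L)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    nn_dense_init(dims[i], dims[i + 1L])
  })
  state <- nn_adam_init(layers)
  n <- nrow(X)
  val_idx <- sample(n, max(1L, round(val_frac * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  wloss <- function(z, yy, ww) {
    p <- 1 / (1 + exp(-z))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(ww * -(yy * log(p) + (1 - yy) * log(1 - p))) / sum(ww)
  }
  best <- list(layers = layers, val = Inf, epoch = 0L)
  t <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; wsum <- 0
    for (s in seq(1L, length(ord), by = batch)) {
      idx <- ord[s:min(s + batch - 1L, length(ord))]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]; wb <- weights[idx]
      fw <- nn_seq_forward(layers, Xb, final_linear = TRUE,
                           dropout = dropout, train = TRUE)
      z <- drop(fw$out)
      p <- 1 / (1 + exp(-z))
      ep_loss <- ep_loss + wloss(z, yb, wb) * sum(wb)
      wsum <- wsum + sum(wb)
      dOut <- matrix(wb * (p - yb) / sum(wb), ncol = 1L)
      t <- t + 1L
      upd <- nn_adam_step(layers, nn_seq_backward(layers, fw$caches, dOut,
                                                  dropout)$grads,
                          state, t, lr)
      layers <- upd$layers; state <- upd$state
    }
    zv <- drop(nn_seq_forward(layers, X[val_idx, , drop = FALSE])$out)
    val <- wloss(zv, y[val_idx], weights[val_idx])
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / wsum,
                                   val_loss = val))
    if (val < best$val) best <- list(layers = layers, val = val, epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  list(layers = best$layers, history = hist, best_epoch = best$epoch)
}

nn_mlp_predict <- function(layers, X) {
  drop(nn_seq_forward(layers, X, final_linear = TRUE)$out)
}
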