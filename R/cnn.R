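# Self-contained 1-D convolutional network engine for snippet
# classification. One "branch" is conv(n_filters x filter_len) -> ReLU ->
# dropout -> max-pool -> flatten; branch feature vectors are concatenated
# and classified by a single sigmoid dense unit. Convolution is computed
# as an im2col matrix product so the heavy lifting stays in BLAS; training
# is plain minibatch Adam on the (optionally class-weighted) binary
# cross-entropy. Everything is deterministic given the model seed.

branch_init <- function(c_in, filter_len, n_filters) {
  fan_in <- c_in * filter_len
  list(
    c_in = c_in,
    Wc = matrix(stats::rnorm(fan_in * n_filters, sd = sqrt(2 / fan_in)),
                fan_in, n_filters),
    bc = numeric(n_filters))
}

# X: (B, c_in, L) slab -> im2col matrix (B*P, c_in*filter_len), rows
# ordered batch-fastest, columns (tap within filter) fastest per channel.
# Column j of a channel block is the (B x P) slab of samples the j-th
# filter tap sees, written in one contiguous assignment per tap.
im2col <- function(X, filter_len) {
  B <- dim(X)[1]; c_in <- dim(X)[2]; L <- dim(X)[3]
  P <- L - filter_len + 1L
  A <- matrix(0, B * P, filter_len * c_in)
  for (c in seq_len(c_in)) {
    S <- X[, c, , drop = FALSE]
    dim(S) <- c(B, L)
    for (j in seq_len(filter_len)) {
      A[, (c - 1L) * filter_len + j] <- S[, j:(j + P - 1L)]
    }
  }
  A
}

branch_forward <- function(br, slab, hyper, training = FALSE) {
  B <- dim(slab)[1]
  fl <- hyper$filter_len; nf <- hyper$n_filters; pool <- hyper$pool_size
  P <- dim(slab)[3] - fl + 1L
  A <- im2col(slab[, br$channels, , drop = FALSE], fl)
  Z <- A %*% br$Wc
  Z <- Z + rep(br$bc, each = nrow(Z))
  relu_mask <- Z > 0
  Z[!relu_mask] <- 0
  drop_mask <- NULL
  if (training && hyper$dropout > 0) {
    drop_mask <- (stats::runif(length(Z)) >= hyper$dropout) / (1 - hyper$dropout)
    Z <- Z * drop_mask
  }
  nP <- P %/% pool
  Zt <- Z
  dim(Zt) <- c(B, P, nf)
  Zt <- Zt[, seq_len(nP * pool), , drop = FALSE]
  dim(Zt) <- c(B, pool, nP, nf)
  pooled <- Zt[, 1L, , , drop = FALSE]
  dim(pooled) <- c(B, nP, nf)
  argmax <- array(1L, c(B, nP, nf))
  if (pool > 1L) {
    for (w in 2:pool) {
      sl <- Zt[, w, , , drop = FALSE]
      dim(sl) <- c(B, nP, nf)
      upd <- sl > pooled
      pooled[upd] <- sl[upd]
      argmax[upd] <- w
    }
  }
  H <- pooled
  dim(H) <- c(B, nP * nf)
  list(H = H, cache = list(A = A, relu_mask = relu_mask,
                           drop_mask = drop_mask, argmax = argmax,
                           B = B, P = P, nP = nP, nf = nf, pool = pool))
}

branch_backward <- function(br, cache, dH) {
  B <- cache$B; P <- cache$P; nP <- cache$nP
  nf <- cache$nf; pool <- cache$pool
  dpooled <- dH
  dim(dpooled) <- c(B, nP, nf)
  iB <- rep_len(seq_len(B), B * nP * nf)
  iG <- rep(rep(seq_len(nP), each = B), times = nf)
  iF <- rep(seq_len(nf), each = B * nP)
  lin <- iB + (as.vector(cache$argmax) - 1L) * B +
    (iG - 1L) * B * pool + (iF - 1L) * B * pool * nP
  dZt <- numeric(B * pool * nP * nf)
  dZt[lin] <- as.vector(dpooled)
  dim(dZt) <- c(B, pool * nP, nf)
  dZ <- array(0, c(B, P, nf))
  dZ[, seq_len(pool * nP), ] <- dZt
  dim(dZ) <- c(B * P, nf)
  if (!is.null(cache$drop_mask)) dZ <- dZ * cache$drop_mask
  dZ[!cache$relu_mask] <- 0
  list(dWc = crossprod(cache$A, dZ), dbc = colSums(dZ))
}

model_forward <- function(model, X, training = FALSE) {
  outs <- lapply(model$branches, branch_forward, slab = X,
                 hyper = model$hyper, training = training)
  H <- do.call(cbind, lapply(outs, `[[`, "H"))
  z <- drop(H %*% model$dense$w) + model$dense$b
  list(scores = stats::plogis(z), H = H,
       caches = lapply(outs, `[[`, "cache"))
}

adam_new <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(state, grads, params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(grads)) {
    g <- grads[[k]]
    if (is.null(state$m[[k]])) {
      state$m[[k]] <- g * 0
      state$v[[k]] <- g * 0
    }
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# flatten model parameters into the named list adam_step expects
model_params <- function(model) {
  p <- list()
  for (i in seq_along(model$branches)) {
    p[[paste0("Wc", i)]] <- model$branches[[i]]$Wc
    p[[paste0("bc", i)]] <- model$branches[[i]]$bc
  }
  p$wd <- model$dense$w
  p$bd <- model$dense$b
  p
}

model_set_params <- function(model, p) {
  for (i in seq_along(model$branches)) {
    model$branches[[i]]$Wc <- p[[paste0("Wc", i)]]
    model$branches[[i]]$bc <- p[[paste0("bc", i)]]
  }
  model$dense$w <- p$wd
  model$dense$b <- p$bd
  model
}

# one minibatch: forward, weighted-BCE loss, full gradient
model_loss_grads <- function(model, X, y, w) {
  fw <- model_forward(model, X, training = TRUE)
  s <- fw$scores
  B <- length(y)
  se <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  loss <- -sum(w * (y * log(se) + (1 - y) * log(1 - se))) / B
  dz <- w * (s - y) / B
  grads <- list()
  grads$wd <- drop(crossprod(fw$H, dz))
  grads$bd <- sum(dz)
  dHall <- outer(dz, model$dense$w)
  off <- 0L
  for (i in seq_along(model$branches)) {
    Fb <- model$feat_per_branch
    g <- branch_backward(model$branches[[i]], fw$caches[[i]],
                         dHall[, (off + 1L):(off + Fb), drop = FALSE])
    grads[[paste0("Wc", i)]] <- g$dWc
    grads[[paste0("bc", i)]] <- g$dbc
    off <- off + Fb
  }
  list(loss = loss, grads = grads)
}
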