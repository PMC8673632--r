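# Two-hidden-layer feed-forward network trained with Adam, implemented with
# plain matrix algebra.  Sizes here are small (tens of features, up to a few
# tens of thousands of samples), so vectorised R is fast enough and keeps
# the package free of heavyweight dependencies.

LEAKY_SLOPE <- 0.01
ADAM_LR <- 1e-3
MLP_MAX_EPOCHS <- 100L
MLP_PATIENCE <- 5L

leaky_relu <- function(x) ifelse(x > 0, x, LEAKY_SLOPE * x)
leaky_grad <- function(x) ifelse(x > 0, 1, LEAKY_SLOPE)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(W, X, drop_masks = NULL) {
  a1p <- sweep(X %*% W$W1, 2, W$b1, "+")
  a1 <- leaky_relu(a1p)
  if (!is.null(drop_masks)) a1 <- a1 * drop_masks$m1
  a2p <- sweep(a1 %*% W$W2, 2, W$b2, "+")
  a2 <- leaky_relu(a2p)
  if (!is.null(drop_masks)) a2 <- a2 * drop_masks$m2
  z <- sweep(a2 %*% W$W3, 2, W$b3, "+")
  list(a1p = a1p, a1 = a1, a2p = a2p, a2 = a2, prob = softmax_rows(z))
}

mlp_loss <- function(W, X, y1) {       # y1: 1-based class index
  p <- mlp_forward(W, X)$prob
  -mean(log(pmax(p[cbind(seq_along(y1), y1)], 1e-12)))
}

# One Adam step over the list of parameter gradients.
adam_step <- function(W, G, state, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(G)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * G[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * G[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    W[[nm]] <- W[[nm]] - ADAM_LR * mhat / (sqrt(vhat) + eps)
  }
  list(W = W, state = state)
}

# Fit the network.  A stratified 20% holdout of the training rows drives
# early stopping (validation cross-entropy, patience MLP_PATIENCE, best
# weights restored).  Expects the caller to have seeded the RNG.
mlp_fit <- function(X, y, n_classes, spec) {
  n <- nrow(X); p <- ncol(X)
  y1 <- y + 1L
  # stratified holdout: every class contributes ~20%, at least 1 if it can
  val_idx <- unlist(lapply(split(seq_len(n), y1), function(ix) {
    if (length(ix) < 2L) return(integer(0))
    sample(ix, max(1L, floor(0.2 * length(ix))))
  }), use.names = FALSE)
  if (length(val_idx) == 0L || length(val_idx) == n) {
    tr_idx <- seq_len(n); val_idx <- seq_len(n)
  } else tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y1[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y1[val_idx]

  sizes <- list(W1 = c(p, spec$layer1), b1 = c(1, spec$layer1),
                W2 = c(spec$layer1, spec$layer2), b2 = c(1, spec$layer2),
                W3 = c(spec$layer2, n_classes), b3 = c(1, n_classes))
  W <- lapply(names(sizes), function(nm) {
    d <- sizes[[nm]]
    if (startsWith(nm, "b")) matrix(0, d[1], d[2])
    else matrix(stats::rnorm(prod(d), 0, spec$init_stddev), d[1], d[2])
  })
  names(W) <- names(sizes)
  W$b1 <- as.vector(W$b1); W$b2 <- as.vector(W$b2); W$b3 <- as.vector(W$b3)
  state <- list(m = lapply(W, function(w) w * 0),
                v = lapply(W, function(w) w * 0))

  ntr <- nrow(Xtr)
  best <- list(W = W, loss = Inf, epoch = 0L)
  val_history <- numeric(0)
  step <- 0L
  keep <- 1 - spec$dropout
  for (epoch in seq_len(MLP_MAX_EPOCHS)) {
    perm <- sample(ntr)
    for (start in seq(1L, ntr, by = spec$minibatch)) {
      ix <- perm[start:min(start + spec$minibatch - 1L, ntr)]
      Xb <- Xtr[ix, , drop = FALSE]
      yb <- ytr[ix]
      nb <- length(ix)
      masks <- if (spec$dropout > 0) {
        list(m1 = matrix(stats::rbinom(nb * spec$layer1, 1, keep),
                         nb) / keep,
             m2 = matrix(stats::rbinom(nb * spec$layer2, 1, keep),
                         nb) / keep)
      } else NULL
      f <- mlp_forward(W, Xb, masks)
      dz <- f$prob
      dz[cbind(seq_len(nb), yb)] <- dz[cbind(seq_len(nb), yb)] - 1
      dz <- dz / nb
      G <- list()
      G$W3 <- crossprod(f$a2, dz); G$b3 <- colSums(dz)
      da2 <- dz %*% t(W$W3)
      if (!is.null(masks)) da2 <- da2 * masks$m2
      da2 <- da2 * leaky_grad(f$a2p)
      G$W2 <- crossprod(f$a1, da2); G$b2 <- colSums(da2)
      da1 <- da2 %*% t(W$W2)
      if (!is.null(masks)) da1 <- da1 * masks$m1
      da1 <- da1 * leaky_grad(f$a1p)
      G$W1 <- crossprod(Xb, da1); G$b1 <- colSums(da1)
      step <- step + 1L
      upd <- adam_step(W, G, state, step)
      W <- upd$W; state <- upd$state
    }
    vloss <- mlp_loss(W, Xval, yval)
    val_history <- c(val_history, vloss)
    if (vloss < best$loss) best <- list(W = W, loss = vloss, epoch = epoch)
    if (epoch - best$epoch >= MLP_PATIENCE) break
  }
  list(W = best$W, n_classes = n_classes,
       val_history = val_history, best_epoch = best$epoch,
       best_val_loss = best$loss, final_val_loss = val_history[length(val_history)])
}

mlp_proba <- function(fit, X) {
  mlp_forward(fit$W, X)$prob
}
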