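# Compact convolutional decoder for single-trial EEG, following the
# EEGNet-v4 topology: temporal convolution (F1 filters, kernel ~ half the
# sampling rate), depthwise spatial convolution over all channels (depth D),
# batch normalization + ELU + average pooling + dropout, separable temporal
# convolution (F2 filters), a second pool/dropout stage, and a linear
# classification head with max-norm constraints on the depthwise and dense
# weights. Implemented natively on BLAS matrix products (temporal
# convolutions as banded Toeplitz multiplications), trained with Adam on
# binary cross-entropy. Gradients are hand-derived and verified against
# finite differences in the test suite.

# ---- small building blocks -------------------------------------------------

# Index map for a same-padded 1-D convolution of length `T_len` with kernel
# length `kl`: for each kernel tap, the linear indices of the Toeplitz
# matrix cells holding that tap.
conv_index_map <- function(T_len, kl) {
  pad <- floor((kl - 1) / 2)
  lapply(seq_len(kl), function(k) {
    off <- k - 1L - pad                      # input index i = j + off
    j <- seq(max(1L, 1L - off), min(T_len, T_len - off))
    i <- j + off
    i + T_len * (j - 1L)                     # linear index into [T_len, T_len]
  })
}

conv_toeplitz <- function(w, T_len, idx_map) {
  M <- matrix(0, T_len, T_len)
  for (k in seq_along(w)) M[idx_map[[k]]] <- w[k]
  M
}

conv_weight_grad <- function(G, idx_map) {
  vapply(idx_map, function(ix) sum(G[ix]), 1.0)
}

pool_matrix <- function(T_in, p) {
  T_out <- T_in %/% p
  P <- matrix(0, T_in, T_out)
  for (j in seq_len(T_out)) P[(j - 1L) * p + seq_len(p), j] <- 1 / p
  P
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x, fx) ifelse(x > 0, 1, fx + 1)

bn_forward <- function(x, gamma, beta, training, run_mean, run_var,
                       momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- mean(x)
    va <- mean((x - mu)^2)
  } else {
    mu <- run_mean
    va <- run_var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- (x - mu) * ivar
  list(y = gamma * xhat + beta, xhat = xhat, ivar = ivar,
       run_mean = if (training) (1 - momentum) * run_mean + momentum * mu else run_mean,
       run_var = if (training) (1 - momentum) * run_var + momentum * va else run_var)
}

bn_backward <- function(dy, cache, gamma) {
  n <- length(dy)
  s1 <- sum(dy)
  s2 <- sum(dy * cache$xhat)
  dx <- gamma * cache$ivar / n * (n * dy - s1 - cache$xhat * s2)
  list(dx = dx, dgamma = s2, dbeta = s1)
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# ---- model -----------------------------------------------------------------

eegnet_init <- function(n_ch, n_times, sfreq, F1 = 8L, D = 2L, F2 = 16L) {
  kl <- max(3L, round(sfreq / 2))
  ks <- 16L
  p1 <- 4L
  p2 <- 8L
  T1 <- n_times %/% p1
  if (T1 < p2) stop("epoch too short for the compact decoder (need >= ",
                    p1 * p2, " timepoints)")
  ks <- min(ks, T1)
  T2 <- T1 %/% p2
  M <- F1 * D
  net <- list(
    n_ch = n_ch, n_times = n_times, F1 = F1, D = D, F2 = F2, M = M,
    kl = kl, ks = ks, p1 = p1, p2 = p2, T1 = T1, T2 = T2,
    idx1 = conv_index_map(n_times, kl),
    idxs = conv_index_map(T1, ks),
    P1 = pool_matrix(n_times, p1),
    P2 = pool_matrix(T1, p2),
    drop_p = 0.25,
    params = list(
      W1 = glorot(F1, kl, kl, kl),
      Wd = glorot(M, n_ch, n_ch, n_ch),
      g1 = rep(1, F1), b1 = rep(0, F1),
      g2 = rep(1, M), b2 = rep(0, M),
      Ws = glorot(M, ks, ks, ks),
      Wp = glorot(F2, M, M, F2),
      g3 = rep(1, F2), b3 = rep(0, F2),
      Wo = matrix(0, F2 * T2, 1), bo = 0
    ),
    run = list(m1 = rep(0, F1), v1 = rep(1, F1),
               m2 = rep(0, M), v2 = rep(1, M),
               m3 = rep(0, F2), v3 = rep(1, F2))
  )
  net
}

# Forward pass on a batch. x: [B, C, T]. Returns logits and, when
# `training`, every cache needed for the backward pass (dropout masks drawn
# from the current RNG state).
eegnet_forward <- function(net, x, training = FALSE) {
  p <- net$params
  B <- dim(x)[1L]; C <- net$n_ch; T0 <- net$n_times
  M <- net$M; F1 <- net$F1; D <- net$D; F2 <- net$F2
  T1 <- net$T1; T2 <- net$T2
  cache <- list(B = B)

  Xmat <- matrix(x, B * C, T0)                       # rows (b,c), b fastest
  cache$Xmat <- Xmat

  # temporal convolution + BN per filter map
  H <- vector("list", F1)
  cache$bn1 <- vector("list", F1)
  cache$H1pre <- if (training) vector("list", F1) else NULL
  for (f in seq_len(F1)) {
    TZ <- conv_toeplitz(p$W1[f, ], T0, net$idx1)
    Hf <- Xmat %*% TZ
    if (training) cache$H1pre[[f]] <- Hf
    bn <- bn_forward(Hf, p$g1[f], p$b1[f], training,
                     net$run$m1[f], net$run$v1[f])
    if (training) {
      net$run$m1[f] <- bn$run_mean; net$run$v1[f] <- bn$run_var
      cache$bn1[[f]] <- list(xhat = bn$xhat, ivar = bn$ivar)
    }
    H[[f]] <- bn$y
  }
  cache$H1 <- if (training) H else NULL

  # depthwise spatial convolution: contract over channels
  Z2 <- matrix(0, M, B * T0)                          # cols (b,t), b fastest
  cache$Hm <- if (training) vector("list", F1) else NULL
  for (f in seq_len(F1)) {
    arr <- array(H[[f]], c(B, C, T0))
    m <- matrix(aperm(arr, c(2, 1, 3)), C, B * T0)
    if (training) cache$Hm[[f]] <- m
    rows <- (f - 1L) * D + seq_len(D)
    Z2[rows, ] <- p$Wd[rows, , drop = FALSE] %*% m
  }
  cache$Z2pre <- if (training) Z2 else NULL

  # BN per map + ELU
  cache$bn2 <- if (training) vector("list", M) else NULL
  A2 <- Z2
  for (mm in seq_len(M)) {
    bn <- bn_forward(Z2[mm, ], p$g2[mm], p$b2[mm], training,
                     net$run$m2[mm], net$run$v2[mm])
    if (training) {
      net$run$m2[mm] <- bn$run_mean; net$run$v2[mm] <- bn$run_var
      cache$bn2[[mm]] <- list(xhat = bn$xhat, ivar = bn$ivar)
    }
    A2[mm, ] <- bn$y
  }
  E2 <- elu(A2)
  cache$A2 <- if (training) A2 else NULL
  cache$E2 <- if (training) E2 else NULL

  # average pool over time (factor p1) + dropout
  Z3 <- matrix(as.vector(E2), M * B, T0) %*% net$P1   # rows (m,b), m fastest
  if (training) {
    mask1 <- matrix(stats::rbinom(length(Z3), 1, 1 - net$drop_p) /
                      (1 - net$drop_p), nrow(Z3), ncol(Z3))
    Z3 <- Z3 * mask1
    cache$mask1 <- mask1
  }
  cache$Z3 <- if (training) Z3 else NULL

  # separable convolution: depthwise temporal then pointwise across maps
  S <- matrix(0, M * B, T1)
  cache$rows_m <- lapply(seq_len(M), function(mm) seq(mm, M * B, by = M))
  for (mm in seq_len(M)) {
    TZ <- conv_toeplitz(p$Ws[mm, ], T1, net$idxs)
    S[cache$rows_m[[mm]], ] <- Z3[cache$rows_m[[mm]], , drop = FALSE] %*% TZ
  }
  cache$S <- if (training) S else NULL
  Sm <- matrix(as.vector(S), M, B * T1)               # cols (b,t1), b fastest
  P3 <- p$Wp %*% Sm                                   # [F2, B*T1]
  cache$Sm <- if (training) Sm else NULL

  cache$bn3 <- if (training) vector("list", F2) else NULL
  A3 <- P3
  for (f2 in seq_len(F2)) {
    bn <- bn_forward(P3[f2, ], p$g3[f2], p$b3[f2], training,
                     net$run$m3[f2], net$run$v3[f2])
    if (training) {
      net$run$m3[f2] <- bn$run_mean; net$run$v3[f2] <- bn$run_var
      cache$bn3[[f2]] <- list(xhat = bn$xhat, ivar = bn$ivar)
    }
    A3[f2, ] <- bn$y
  }
  E3 <- elu(A3)
  cache$A3 <- if (training) A3 else NULL
  cache$E3 <- if (training) E3 else NULL

  Q <- matrix(as.vector(E3), F2 * B, T1) %*% net$P2   # rows (f2,b), f2 fastest
  if (training) {
    mask2 <- matrix(stats::rbinom(length(Q), 1, 1 - net$drop_p) /
                      (1 - net$drop_p), nrow(Q), ncol(Q))
    Q <- Q * mask2
    cache$mask2 <- mask2
  }
  Feat <- matrix(aperm(array(Q, c(F2, B, T2)), c(2, 1, 3)), B, F2 * T2)
  cache$Feat <- Feat
  logits <- as.vector(Feat %*% p$Wo) + p$bo
  list(logits = logits, cache = cache, net = net)
}

# Backward pass: returns gradients for every parameter.
eegnet_backward <- function(net, cache, dlogits) {
  p <- net$params
  B <- cache$B; C <- net$n_ch; T0 <- net$n_times
  M <- net$M; F1 <- net$F1; D <- net$D; F2 <- net$F2
  T1 <- net$T1; T2 <- net$T2
  g <- list()

  g$Wo <- crossprod(cache$Feat, dlogits)
  g$bo <- sum(dlogits)
  dFeat <- outer(dlogits, as.vector(p$Wo))            # [B, F2*T2]

  dQ <- matrix(aperm(array(dFeat, c(B, F2, T2)), c(2, 1, 3)), F2 * B, T2)
  dQ <- dQ * cache$mask2
  dE3m <- dQ %*% t(net$P2)                            # [F2*B, T1]
  dE3 <- matrix(as.vector(dE3m), F2, B * T1)

  dA3 <- dE3 * elu_grad(cache$A3, cache$E3)
  dP3 <- dA3
  g$g3 <- numeric(F2); g$b3 <- numeric(F2)
  for (f2 in seq_len(F2)) {
    bb <- bn_backward(dA3[f2, ], cache$bn3[[f2]], p$g3[f2])
    dP3[f2, ] <- bb$dx
    g$g3[f2] <- bb$dgamma; g$b3[f2] <- bb$dbeta
  }

  g$Wp <- dP3 %*% t(cache$Sm)
  dSm <- t(p$Wp) %*% dP3                              # [M, B*T1]
  dS <- matrix(as.vector(dSm), M * B, T1)

  dZ3 <- matrix(0, M * B, T1)
  g$Ws <- matrix(0, M, net$ks)
  for (mm in seq_len(M)) {
    rows <- cache$rows_m[[mm]]
    TZ <- conv_toeplitz(p$Ws[mm, ], T1, net$idxs)
    dZ3[rows, ] <- dS[rows, , drop = FALSE] %*% t(TZ)
    G <- crossprod(cache$Z3[rows, , drop = FALSE], dS[rows, , drop = FALSE])
    g$Ws[mm, ] <- conv_weight_grad(G, net$idxs)
  }

  dZ3 <- dZ3 * cache$mask1
  dE2m <- dZ3 %*% t(net$P1)                           # [M*B, T0]
  dE2 <- matrix(as.vector(dE2m), M, B * T0)

  dA2 <- dE2 * elu_grad(cache$A2, cache$E2)
  dZ2 <- dA2
  g$g2 <- numeric(M); g$b2 <- numeric(M)
  for (mm in seq_len(M)) {
    bb <- bn_backward(dA2[mm, ], cache$bn2[[mm]], p$g2[mm])
    dZ2[mm, ] <- bb$dx
    g$g2[mm] <- bb$dgamma; g$b2[mm] <- bb$dbeta
  }

  g$Wd <- matrix(0, M, C)
  g$W1 <- matrix(0, F1, net$kl)
  g$g1 <- numeric(F1); g$b1 <- numeric(F1)
  for (f in seq_len(F1)) {
    rows <- (f - 1L) * D + seq_len(D)
    dZf <- dZ2[rows, , drop = FALSE]
    g$Wd[rows, ] <- dZf %*% t(cache$Hm[[f]])
    dm <- t(p$Wd[rows, , drop = FALSE]) %*% dZf       # [C, B*T0]
    dH <- matrix(aperm(array(dm, c(C, B, T0)), c(2, 1, 3)), B * C, T0)
    bb <- bn_backward(dH, cache$bn1[[f]], p$g1[f])
    g$g1[f] <- bb$dgamma; g$b1[f] <- bb$dbeta
    G <- crossprod(cache$Xmat, matrix(bb$dx, B * C, T0))
    g$W1[f, ] <- conv_weight_grad(G, net$idx1)
  }
  g
}

eegnet_loss_grad <- function(net, x, y, training = TRUE) {
  fw <- eegnet_forward(net, x, training = training)
  pr <- 1 / (1 + exp(-pmin(pmax(fw$logits, -35), 35)))
  eps <- 1e-12
  loss <- -mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps))
  dlogits <- (pr - y) / length(y)
  grads <- eegnet_backward(fw$net, fw$cache, dlogits)
  list(loss = loss, grads = grads, net = fw$net)
}

adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Max-norm constraints as in the published architecture: each depthwise
# spatial filter is renormed to ||w|| <= 1, the dense weight to ||w|| <= 0.25.
apply_maxnorm <- function(params) {
  nrm <- sqrt(rowSums(params$Wd^2))
  scl <- pmin(1, 1 / pmax(nrm, 1e-12))
  params$Wd <- params$Wd * scl
  wn <- sqrt(sum(params$Wo^2))
  if (wn > 0.25) params$Wo <- params$Wo * (0.25 / wn)
  params
}

eegnet_train <- function(x, y, sfreq, cfg) {
  net <- eegnet_init(dim(x)[2L], dim(x)[3L], sfreq)
  state <- adam_init(net$params)
  n <- dim(x)[1L]
  for (epoch in seq_len(cfg$cycles)) {
    ord <- sample(n)
    starts <- seq(1, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      lg <- eegnet_loss_grad(net, x[idx, , , drop = FALSE], y[idx])
      net <- lg$net                       # updated BN running stats
      upd <- adam_step(net$params, lg$grads, state, cfg$lr)
      net$params <- apply_maxnorm(upd$params)
      state <- upd$state
    }
  }
  net
}

eegnet_predict <- function(net, x) {
  fw <- eegnet_forward(net, x, training = FALSE)
  as.numeric(fw$logits > 0)
}

# Stratified-CV accuracy of the compact decoder; folds are given, the
# training RNG (shuffling, init, dropout) derives from cfg$seed.
eegnet_cv_accuracy <- function(X, y, fold, cfg, sfreq) {
  k <- max(fold)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    accs[f] <- with_seed(derive_seed(cfg$seed, "eegnet", f), {
      net <- eegnet_train(X[tr, , , drop = FALSE], y[tr], sfreq, cfg)
      mean(eegnet_predict(net, X[te, , , drop = FALSE]) == y[te])
    })
  }
  mean(accs)
}
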