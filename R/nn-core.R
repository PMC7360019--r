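# Internal neural-network engine.
#
# The tagger is a small computational graph (char embedding -> width-4
# convolution -> ReLU -> global max pool -> add word vector -> batch norm ->
# bi-LSTM -> batch norm -> sigmoid dense), implemented directly on BLAS
# matrix operations with analytic backward passes. Token n of a batch lives
# at row n = (b - 1) * seqLen + t, so each LSTM timestep is a contiguous
# stride of rows. Gradient correctness is pinned down by a finite-difference
# check in the test suite.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

# ---- parameter initialization ------------------------------------------------

.glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

.initTower <- function(cfg, nChar) {
  D <- cfg$wordDim; dc <- cfg$charDim; nf <- cfg$cnnFilters; U <- cfg$lstmUnits
  charEmb <- matrix(stats::runif(nChar * dc, -0.05, 0.05), nChar, dc)
  charEmb[1L, ] <- 0  # <pad> embedding stays zero
  lstm <- function() {
    b <- numeric(4 * U)
    b[(U + 1L):(2L * U)] <- 1  # forget-gate bias
    list(Wx = .glorot(D, 4 * U), Wh = .glorot(U, 4 * U), b = b)
  }
  list(charEmb = charEmb,
       convW = .glorot(cfg$cnnWidth * dc, nf), convB = numeric(nf),
       bn1 = list(gamma = rep(1, nf), beta = numeric(nf),
                  mean = numeric(nf), var = rep(1, nf)),
       fwd = lstm(), bwd = lstm(),
       bn2 = list(gamma = rep(1, 2 * U), beta = numeric(2 * U),
                  mean = numeric(2 * U), var = rep(1, 2 * U)))
}

.initDense <- function(cfg) {
  U2 <- 2L * cfg$lstmUnits
  list(w = as.numeric(.glorot(U2, 1L)), b = 0)
}

.initParams <- function(cfg, nChar, seed) {
  .withSeed(seed, c(.initTower(cfg, nChar), list(dense = .initDense(cfg))))
}

# Paths of the trainable tensors inside a params list (running BN statistics
# are maintained by the forward pass, not optimized).
.trainablePaths <- function(withDense = TRUE) {
  p <- list("charEmb", "convW", "convB",
            c("bn1", "gamma"), c("bn1", "beta"),
            c("fwd", "Wx"), c("fwd", "Wh"), c("fwd", "b"),
            c("bwd", "Wx"), c("bwd", "Wh"), c("bwd", "b"),
            c("bn2", "gamma"), c("bn2", "beta"))
  if (withDense) p <- c(p, list(c("dense", "w"), c("dense", "b")))
  p
}

.getPath <- function(lst, path) {
  for (k in path) lst <- lst[[k]]
  lst
}

.setPath <- function(lst, path, value) {
  if (length(path) == 1L) lst[[path]] <- value
  else lst[[path[1L]]] <- .setPath(lst[[path[1L]]], path[-1L], value)
  lst
}

# ---- batch normalization -----------------------------------------------------

.bnFwd <- function(X, bn, train) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + .BN_EPS)
    xhat <- sweep(xc, 2, inv, "*")
    Y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    list(Y = Y, cache = list(xhat = xhat, inv = inv),
         run = list(mean = .BN_MOMENTUM * bn$mean + (1 - .BN_MOMENTUM) * mu,
                    var = .BN_MOMENTUM * bn$var + (1 - .BN_MOMENTUM) * v))
  } else {
    inv <- 1 / sqrt(bn$var + .BN_EPS)
    xhat <- sweep(sweep(X, 2, bn$mean), 2, inv, "*")
    list(Y = sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+"),
         cache = NULL, run = NULL)
  }
}

.bnBwd <- function(dY, bn, cache) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, bn$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- m * dxhat
  dX <- sweep(dX, 2, s1)
  dX <- dX - sweep(cache$xhat, 2, s2, "*")
  dX <- sweep(dX, 2, cache$inv / m, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- character CNN -----------------------------------------------------------

# C: N x L integer matrix of 0-based char ids (PAD = 0), lens: valid lengths.
.cnnFwd <- function(params, C, lens, cfg) {
  N <- nrow(C); L <- ncol(C)
  W <- cfg$cnnWidth
  dc <- cfg$charDim; nf <- cfg$cnnFilters
  P <- L - W + 1L
  stopifnot(P >= 1L)
  M <- matrix(0, N * P, W * dc)
  for (o in seq_len(W)) {
    ids <- as.vector(C[, o:(o + P - 1L), drop = FALSE]) + 1L
    M[, ((o - 1L) * dc + 1L):(o * dc)] <- params$charEmb[ids, , drop = FALSE]
  }
  Z <- M %*% params$convW
  Z <- sweep(Z, 2, params$convB, "+")
  relu <- Z > 0
  A <- Z * relu
  validP <- pmax(lens - W + 1L, 1L)
  pOfRow <- rep(seq_len(P), each = N)
  nOfRow <- rep(seq_len(N), times = P)
  invalid <- pOfRow > validP[nOfRow]
  if (any(invalid)) A[invalid, ] <- -1e30
  G <- A[seq_len(N), , drop = FALSE]
  arg <- matrix(1L, N, nf)
  if (P > 1L) {
    for (p in 2:P) {
      Ap <- A[((p - 1L) * N + 1L):(p * N), , drop = FALSE]
      upd <- Ap > G
      G[upd] <- Ap[upd]
      arg[upd] <- p
    }
  }
  list(G = G, cache = list(M = M, relu = relu, arg = arg, N = N, P = P,
                           C = C))
}

.cnnBwd <- function(params, dG, cache, cfg) {
  N <- cache$N; P <- cache$P
  W <- cfg$cnnWidth; dc <- cfg$charDim; nf <- cfg$cnnFilters
  rsel <- as.vector((cache$arg - 1L) * N + seq_len(N))       # (n, f) entries
  idx <- (rep(seq_len(nf), each = N) - 1L) * (N * P) + rsel  # linear index
  dA <- numeric(N * P * nf)
  dA[idx] <- as.vector(dG)
  dim(dA) <- c(N * P, nf)
  dA[!cache$relu] <- 0
  dconvW <- crossprod(cache$M, dA)
  dconvB <- colSums(dA)
  dM <- dA %*% t(params$convW)
  dEmb <- matrix(0, nrow(params$charEmb), dc)
  for (o in seq_len(W)) {
    ids <- as.vector(cache$C[, o:(o + P - 1L), drop = FALSE]) + 1L
    block <- dM[, ((o - 1L) * dc + 1L):(o * dc), drop = FALSE]
    rs <- rowsum(block, group = ids)
    rows <- as.integer(rownames(rs))
    dEmb[rows, ] <- dEmb[rows, , drop = FALSE] + rs
  }
  dEmb[1L, ] <- 0  # <pad> embedding frozen
  list(dCharEmb = dEmb, dConvW = dconvW, dConvB = dconvB)
}

# ---- LSTM --------------------------------------------------------------------

# X: N x D inputs; idxT[[t]]: row indices of timestep t. Dropout masks (B x D
# and B x U, shared across timesteps, already inverted-scaled) or NULL.
.lstmFwd <- function(lp, X, idxT, U, reverse, dropX = NULL, dropH = NULL) {
  Tn <- length(idxT)
  B <- length(idxT[[1L]])
  H <- matrix(0, B, U); Cc <- matrix(0, B, U)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  cache <- vector("list", Tn)
  Hout <- vector("list", Tn)
  i1 <- 1L:U; i2 <- (U + 1L):(2L * U); i3 <- (2L * U + 1L):(3L * U)
  i4 <- (3L * U + 1L):(4L * U)
  for (t in ord) {
    Xt <- X[idxT[[t]], , drop = FALSE]
    if (!is.null(dropX)) Xt <- Xt * dropX
    Cprev <- Cc
    Hd <- if (!is.null(dropH)) H * dropH else H
    Z <- Xt %*% lp$Wx + Hd %*% lp$Wh
    Z <- sweep(Z, 2, lp$b, "+")
    gi <- .sigm(Z[, i1, drop = FALSE])
    gf <- .sigm(Z[, i2, drop = FALSE])
    gg <- tanh(Z[, i3, drop = FALSE])
    go <- .sigm(Z[, i4, drop = FALSE])
    Cc <- gf * Cprev + gi * gg
    tc <- tanh(Cc)
    H <- go * tc
    Hout[[t]] <- H
    cache[[t]] <- list(Xt = Xt, Hd = Hd, Cprev = Cprev,
                       i = gi, f = gf, g = gg, o = go, tc = tc)
  }
  list(H = Hout, cache = cache)
}

.lstmBwd <- function(lp, dHout, cache, idxT, U, N, D, reverse,
                     dropX = NULL, dropH = NULL) {
  Tn <- length(idxT)
  B <- length(idxT[[1L]])
  dWx <- matrix(0, D, 4 * U); dWh <- matrix(0, U, 4 * U); db <- numeric(4 * U)
  dX <- matrix(0, N, D)
  dHnext <- matrix(0, B, U); dCnext <- matrix(0, B, U)
  ord <- if (reverse) seq_len(Tn) else rev(seq_len(Tn))
  for (t in ord) {
    cc <- cache[[t]]
    dH <- dHout[[t]] + dHnext
    do_ <- dH * cc$tc
    dC <- dH * cc$o * (1 - cc$tc^2) + dCnext
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$Cprev
    dCnext <- dC * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$Xt, dZ)
    dWh <- dWh + crossprod(cc$Hd, dZ)
    db <- db + colSums(dZ)
    dXt <- dZ %*% t(lp$Wx)
    if (!is.null(dropX)) dXt <- dXt * dropX
    dHd <- dZ %*% t(lp$Wh)
    if (!is.null(dropH)) dHd <- dHd * dropH
    dHnext <- dHd
    dX[idxT[[t]], ] <- dX[idxT[[t]], , drop = FALSE] + dXt
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- tower (word representation + contextual encoder) ------------------------

.dropMask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# batch: list(C, lens, Wv, real, idxT, B, Tn). Returns H (N x 2U, PAD rows 0),
# caches for backward, and updated running statistics when training.
.towerFwd <- function(params, batch, cfg, train) {
  N <- nrow(batch$Wv)
  U <- cfg$lstmUnits
  cnn <- .cnnFwd(params, batch$C, batch$lens, cfg)
  S <- batch$Wv + cnn$G
  real <- batch$real
  bn1 <- .bnFwd(S[real, , drop = FALSE], params$bn1, train)
  X <- matrix(0, N, cfg$wordDim)
  X[real, ] <- bn1$Y
  drop <- NULL
  if (train && (cfg$dropout > 0 || cfg$recurrentDropout > 0)) {
    drop <- list(xf = .dropMask(batch$B, cfg$wordDim, cfg$dropout),
                 hf = .dropMask(batch$B, U, cfg$recurrentDropout),
                 xb = .dropMask(batch$B, cfg$wordDim, cfg$dropout),
                 hb = .dropMask(batch$B, U, cfg$recurrentDropout))
  }
  lf <- .lstmFwd(params$fwd, X, batch$idxT, U, reverse = FALSE,
                 dropX = drop$xf, dropH = drop$hf)
  lb <- .lstmFwd(params$bwd, X, batch$idxT, U, reverse = TRUE,
                 dropX = drop$xb, dropH = drop$hb)
  Hcat <- matrix(0, N, 2L * U)
  for (t in seq_along(batch$idxT))
    Hcat[batch$idxT[[t]], ] <- cbind(lf$H[[t]], lb$H[[t]])
  bn2 <- .bnFwd(Hcat[real, , drop = FALSE], params$bn2, train)
  H <- matrix(0, N, 2L * U)
  H[real, ] <- bn2$Y
  run <- if (train) list(bn1 = bn1$run, bn2 = bn2$run) else NULL
  list(H = H,
       cache = list(cnn = cnn$cache, bn1 = bn1$cache, bn2 = bn2$cache,
                    lf = lf, lb = lb, drop = drop, X = X),
       run = run)
}

.towerBwd <- function(params, dH, batch, cache, cfg) {
  N <- nrow(dH)
  U <- cfg$lstmUnits
  real <- batch$real
  b2 <- .bnBwd(dH[real, , drop = FALSE], params$bn2, cache$bn2)
  dHcat <- matrix(0, N, 2L * U)
  dHcat[real, ] <- b2$dX
  Tn <- length(batch$idxT)
  dHf <- vector("list", Tn); dHb <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    rows <- batch$idxT[[t]]
    dHf[[t]] <- dHcat[rows, seq_len(U), drop = FALSE]
    dHb[[t]] <- dHcat[rows, (U + 1L):(2L * U), drop = FALSE]
  }
  gf <- .lstmBwd(params$fwd, dHf, cache$lf$cache, batch$idxT, U, N,
                 cfg$wordDim, reverse = FALSE,
                 dropX = cache$drop$xf, dropH = cache$drop$hf)
  gb <- .lstmBwd(params$bwd, dHb, cache$lb$cache, batch$idxT, U, N,
                 cfg$wordDim, reverse = TRUE,
                 dropX = cache$drop$xb, dropH = cache$drop$hb)
  dX <- gf$dX + gb$dX
  b1 <- .bnBwd(dX[real, , drop = FALSE], params$bn1, cache$bn1)
  dS <- matrix(0, N, cfg$wordDim)
  dS[real, ] <- b1$dX
  cg <- .cnnBwd(params, dS, cache$cnn, cfg)
  list(charEmb = cg$dCharEmb, convW = cg$dConvW, convB = cg$dConvB,
       bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
       fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
       bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db),
       bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
}

# ---- prediction head and loss ------------------------------------------------

.headFwd <- function(dense, H) {
  as.numeric(.sigm(H %*% dense$w + dense$b))
}

# weights: per-token class weight * loss mask / number of unmasked tokens.
.weightedBce <- function(p, y, weights) {
  eps <- 1e-12
  -sum(weights * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

.headBwd <- function(dense, H, p, y, weights, l1) {
  dz <- weights * (p - y)                 # gradient wrt the pre-sigmoid logit
  dw <- as.numeric(crossprod(H, dz)) + l1 * sign(dense$w)
  dbb <- sum(dz)
  dH <- outer(dz, dense$w)
  list(dw = dw, db = dbb, dH = dH)
}

# ---- full forward/backward for one batch -------------------------------------

# baseParams: when non-NULL, the frozen tower whose contextual representation
# is summed with the trainable tower's before the shared prediction layer.
.netFwd <- function(params, batch, cfg, train, baseParams = NULL) {
  tw <- .towerFwd(params, batch, cfg, train)
  H <- tw$H
  baseH <- NULL
  if (!is.null(baseParams)) {
    baseH <- .towerFwd(baseParams, batch, cfg, train = FALSE)$H
    H <- H + baseH
  }
  p <- .headFwd(params$dense, H)
  loss <- .weightedBce(p, batch$y, batch$weights) +
    cfg$l1 * sum(abs(params$dense$w))
  list(p = p, loss = loss, H = H, tower = tw)
}

.netBwd <- function(params, batch, cfg, fw) {
  hb <- .headBwd(params$dense, fw$H, fw$p, batch$y, batch$weights, cfg$l1)
  g <- .towerBwd(params, hb$dH, batch, fw$tower$cache, cfg)
  g$dense <- list(w = hb$dw, b = hb$db)
  g
}

.applyRunningStats <- function(params, run) {
  if (is.null(run)) return(params)
  params$bn1$mean <- run$bn1$mean; params$bn1$var <- run$bn1$var
  params$bn2$mean <- run$bn2$mean; params$bn2$var <- run$bn2$var
  params
}

# ---- Adam --------------------------------------------------------------------

.adamInit <- function(params, paths) {
  zero <- lapply(paths, function(p) {
    x <- .getPath(params, p)
    x * 0
  })
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(params, grads, state, paths, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(paths)) {
    g <- .getPath(grads, paths[[k]])
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    params <- .setPath(params, paths[[k]],
                       .getPath(params, paths[[k]]) - upd)
  }
  list(params = params, state = state)
}
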