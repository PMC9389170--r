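# Batched network engine: forward and reverse-mode passes for every layer
# type in the architecture (1-D conv + ReLU, non-overlapping max-pool,
# inverted dropout, bidirectional GRU with full backpropagation through
# time, dot-product attention, flatten, dense). Activations are arrays of
# shape (batch, time, channels) between sequence layers and plain matrices
# after flattening. Written against the same equations as the reference
# ops in ops.R, but vectorised over the batch; the test suite checks the
# two against each other.

# ---- small shape helpers -------------------------------------------------

mat3 <- function(X) {            # (b, s, c) -> (b*s) x c
  d <- dim(X)
  dim(X) <- c(d[1L] * d[2L], d[3L])
  X
}

arr3 <- function(M, b, s, c) {   # (b*s) x c -> (b, s, c)
  dim(M) <- c(b, s, c)
  M
}

slice_t <- function(X, t, b, c) matrix(X[, t, ], b, c)

# ---- convolution (same padding, ReLU) ------------------------------------

fwd_conv <- function(layer, X) {
  d <- dim(X); b <- d[1L]; s <- d[2L]; cin <- d[3L]
  L <- dim(layer$W)[1L]; f <- dim(layer$W)[3L]
  if (cin != dim(layer$W)[2L])
    stop(sprintf("conv expects %d channel(s), got %d", dim(layer$W)[2L],
                 cin), call. = FALSE)
  pad_l <- (L - 1L) %/% 2L
  Xp <- array(0, c(b, s + L - 1L, cin))
  Xp[, pad_l + seq_len(s), ] <- X
  Ym <- matrix(layer$b, b * s, f, byrow = TRUE)
  for (u in seq_len(L)) {
    Mu <- mat3(Xp[, u:(u + s - 1L), , drop = FALSE])
    Ym <- Ym + Mu %*% matrix(layer$W[u, , ], cin, f)
  }
  mask <- Ym > 0
  Ym[!mask] <- 0
  list(out = arr3(Ym, b, s, f),
       cache = list(Xp = Xp, mask = mask, b = b, s = s, cin = cin,
                    L = L, f = f, pad_l = pad_l))
}

bwd_conv <- function(layer, cache, dY) {
  dYm <- mat3(dY)
  dYm[!cache$mask] <- 0
  dW <- array(0, dim(layer$W))
  dXp <- array(0, dim(cache$Xp))
  for (u in seq_len(cache$L)) {
    idx <- u:(u + cache$s - 1L)
    Mu <- mat3(cache$Xp[, idx, , drop = FALSE])
    dW[u, , ] <- t(Mu) %*% dYm
    dM <- dYm %*% t(matrix(layer$W[u, , ], cache$cin, cache$f))
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] +
      arr3(dM, cache$b, cache$s, cache$cin)
  }
  list(dX = dXp[, cache$pad_l + seq_len(cache$s), , drop = FALSE],
       grads = list(W = dW, b = colSums(dYm)))
}

# ---- max pooling ---------------------------------------------------------

fwd_maxpool <- function(layer, X) {
  d <- dim(X); s <- d[2L]; k <- layer$k
  s2 <- s %/% k
  if (s2 < 1L)
    stop("max-pool input shorter than pooling window", call. = FALSE)
  Y <- X[, seq(1L, by = k, length.out = s2), , drop = FALSE]
  amax <- array(1L, dim(Y))
  if (k > 1L) for (m in 2:k) {
    Am <- X[, seq(m, by = k, length.out = s2), , drop = FALSE]
    upd <- Am > Y            # ties go to the earliest position
    Y[upd] <- Am[upd]
    amax[upd] <- m
  }
  list(out = Y, cache = list(amax = amax, dims = d, k = k, s2 = s2))
}

bwd_maxpool <- function(layer, cache, dY) {
  dX <- array(0, cache$dims)
  for (m in seq_len(cache$k)) {
    idx <- seq(m, by = cache$k, length.out = cache$s2)
    sel <- cache$amax == m
    tmp <- dX[, idx, , drop = FALSE]
    tmp[sel] <- tmp[sel] + dY[sel]
    dX[, idx, ] <- tmp
  }
  list(dX = dX, grads = NULL)
}

# ---- dropout (inverted) --------------------------------------------------

fwd_dropout <- function(layer, X, training) {
  if (!training || layer$rate <= 0)
    return(list(out = X, cache = NULL))
  keep <- 1 - layer$rate
  mask <- array(stats::runif(length(X)) < keep, dim(X)) / keep
  list(out = X * mask, cache = mask)
}

bwd_dropout <- function(layer, cache, dY) {
  list(dX = if (is.null(cache)) dY else dY * cache, grads = NULL)
}

# ---- bidirectional GRU ---------------------------------------------------

gru_dir_fwd <- function(par, X, reverse) {
  d <- dim(X); b <- d[1L]; s <- d[2L]; cin <- d[3L]
  n <- nrow(par$Wr)
  tWr <- t(par$Wr); tUr <- t(par$Ur)
  tWz <- t(par$Wz); tUz <- t(par$Uz)
  tWx <- t(par$Wx); tUx <- t(par$Ux)
  Br <- matrix(par$br, b, n, byrow = TRUE)
  Bz <- matrix(par$bz, b, n, byrow = TRUE)
  Bc <- matrix(par$bc, b, n, byrow = TRUE)
  H <- matrix(0, b, n)
  OUT <- array(0, c(b, s, n))
  R <- OUT; Z <- OUT; HC <- OUT; HP <- OUT; UXH <- OUT
  ord <- if (reverse) seq.int(s, 1L) else seq_len(s)
  for (t in ord) {
    Xt <- slice_t(X, t, b, cin)
    r <- 1 / (1 + exp(-(Xt %*% tWr + H %*% tUr + Br)))
    z <- 1 / (1 + exp(-(Xt %*% tWz + H %*% tUz + Bz)))
    uxh <- H %*% tUx
    hc <- tanh(Xt %*% tWx + r * uxh + Bc)
    HP[, t, ] <- H
    H <- z * H + (1 - z) * hc     # update gate scales the previous state
    OUT[, t, ] <- H
    R[, t, ] <- r; Z[, t, ] <- z; HC[, t, ] <- hc; UXH[, t, ] <- uxh
  }
  list(out = OUT, R = R, Z = Z, HC = HC, HP = HP, UXH = UXH)
}

gru_dir_bwd <- function(par, X, cc, dOUT, reverse) {
  d <- dim(X); b <- d[1L]; s <- d[2L]; cin <- d[3L]
  n <- nrow(par$Wr)
  g <- list(Wr = matrix(0, n, cin), Ur = matrix(0, n, n),
            Wz = matrix(0, n, cin), Uz = matrix(0, n, n),
            Wx = matrix(0, n, cin), Ux = matrix(0, n, n),
            br = numeric(n), bz = numeric(n), bc = numeric(n))
  dX <- array(0, d)
  ord <- if (reverse) seq.int(s, 1L) else seq_len(s)
  carry <- matrix(0, b, n)
  for (j in seq.int(s, 1L)) {      # reverse of processing order
    t <- ord[j]
    dH <- slice_t(dOUT, t, b, n) + carry
    r <- slice_t(cc$R, t, b, n); z <- slice_t(cc$Z, t, b, n)
    hc <- slice_t(cc$HC, t, b, n); Hp <- slice_t(cc$HP, t, b, n)
    uxh <- slice_t(cc$UXH, t, b, n)
    Xt <- slice_t(X, t, b, cin)
    dz <- dH * (Hp - hc)
    dhc <- dH * (1 - z)
    dHp <- dH * z
    dac <- dhc * (1 - hc^2)
    dr <- dac * uxh
    duxh <- dac * r
    dar <- dr * r * (1 - r)
    daz <- dz * z * (1 - z)
    g$Wx <- g$Wx + t(dac) %*% Xt
    g$Ux <- g$Ux + t(duxh) %*% Hp
    g$Wr <- g$Wr + t(dar) %*% Xt
    g$Ur <- g$Ur + t(dar) %*% Hp
    g$Wz <- g$Wz + t(daz) %*% Xt
    g$Uz <- g$Uz + t(daz) %*% Hp
    g$bc <- g$bc + colSums(dac)
    g$br <- g$br + colSums(dar)
    g$bz <- g$bz + colSums(daz)
    dX[, t, ] <- slice_t(dX, t, b, cin) +
      dac %*% par$Wx + dar %*% par$Wr + daz %*% par$Wz
    carry <- dHp + duxh %*% par$Ux + dar %*% par$Ur + daz %*% par$Uz
  }
  list(dX = dX, grads = g)
}

fwd_bigru <- function(layer, X, training) {
  ff <- gru_dir_fwd(layer$fwd, X, reverse = FALSE)
  bb <- gru_dir_fwd(layer$bwd, X, reverse = TRUE)
  n <- nrow(layer$fwd$Wr)
  if (identical(layer$output, "concat")) {
    d <- dim(X)
    out <- array(0, c(d[1L], d[2L], 2L * n))
    out[, , seq_len(n)] <- ff$out
    out[, , n + seq_len(n)] <- bb$out
  } else {
    out <- list(F = ff$out, B = bb$out)
  }
  cache <- if (training) list(ff = ff, bb = bb, X = X, n = n) else NULL
  list(out = out, cache = cache)
}

bwd_bigru <- function(layer, cache, dY) {
  n <- cache$n
  if (identical(layer$output, "concat")) {
    dF <- dY[, , seq_len(n), drop = FALSE]
    dB <- dY[, , n + seq_len(n), drop = FALSE]
  } else {
    dF <- dY$dF
    dB <- dY$dB
  }
  rf <- gru_dir_bwd(layer$fwd, cache$X, cache$ff, dF, reverse = FALSE)
  rb <- gru_dir_bwd(layer$bwd, cache$X, cache$bb, dB, reverse = TRUE)
  list(dX = rf$dX + rb$dX,
       grads = list(fwd = rf$grads, bwd = rb$grads))
}

# ---- dot-product attention ----------------------------------------------

fwd_attention <- function(layer, X, training) {
  Fa <- X$F; Ba <- X$B
  d <- dim(Fa); b <- d[1L]; s <- d[2L]; n <- d[3L]
  out <- array(0, c(b, s, n))
  A_all <- if (training) array(0, c(b, s, s)) else NULL
  for (i in seq_len(b)) {
    Fm <- matrix(Fa[i, , ], s, n)
    Bm <- matrix(Ba[i, , ], s, n)
    S <- Fm %*% t(Bm)
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    A <- E / rowSums(E)
    out[i, , ] <- A %*% Bm
    if (training) A_all[i, , ] <- A
  }
  list(out = out,
       cache = if (training) list(A = A_all, F = Fa, B = Ba) else NULL)
}

bwd_attention <- function(layer, cache, dY) {
  d <- dim(cache$F); b <- d[1L]; s <- d[2L]; n <- d[3L]
  dF <- array(0, d); dB <- array(0, d)
  for (i in seq_len(b)) {
    Fm <- matrix(cache$F[i, , ], s, n)
    Bm <- matrix(cache$B[i, , ], s, n)
    A <- matrix(cache$A[i, , ], s, s)
    dO <- matrix(dY[i, , ], s, n)
    dA <- dO %*% t(Bm)
    dBi <- t(A) %*% dO
    dS <- A * (dA - rowSums(dA * A))
    dF[i, , ] <- dS %*% Bm
    dB[i, , ] <- dBi + t(dS) %*% Fm
  }
  list(dX = list(dF = dF, dB = dB), grads = NULL)
}

# ---- flatten and dense ---------------------------------------------------

fwd_flatten <- function(layer, X) {
  d <- dim(X)
  dim(X) <- c(d[1L], d[2L] * d[3L])
  list(out = X, cache = d)
}

bwd_flatten <- function(layer, cache, dY) {
  dim(dY) <- cache
  list(dX = dY, grads = NULL)
}

fwd_dense <- function(layer, X) {
  if (ncol(X) != ncol(layer$W))
    stop(sprintf("dense layer expects %d inputs, got %d", ncol(layer$W),
                 ncol(X)), call. = FALSE)
  A <- X %*% t(layer$W) + matrix(layer$b, nrow(X), length(layer$b),
                                 byrow = TRUE)
  out <- switch(layer$activation,
    relu = pmax(A, 0),
    softmax = {
      A2 <- A - apply(A, 1L, max)
      E <- exp(A2)
      E / rowSums(E)
    },
    A)
  list(out = out, cache = list(X = X, A = A))
}

bwd_dense <- function(layer, cache, dY) {
  # for the softmax head the caller supplies the pre-activation gradient
  # (probs - onehot)/batch directly, so no Jacobian is applied here
  dZ <- switch(layer$activation,
               relu = dY * (cache$A > 0),
               dY)
  list(dX = dZ %*% layer$W,
       grads = list(W = t(dZ) %*% cache$X, b = colSums(dZ)))
}

# ---- whole-network passes ------------------------------------------------

net_forward <- function(layers, X, training = FALSE) {
  caches <- if (training) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
                conv = fwd_conv(ly, X),
                maxpool = fwd_maxpool(ly, X),
                dropout = fwd_dropout(ly, X, training),
                bigru = fwd_bigru(ly, X, training),
                attention = fwd_attention(ly, X, training),
                flatten = fwd_flatten(ly, X),
                dense = fwd_dense(ly, X),
                stop("unknown layer type: ", ly$type))
    X <- r$out
    if (training) caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

net_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    r <- switch(ly$type,
                conv = bwd_conv(ly, cc, dOut),
                maxpool = bwd_maxpool(ly, cc, dOut),
                dropout = bwd_dropout(ly, cc, dOut),
                bigru = bwd_bigru(ly, cc, dOut),
                attention = bwd_attention(ly, cc, dOut),
                flatten = bwd_flatten(ly, cc, dOut),
                dense = bwd_dense(ly, cc, dOut),
                stop("unknown layer type: ", ly$type))
    if (!is.null(r$grads)) grads[[i]] <- r$grads
    dOut <- r$dX
  }
  grads
}

# ---- parameter trees -----------------------------------------------------

net_params <- function(layers) {
  lapply(layers, function(ly) {
    switch(ly$type,
           conv = list(W = ly$W, b = ly$b),
           dense = list(W = ly$W, b = ly$b),
           bigru = list(fwd = ly$fwd, bwd = ly$bwd),
           NULL)
  })
}

net_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    p <- params[[i]]
    if (is.null(p)) next
    ly <- layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      layers[[i]]$W <- p$W
      layers[[i]]$b <- p$b
    } else if (ly$type == "bigru") {
      layers[[i]]$fwd <- p$fwd
      layers[[i]]$bwd <- p$bwd
    }
  }
  layers
}

# apply f(a, b) leaf-wise over two parallel trees of numeric arrays
tree_map2 <- function(f, a, b) {
  if (is.list(a))
    return(mapply(tree_map2, a, b, MoreArgs = list(f = f),
                  SIMPLIFY = FALSE))
  f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

tree_count <- function(a) {
  if (is.list(a)) return(sum(vapply(a, tree_count, numeric(1))))
  if (is.null(a)) 0 else length(a)
}
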