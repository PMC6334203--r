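# Minimal convolutional network engine.
#
# Tensors are plain R arrays with dims (H, W, N, C) -- channel-last, so that
# (i) reshaping to the (pixel*sample) x channel matrices the GEMMs want is a
# zero-copy `dim<-`, and (ii) channel concatenation/splitting is contiguous.
# All heavy lifting is GEMM via im2col with cached gather indices, so
# throughput tracks the BLAS. Each primitive returns a forward value plus a
# cache, and has a matching backward that consumes the cache. Weight layout
# for a k x k convolution with Cin inputs and Cout outputs is a (k*k*Cin) x
# Cout matrix whose rows are ordered (ky, kx, c), ky fastest -- the order
# im2col emits patch elements in.

nn_pad <- function(X, p) {
  if (p == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  Xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- X
  Xp
}

# Gather-index caches. conv index: (oh*ow*N) x (k*k*C) linear indices into a
# padded (Hp, Wp, N, C) volume; rows ordered pixel-fastest then sample,
# columns (ky, kx, c). The spatial variant spans a (Hp, Wp, N) volume and is
# used by the transposed-conv scatter.
.nn_idx_cache <- new.env(parent = emptyenv())
nn_conv_idx <- function(Hp, Wp, N, C, k, s, oh, ow) {
  key <- paste("c", Hp, Wp, N, C, k, s, oh, ow, sep = "_")
  got <- .nn_idx_cache[[key]]
  if (!is.null(got)) return(got)
  corner <- rep((seq_len(oh) - 1L) * s, times = ow) +
    Hp * rep((seq_len(ow) - 1L) * s, each = oh)
  offs <- rep(0:(k - 1), times = k) + Hp * rep(0:(k - 1), each = k)
  rows <- outer(corner, (0:(N - 1L)) * (Hp * Wp), "+")      # (ohw, N)
  cols <- outer(offs, (0:(C - 1L)) * (Hp * Wp * N), "+")    # (k*k, C)
  idx <- outer(as.vector(rows), as.vector(cols), "+") + 1
  storage.mode(idx) <- "integer"
  .nn_idx_cache[[key]] <- idx
  idx
}
nn_spatial_idx <- function(Hp, Wp, N, k, s, oh, ow) {
  nn_conv_idx(Hp, Wp, N, 1L, k, s, oh, ow)
}

# im2col: (oh*ow*N) x (k*k*C) patch matrix
nn_im2col <- function(X, k, s = 1L, p = 0L) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  if ((H + 2 * p - k) %% s != 0 || (W + 2 * p - k) %% s != 0) {
    stop(sprintf("conv geometry mismatch: H=%d k=%d s=%d p=%d", H, k, s, p),
         call. = FALSE)
  }
  oh <- (H + 2L * p - k) %/% s + 1L
  ow <- (W + 2L * p - k) %/% s + 1L
  Xp <- nn_pad(X, p)
  idx <- nn_conv_idx(H + 2L * p, W + 2L * p, N, C, k, s, oh, ow)
  M <- Xp[as.vector(idx)]
  dim(M) <- dim(idx)
  list(M = M, oh = oh, ow = ow, dimX = d)
}

conv_fwd <- function(X, Wm, b, k, s = 1L, p = 0L) {
  ic <- nn_im2col(X, k, s, p)
  Y <- ic$M %*% Wm
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(ic$oh, ic$ow, dim(X)[3], ncol(Wm))
  list(out = Y,
       cache = list(M = ic$M, dimX = ic$dimX, k = k, s = s, p = p,
                    oh = ic$oh, ow = ic$ow))
}

conv_bwd <- function(dY, cache, Wm, need_dx = TRUE) {
  k <- cache$k; s <- cache$s; p <- cache$p
  d <- cache$dimX
  N <- d[3]; C <- d[4]
  Cout <- ncol(Wm)
  oh <- cache$oh; ow <- cache$ow
  dYm <- dY
  dim(dYm) <- c(oh * ow * N, Cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dX <- NULL
  if (need_dx) {
    # gradient w.r.t. the input = zero-stuffed dY convolved with the
    # spatially flipped, channel-transposed kernel
    if (s > 1L) {
      Hs <- (oh - 1L) * s + 1L; Ws <- (ow - 1L) * s + 1L
      dYs <- array(0, c(Hs, Ws, N, Cout))
      dYs[seq(1L, Hs, by = s), seq(1L, Ws, by = s), , ] <- dY
    } else {
      dYs <- dY
    }
    Warr <- array(Wm, c(k, k, C, Cout))
    Wf <- matrix(aperm(Warr[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3)),
                 k * k * Cout, C)
    q <- k - 1L - p
    dX <- conv_fwd(dYs, Wf, NULL, k, 1L, q)$out
  }
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution (stride-s learned upsampling), the adjoint of a
# stride-s convolution. Weight layout: Cin x (k*k*Cout), columns ordered
# (ky, kx, co), ky fastest. Each input pixel emits a k x k patch into the
# output; overlapping patches accumulate. Output side is (H-1)*s + k - 2p;
# with k=4, s=2, p=1 this exactly doubles the resolution.
tconv_fwd <- function(X, Wt, b, k, s = 2L, p = 1L) {
  d <- dim(X)
  hi <- d[1]; wi <- d[2]; N <- d[3]; Cin <- d[4]
  kk <- k * k
  Cout <- ncol(Wt) %/% kk
  Hp <- (hi - 1L) * s + k
  Wp <- (wi - 1L) * s + k
  Ho <- Hp - 2L * p; Wo <- Wp - 2L * p
  Xall <- X
  dim(Xall) <- c(hi * wi * N, Cin)
  P <- Xall %*% Wt
  isp <- nn_spatial_idx(Hp, Wp, N, k, s, hi, wi)   # (hi*wi*N) x kk
  outp <- matrix(0, Hp * Wp * N, Cout)
  for (j in seq_len(ncol(P))) {
    co <- (j - 1L) %/% kk + 1L
    ii <- isp[, (j - 1L) %% kk + 1L]
    outp[ii, co] <- outp[ii, co] + P[, j]
  }
  dim(outp) <- c(Hp, Wp, N, Cout)
  out <- outp[p + seq_len(Ho), p + seq_len(Wo), , , drop = FALSE]
  if (!is.null(b)) out <- out + rep(b, each = Ho * Wo * N)
  list(out = out, cache = list(Xall = Xall, dimX = d, k = k, s = s, p = p,
                               Cout = Cout))
}

tconv_bwd <- function(dY, cache, Wt, need_dx = TRUE) {
  d <- cache$dimX
  ic <- nn_im2col(dY, cache$k, cache$s, cache$p)   # rows match Xall's rows
  dWt <- crossprod(cache$Xall, ic$M)
  dYm <- dY
  dim(dYm) <- c(length(dY) %/% cache$Cout, cache$Cout)
  db <- colSums(dYm)
  dX <- NULL
  if (need_dx) {
    dX <- ic$M %*% t(Wt)
    dim(dX) <- d
  }
  list(dX = dX, dW = dWt, db = db)
}

maxpool_fwd <- function(X) {
  d <- dim(X)
  H <- d[1]; W <- d[2]
  oh <- H %/% 2L; ow <- W %/% 2L
  i1 <- seq(1L, H, by = 2L); j1 <- seq(1L, W, by = 2L)
  V <- cbind(as.vector(X[i1, j1, , , drop = FALSE]),
             as.vector(X[i1 + 1L, j1, , , drop = FALSE]),
             as.vector(X[i1, j1 + 1L, , , drop = FALSE]),
             as.vector(X[i1 + 1L, j1 + 1L, , , drop = FALSE]))
  amax <- max.col(V, ties.method = "first")
  Y <- V[cbind(seq_len(nrow(V)), amax)]
  dim(Y) <- c(oh, ow, d[3], d[4])
  list(out = Y, cache = list(dimX = d, amax = amax))
}

maxpool_bwd <- function(dY, cache) {
  d <- cache$dimX
  H <- d[1]; W <- d[2]
  oh <- H %/% 2L; ow <- W %/% 2L
  npl <- d[3] * d[4]                     # combined sample x channel planes
  oyg <- rep(seq_len(oh), times = ow * npl)
  oxg <- rep(rep(seq_len(ow), each = oh), times = npl)
  plg <- rep(seq_len(npl), each = oh * ow)
  dy <- c(1L, 2L, 1L, 2L)[cache$amax]
  dx <- c(1L, 1L, 2L, 2L)[cache$amax]
  lin <- (2L * oyg - 2L + dy) + H * (2L * oxg - 2L + dx - 1L) +
    H * W * (plg - 1L)
  dX <- array(0, d)
  dX[lin] <- as.vector(dY)
  dX
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dY, cache) dY * cache

# channel-wise batch normalisation over (H, W, N)
bn_fwd <- function(X, bn, train = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  C <- d[4]
  nr <- prod(d[1:3])
  Xm <- X
  dim(Xm) <- c(nr, C)
  if (train) {
    mu <- .colMeans(Xm, nr, C)
    va <- .colMeans(Xm * Xm, nr, C) - mu^2
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * va
  } else {
    mu <- bn$rmean
    va <- bn$rvar
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (Xm - rep(mu, each = nr)) * rep(invstd, each = nr)
  Y <- xhat * rep(bn$gamma, each = nr) + rep(bn$beta, each = nr)
  dim(Y) <- d
  list(out = Y, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, dims = d, train = train))
}
bn_bwd <- function(dY, cache, bn) {
  d <- cache$dims
  C <- d[4]
  nr <- prod(d[1:3])
  dYm <- dY
  dim(dYm) <- c(nr, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(bn$gamma, each = nr)
  if (cache$train) {
    s1 <- .colMeans(dxhat, nr, C)
    s2 <- .colMeans(dxhat * xhat, nr, C)
    dX <- (dxhat - rep(s1, each = nr) - xhat * rep(s2, each = nr)) *
      rep(cache$invstd, each = nr)
  } else {
    dX <- dxhat * rep(cache$invstd, each = nr)
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# bind (H, W, N, C) arrays along the channel axis (contiguous, so just c())
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- unlist(lapply(xs, as.vector), use.names = FALSE)
  dim(out) <- c(d[1], d[2], d[3],
                sum(vapply(xs, function(x) dim(x)[4], 0)))
  out
}

# Convolutional LSTM cell: gate pre-activations are a single convolution of
# the channel-concatenated (input, hidden) pair into 4*Ch channels ordered
# (input, forget, output, candidate).
clstm_init <- function(k, Cx, Ch) {
  fan_in <- k * k * (Cx + Ch)
  W <- matrix(stats::rnorm(fan_in * 4 * Ch, sd = sqrt(1 / fan_in)),
              fan_in, 4 * Ch)
  b <- rep(0, 4 * Ch)
  b[Ch + seq_len(Ch)] <- 1  # forget-gate bias starts open
  list(W = W, b = b)
}

clstm_fwd <- function(x, h, c, W, b, k) {
  Ch <- dim(h)[4]
  xh <- abind4(x, h)
  cf <- conv_fwd(xh, W, b, k, 1L, (k - 1L) %/% 2L)
  z <- cf$out
  gi <- sigmoid(z[, , , seq_len(Ch), drop = FALSE])
  gf <- sigmoid(z[, , , Ch + seq_len(Ch), drop = FALSE])
  go <- sigmoid(z[, , , 2L * Ch + seq_len(Ch), drop = FALSE])
  gg <- tanh(z[, , , 3L * Ch + seq_len(Ch), drop = FALSE])
  c1 <- gf * c + gi * gg
  tc1 <- tanh(c1)
  h1 <- go * tc1
  list(h = h1, c = c1,
       cache = list(conv = cf$cache, gi = gi, gf = gf, go = go, gg = gg,
                    c0 = c, tc1 = tc1, Cx = dim(x)[4], Ch = Ch))
}

clstm_bwd <- function(dh1, dc1, cache, W) {
  Ch <- cache$Ch
  dgo <- dh1 * cache$tc1
  dtc <- dh1 * cache$go * (1 - cache$tc1^2) + dc1
  dgf <- dtc * cache$c0
  dc0 <- dtc * cache$gf
  dgi <- dtc * cache$gg
  dgg <- dtc * cache$gi
  dz <- abind4(dgi * cache$gi * (1 - cache$gi),
               dgf * cache$gf * (1 - cache$gf),
               dgo * cache$go * (1 - cache$go),
               dgg * (1 - cache$gg^2))
  cb <- conv_bwd(dz, cache$conv, W, need_dx = TRUE)
  dxh <- cb$dX
  list(dx = dxh[, , , seq_len(cache$Cx), drop = FALSE],
       dh0 = dxh[, , , cache$Cx + seq_len(Ch), drop = FALSE],
       dc0 = dc0, dW = cb$dW, db = cb$db)
}

dense_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}
dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

conv_init <- function(k, Cin, Cout, gain = 2) {
  fan_in <- k * k * Cin
  matrix(stats::rnorm(fan_in * Cout, sd = sqrt(gain / fan_in)), fan_in, Cout)
}

tconv_init <- function(k, Cin, Cout, gain = 2) {
  fan_in <- k * k * Cin / 4   # effective fan-in per output pixel at stride 2
  matrix(stats::rnorm(Cin * k * k * Cout, sd = sqrt(gain / fan_in)),
         Cin, k * k * Cout)
}

# Adam with additive L2 on weight matrices (names ending "_W")
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && grepl("_W$", nm)) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate a gradient list into a running total
grad_acc <- function(total, g) {
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  }
  total
}
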