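# The network engine is hand-rolled, so every primitive's backward pass is
# checked against central finite differences on small random problems.

test_that("convolution forward/backward match finite differences", {
  set.seed(42)
  cases <- list(list(hw = 5L, cin = 2L, cout = 3L, k = 3L, s = 1L, p = 1L),
                list(hw = 8L, cin = 2L, cout = 2L, k = 6L, s = 2L, p = 2L))
  for (cs in cases) {
    X <- array(rnorm(cs$hw^2 * 2 * cs$cin), c(cs$hw, cs$hw, 2L, cs$cin))
    Wm <- epmodkit:::conv_init(cs$k, cs$cin, cs$cout)
    b <- rnorm(cs$cout)
    cf <- epmodkit:::conv_fwd(X, Wm, b, cs$k, cs$s, cs$p)
    tgt <- array(rnorm(length(cf$out)), dim(cf$out))
    loss <- function(Xv, Wv, bv) {
      f <- epmodkit:::conv_fwd(array(Xv, dim(X)), matrix(Wv, nrow(Wm)), bv,
                               cs$k, cs$s, cs$p)
      sum((f$out - tgt)^2) / 2
    }
    cb <- epmodkit:::conv_bwd(cf$out - tgt, cf$cache, Wm)
    expect_close(cb$dX, array(num_grad(function(v) loss(v, Wm, b),
                                       as.vector(X)), dim(X)), 1e-6)
    expect_close(cb$dW, matrix(num_grad(function(v) loss(X, v, b),
                                        as.vector(Wm)), nrow(Wm)), 1e-6)
    expect_close(cb$db, num_grad(function(v) loss(X, Wm, v), b), 1e-6)
  }
})

test_that("transposed convolution doubles resolution and back-propagates
           exactly", {
  set.seed(1)
  X <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  Wt <- epmodkit:::tconv_init(4L, 2L, 3L)
  b <- rnorm(3)
  tf <- epmodkit:::tconv_fwd(X, Wt, b, 4L, 2L, 1L)
  expect_identical(dim(tf$out), c(6L, 6L, 2L, 3L))
  tgt <- array(rnorm(length(tf$out)), dim(tf$out))
  loss <- function(Xv, Wv, bv) {
    f <- epmodkit:::tconv_fwd(array(Xv, dim(X)), matrix(Wv, nrow(Wt)), bv,
                              4L, 2L, 1L)
    sum((f$out - tgt)^2) / 2
  }
  tb <- epmodkit:::tconv_bwd(tf$out - tgt, tf$cache, Wt)
  expect_close(tb$dX, array(num_grad(function(v) loss(v, Wt, b),
                                     as.vector(X)), dim(X)), 1e-6)
  expect_close(tb$dW, matrix(num_grad(function(v) loss(X, v, b),
                                      as.vector(Wt)), nrow(Wt)), 1e-6)
  expect_close(tb$db, num_grad(function(v) loss(X, Wt, v), b), 1e-6)
})

test_that("max-pooling and batch-norm gradients are exact", {
  set.seed(2)
  X <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  mf <- epmodkit:::maxpool_fwd(X)
  tgt <- array(rnorm(length(mf$out)), dim(mf$out))
  lp <- function(Xv) {
    f <- epmodkit:::maxpool_fwd(array(Xv, dim(X)))
    sum((f$out - tgt)^2) / 2
  }
  expect_close(epmodkit:::maxpool_bwd(mf$out - tgt, mf$cache),
               array(num_grad(lp, as.vector(X)), dim(X)), 1e-6)

  Xb <- array(rnorm(4 * 4 * 3 * 3), c(4, 4, 3, 3))
  bn <- list(gamma = runif(3, 0.5, 1.5), beta = rnorm(3),
             rmean = rep(0, 3), rvar = rep(1, 3))
  bf <- epmodkit:::bn_fwd(Xb, bn, train = TRUE)
  tb <- array(rnorm(length(Xb)), dim(Xb))
  lb <- function(Xv, gv, bv) {
    bnl <- bn; bnl$gamma <- gv; bnl$beta <- bv
    f <- epmodkit:::bn_fwd(array(Xv, dim(Xb)), bnl, train = TRUE)
    sum((f$out - tb)^2) / 2
  }
  bb <- epmodkit:::bn_bwd(bf$out - tb, bf$cache, bn)
  expect_close(bb$dX, array(num_grad(function(v) lb(v, bn$gamma, bn$beta),
                                     as.vector(Xb)), dim(Xb)), 1e-6)
  expect_close(bb$dgamma,
               num_grad(function(v) lb(Xb, v, bn$beta), bn$gamma), 1e-6)
  expect_close(bb$dbeta,
               num_grad(function(v) lb(Xb, bn$gamma, v), bn$beta), 1e-6)
})

test_that("the ConvLSTM cell back-propagates through state, input and
           weights", {
  set.seed(3)
  Cx <- 2L; Ch <- 3L; k <- 3L
  x <- array(rnorm(4 * 4 * 2 * Cx), c(4, 4, 2, Cx))
  h <- array(rnorm(4 * 4 * 2 * Ch), c(4, 4, 2, Ch))
  cc <- array(rnorm(4 * 4 * 2 * Ch), c(4, 4, 2, Ch))
  ini <- epmodkit:::clstm_init(k, Cx, Ch)
  s <- epmodkit:::clstm_fwd(x, h, cc, ini$W, ini$b, k)
  th <- array(rnorm(length(s$h)), dim(s$h))
  loss <- function(xv, hv, cv, Wv, bv) {
    st <- epmodkit:::clstm_fwd(array(xv, dim(x)), array(hv, dim(h)),
                               array(cv, dim(cc)), matrix(Wv, nrow(ini$W)),
                               bv, k)
    sum((st$h - th)^2) / 2 + sum(st$c^3) / 6
  }
  sb <- epmodkit:::clstm_bwd(s$h - th, s$c^2 / 2, s$cache, ini$W)
  expect_close(sb$dx, array(num_grad(function(v)
    loss(v, h, cc, ini$W, ini$b), as.vector(x)), dim(x)), 1e-6)
  expect_close(sb$dh0, array(num_grad(function(v)
    loss(x, v, cc, ini$W, ini$b), as.vector(h)), dim(h)), 1e-6)
  expect_close(sb$dc0, array(num_grad(function(v)
    loss(x, h, v, ini$W, ini$b), as.vector(cc)), dim(cc)), 1e-6)
  expect_close(sb$dW, matrix(num_grad(function(v)
    loss(x, h, cc, v, ini$b), as.vector(ini$W)), nrow(ini$W)), 1e-6)
  expect_close(sb$db, num_grad(function(v)
    loss(x, h, cc, ini$W, v), ini$b), 1e-6)
})

test_that("Adam descends a convex quadratic deterministically", {
  params <- list(w_W = matrix(c(3, -2), 1))
  st <- epmodkit:::adam_init(params)
  for (i in 1:300) {
    g <- list(w_W = 2 * params$w_W)
    up <- epmodkit:::adam_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(max(abs(params$w_W)), 1e-2)
})
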