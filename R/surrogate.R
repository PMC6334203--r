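#' Configuration for the convolutional-recurrent forecasting network
#'
#' The surrogate consumes `kb` sequential frames of the diffusing field,
#' encodes each through a three-layer convolutional encoder (each layer:
#' convolution, batch normalisation, ReLU, 2x2 max-pool, so the latent grid
#' is 1/8 of the input per side), advances the latent state through a
#' convolutional LSTM, and decodes each rollout step back to full resolution
#' through three stride-2 transposed convolutions (the last one linear, since
#' field values are signed). Training back-propagates the mean squared error
#' of the first `kt` predicted frames only; at evaluation time the cell
#' free-runs for `k_out` steps.
#'
#' @param kb Input frame count (2 or 3).
#' @param kt Number of back-propagated target frames (1-7).
#' @param k_out Rollout length (default 11).
#' @param input_size Frame side length; must be divisible by 8 (default 64).
#' @param enc_channels,enc_filter Encoder channels (default 64, 32, 32) and
#'   filter size (default 5).
#' @param lstm_channels,lstm_filter ConvLSTM hidden channels (default 32) and
#'   filter size (default 5, odd).
#' @param dec_channels,dec_filter Hidden decoder channels (default 32, 64)
#'   and filter size (default 4); the final stride-2 layer emits one channel
#'   per decoded frame.
#' @param lr0,lr_drop_epoch,lr_drop_factor Learning-rate schedule: start at
#'   `lr0` (default 5e-4), divide by `lr_drop_factor` after `lr_drop_epoch`.
#' @param epochs,batch Training epochs (default 1000) and batch size (64).
#' @param weight_decay L2 penalty on weight matrices (default 1e-5).
#' @param folds,val_frac Cross-validation folds (5) and validation fraction
#'   of the training split (0.2).
#' @param seed Default seed for weight initialisation and batching.
#' @param teacher_forcing If `TRUE`, the recurrent cell receives the encoded
#'   ground-truth previous frame at each training rollout step instead of
#'   free-running (no gradient flows through the teacher encoding).
#' @param latent_state Which recurrent activity [extract_latents()] captures.
#' @param nmse_denominator `"meansq"` (mean-square of the target frame,
#'   dimensionless NMSE; default) or `"norm"` (literal L2 norm).
#' @return An object of class `epk_surrogate_config`.
#' @export
surrogate_config <- function(kb = 3L, kt = 4L, k_out = 11L, input_size = 64L,
                             enc_channels = c(64L, 32L, 32L), enc_filter = 5L,
                             lstm_channels = 32L, lstm_filter = 5L,
                             dec_channels = c(32L, 64L), dec_filter = 4L,
                             lr0 = 5e-4, lr_drop_epoch = 700L,
                             lr_drop_factor = 10, epochs = 1000L,
                             batch = 64L, weight_decay = 1e-5,
                             folds = 5L, val_frac = 0.2, seed = 1L,
                             teacher_forcing = FALSE,
                             latent_state = c("hidden", "cell"),
                             nmse_denominator = c("meansq", "norm")) {
  kb <- as.integer(kb); kt <- as.integer(kt); k_out <- as.integer(k_out)
  if (!kb %in% c(2L, 3L)) stop("kb must be 2 or 3", call. = FALSE)
  if (kt < 1L || kt > 7L) stop("kt must be between 1 and 7", call. = FALSE)
  if (k_out < 7L) stop("k_out must be >= 7", call. = FALSE)
  input_size <- as.integer(input_size)
  if (input_size %% 8L != 0L) stop("input_size must be divisible by 8",
                                   call. = FALSE)
  if (lstm_filter %% 2L == 0L) stop("lstm_filter must be odd", call. = FALSE)
  if (length(enc_channels) != 3L || length(dec_channels) != 2L) {
    stop("encoder takes 3 channel counts, decoder 2 hidden ones",
         call. = FALSE)
  }
  structure(list(kb = kb, kt = kt, k_out = k_out, input_size = input_size,
                 enc_channels = as.integer(enc_channels),
                 enc_filter = as.integer(enc_filter),
                 lstm_channels = as.integer(lstm_channels),
                 lstm_filter = as.integer(lstm_filter),
                 dec_channels = as.integer(dec_channels),
                 dec_filter = as.integer(dec_filter),
                 lr0 = lr0, lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_drop_factor = lr_drop_factor,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 weight_decay = weight_decay, folds = as.integer(folds),
                 val_frac = val_frac, seed = as.integer(seed),
                 teacher_forcing = isTRUE(teacher_forcing),
                 latent_state = match.arg(latent_state),
                 nmse_denominator = match.arg(nmse_denominator)),
            class = "epk_surrogate_config")
}

#' Build an untrained surrogate model
#'
#' @param config An `epk_surrogate_config`.
#' @param seed Seed for weight initialisation (defaults to `config$seed`).
#' @return An object of class `epk_surrogate`.
#' @export
build_surrogate <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "epk_surrogate_config"))
  e <- config$enc_channels; d <- config$dec_channels
  f <- config$enc_filter; lf <- config$lstm_filter; df <- config$dec_filter
  ch <- config$lstm_channels
  params <- with_seed_if(seed, {
    lstm <- clstm_init(lf, e[3], ch)
    list(
      enc1_W = conv_init(f, 1L, e[1]), enc1_b = rep(0, e[1]),
      bn1_gamma = rep(1, e[1]), bn1_beta = rep(0, e[1]),
      enc2_W = conv_init(f, e[1], e[2]), enc2_b = rep(0, e[2]),
      bn2_gamma = rep(1, e[2]), bn2_beta = rep(0, e[2]),
      enc3_W = conv_init(f, e[2], e[3]), enc3_b = rep(0, e[3]),
      bn3_gamma = rep(1, e[3]), bn3_beta = rep(0, e[3]),
      lstm_W = lstm$W, lstm_b = lstm$b,
      dec1_W = tconv_init(df, ch, d[1]), dec1_b = rep(0, d[1]),
      bnd1_gamma = rep(1, d[1]), bnd1_beta = rep(0, d[1]),
      dec2_W = tconv_init(df, d[1], d[2]), dec2_b = rep(0, d[2]),
      bnd2_gamma = rep(1, d[2]), bnd2_beta = rep(0, d[2]),
      dec3_W = tconv_init(df, d[2], 1L, gain = 1), dec3_b = 0
    )
  })
  bn_run <- list(bn1 = list(rmean = rep(0, e[1]), rvar = rep(1, e[1])),
                 bn2 = list(rmean = rep(0, e[2]), rvar = rep(1, e[2])),
                 bn3 = list(rmean = rep(0, e[3]), rvar = rep(1, e[3])),
                 bnd1 = list(rmean = rep(0, d[1]), rvar = rep(1, d[1])),
                 bnd2 = list(rmean = rep(0, d[2]), rvar = rep(1, d[2])))
  structure(list(params = params, bn_run = bn_run, config = config,
                 scale = 1, train_log = NULL),
            class = "epk_surrogate")
}

bn_of <- function(params, bn_run, name) {
  list(gamma = params[[paste0(name, "_gamma")]],
       beta = params[[paste0(name, "_beta")]],
       rmean = bn_run[[name]]$rmean, rvar = bn_run[[name]]$rvar)
}

# encoder for one frame (H, W, N, 1) -> (H/8, W/8, N, e3)
encoder_fwd <- function(x, params, bn_run, cfg, train) {
  f <- cfg$enc_filter; pad <- (f - 1L) %/% 2L
  cache <- list()
  cur <- x
  for (l in 1:3) {
    cv <- conv_fwd(cur, params[[paste0("enc", l, "_W")]],
                   params[[paste0("enc", l, "_b")]], f, 1L, pad)
    bnm <- paste0("bn", l)
    bf <- bn_fwd(cv$out, bn_of(params, bn_run, bnm), train)
    bn_run[[bnm]]$rmean <- bf$bn$rmean
    bn_run[[bnm]]$rvar <- bf$bn$rvar
    rl <- relu_fwd(bf$out)
    mp <- maxpool_fwd(rl$out)
    cache[[l]] <- list(conv = cv$cache, bn = bf$cache, relu = rl$cache,
                       pool = mp$cache)
    cur <- mp$out
  }
  list(out = cur, cache = cache, bn_run = bn_run)
}

encoder_bwd <- function(de, cache, params, cfg) {
  grads <- list()
  cur <- de
  for (l in 3:1) {
    cur <- maxpool_bwd(cur, cache[[l]]$pool)
    cur <- relu_bwd(cur, cache[[l]]$relu)
    bnm <- paste0("bn", l)
    bb <- bn_bwd(cur, cache[[l]]$bn, bn_of(params, list(), bnm))
    grads[[paste0(bnm, "_gamma")]] <- bb$dgamma
    grads[[paste0(bnm, "_beta")]] <- bb$dbeta
    cb <- conv_bwd(bb$dX, cache[[l]]$conv,
                   params[[paste0("enc", l, "_W")]], need_dx = (l > 1L))
    grads[[paste0("enc", l, "_W")]] <- cb$dW
    grads[[paste0("enc", l, "_b")]] <- cb$db
    cur <- cb$dX
  }
  grads
}

decoder_fwd <- function(h, params, bn_run, cfg, train) {
  df <- cfg$dec_filter
  t1 <- tconv_fwd(h, params$dec1_W, params$dec1_b, df, 2L, 1L)
  b1 <- bn_fwd(t1$out, bn_of(params, bn_run, "bnd1"), train)
  bn_run$bnd1$rmean <- b1$bn$rmean; bn_run$bnd1$rvar <- b1$bn$rvar
  r1 <- relu_fwd(b1$out)
  t2 <- tconv_fwd(r1$out, params$dec2_W, params$dec2_b, df, 2L, 1L)
  b2 <- bn_fwd(t2$out, bn_of(params, bn_run, "bnd2"), train)
  bn_run$bnd2$rmean <- b2$bn$rmean; bn_run$bnd2$rvar <- b2$bn$rvar
  r2 <- relu_fwd(b2$out)
  t3 <- tconv_fwd(r2$out, params$dec3_W, params$dec3_b, df, 2L, 1L)
  list(out = t3$out,
       cache = list(t1 = t1$cache, b1 = b1$cache, r1 = r1$cache,
                    t2 = t2$cache, b2 = b2$cache, r2 = r2$cache,
                    t3 = t3$cache),
       bn_run = bn_run)
}

decoder_bwd <- function(dy, cache, params, cfg) {
  grads <- list()
  tb3 <- tconv_bwd(dy, cache$t3, params$dec3_W)
  grads$dec3_W <- tb3$dW; grads$dec3_b <- tb3$db
  cur <- relu_bwd(tb3$dX, cache$r2)
  bb2 <- bn_bwd(cur, cache$b2, bn_of(params, list(), "bnd2"))
  grads$bnd2_gamma <- bb2$dgamma; grads$bnd2_beta <- bb2$dbeta
  tb2 <- tconv_bwd(bb2$dX, cache$t2, params$dec2_W)
  grads$dec2_W <- tb2$dW; grads$dec2_b <- tb2$db
  cur <- relu_bwd(tb2$dX, cache$r1)
  bb1 <- bn_bwd(cur, cache$b1, bn_of(params, list(), "bnd1"))
  grads$bnd1_gamma <- bb1$dgamma; grads$bnd1_beta <- bb1$dbeta
  tb1 <- tconv_bwd(bb1$dX, cache$t1, params$dec1_W)
  grads$dec1_W <- tb1$dW; grads$dec1_b <- tb1$db
  list(grads = grads, dh = tb1$dX)
}

# Full forward pass on standardised inputs.
# X: (H, W, N, kb); decodes the first n_dec of n_pred rollout steps.
surrogate_forward <- function(params, bn_run, cfg, X, n_pred, n_dec,
                              train = FALSE, keep_caches = FALSE,
                              teacher = NULL) {
  d <- dim(X)
  H <- d[1]; N <- d[3]
  hh <- H %/% 8L
  ch <- cfg$lstm_channels
  e3 <- cfg$enc_channels[3]
  enc_caches <- vector("list", cfg$kb)
  enc_out <- vector("list", cfg$kb)
  for (t in seq_len(cfg$kb)) {
    ef <- encoder_fwd(X[, , , t, drop = FALSE], params, bn_run, cfg, train)
    bn_run <- ef$bn_run
    enc_out[[t]] <- ef$out
    if (keep_caches) enc_caches[[t]] <- ef$cache
  }
  h <- array(0, c(hh, hh, N, ch))
  cc <- array(0, c(hh, hh, N, ch))
  lstm_caches <- vector("list", cfg$kb + n_pred)
  for (t in seq_len(cfg$kb)) {
    st <- clstm_fwd(enc_out[[t]], h, cc, params$lstm_W, params$lstm_b,
                    cfg$lstm_filter)
    h <- st$h; cc <- st$c
    if (keep_caches) lstm_caches[[t]] <- st$cache
  }
  zero_in <- array(0, c(hh, hh, N, e3))
  preds <- array(0, c(H, H, N, n_dec))
  hs <- vector("list", n_pred)
  dec_caches <- vector("list", n_dec)
  for (r in seq_len(n_pred)) {
    # teacher forcing feeds the ground truth of the *previous* step
    xin <- if (!is.null(teacher) && r > 1L && (r - 1L) <= dim(teacher)[4]) {
      ef <- encoder_fwd(teacher[, , , r - 1L, drop = FALSE], params, bn_run,
                        cfg, train)
      bn_run <- ef$bn_run
      ef$out
    } else zero_in
    st <- clstm_fwd(xin, h, cc, params$lstm_W, params$lstm_b,
                    cfg$lstm_filter)
    h <- st$h; cc <- st$c
    hs[[r]] <- if (cfg$latent_state == "hidden") h else cc
    if (keep_caches) lstm_caches[[cfg$kb + r]] <- st$cache
    if (r <= n_dec) {
      dfw <- decoder_fwd(h, params, bn_run, cfg, train)
      bn_run <- dfw$bn_run
      preds[, , , r] <- dfw$out[, , , 1]
      if (keep_caches) dec_caches[[r]] <- dfw$cache
    }
  }
  list(preds = preds, hs = hs, bn_run = bn_run,
       caches = if (keep_caches) list(enc = enc_caches, lstm = lstm_caches,
                                      dec = dec_caches),
       dims = list(H = H, N = N, n_pred = n_pred, n_dec = n_dec))
}

# backward pass for the mean-squared error over the decoded frames
surrogate_bwd <- function(fw, targets, params, cfg) {
  dims <- fw$dims
  H <- dims$H; N <- dims$N; n_dec <- dims$n_dec
  numel <- length(targets)
  grads <- list()
  dh_dec <- vector("list", n_dec)
  for (r in n_dec:1) {
    dy <- (2 / numel) * (fw$preds[, , , r] - targets[, , , r])
    dim(dy) <- c(H, H, N, 1L)
    db <- decoder_bwd(dy, fw$caches$dec[[r]], params, cfg)
    grads <- grad_acc(grads, db$grads)
    dh_dec[[r]] <- db$dh
  }
  hh <- H %/% 8L
  ch <- cfg$lstm_channels
  dh <- array(0, c(hh, hh, N, ch))
  dc <- array(0, c(hh, hh, N, ch))
  for (r in dims$n_pred:1) {
    if (r <= n_dec) dh <- dh + dh_dec[[r]]
    lb <- clstm_bwd(dh, dc, fw$caches$lstm[[cfg$kb + r]], params$lstm_W)
    grads <- grad_acc(grads, list(lstm_W = lb$dW, lstm_b = lb$db))
    dh <- lb$dh0; dc <- lb$dc0
  }
  for (t in cfg$kb:1) {
    lb <- clstm_bwd(dh, dc, fw$caches$lstm[[t]], params$lstm_W)
    grads <- grad_acc(grads, list(lstm_W = lb$dW, lstm_b = lb$db))
    dh <- lb$dh0; dc <- lb$dc0
    ge <- encoder_bwd(lb$dx, fw$caches$enc[[t]], params, cfg)
    grads <- grad_acc(grads, ge)
  }
  grads
}

# pull (inputs, targets) arrays -- layout (H, W, n_sims, frames) -- out of an
# archive produced by batch_simulate
archive_tensors <- function(sims, cfg, n_target = cfg$k_out) {
  n <- length(sims)
  H <- dim(sims[[1]]$frames)[1]
  nf <- dim(sims[[1]]$frames)[3]
  if (nf < cfg$kb + n_target) {
    stop(sprintf("archive frames (%d) < kb + horizon (%d)", nf,
                 cfg$kb + n_target), call. = FALSE)
  }
  X <- array(0, c(H, H, n, cfg$kb))
  Y <- array(0, c(H, H, n, n_target))
  for (i in seq_len(n)) {
    X[, , i, ] <- sims[[i]]$frames[, , seq_len(cfg$kb)]
    Y[, , i, ] <- sims[[i]]$frames[, , cfg$kb + seq_len(n_target)]
  }
  list(X = X, Y = Y)
}

#' Train the surrogate on a simulation archive
#'
#' Minimises the MSE of the first `kt` predicted frames with Adam, weight
#' decay and the configured learning-rate schedule. A fraction `val_frac` of
#' the training simulations is set aside for validation and the returned
#' model carries the weights of the epoch with the best validation loss.
#' Inputs are standardised by the global standard deviation of the training
#' frames; the inverse transform is applied before any metric is computed.
#'
#' @param archive Archive from [batch_simulate()] (or any list with `sims`).
#' @param config An `epk_surrogate_config`.
#' @param seed Seed controlling initialisation, the validation split and
#'   batch order (defaults to `config$seed`).
#' @param verbose Print per-epoch losses.
#' @return A trained `epk_surrogate` with a `train_log` data frame.
#' @export
train_surrogate <- function(archive, config, seed = config$seed,
                            verbose = FALSE) {
  sims <- archive$sims
  n <- length(sims)
  if (n < 2L) stop("need at least 2 simulations", call. = FALSE)
  dt <- archive_tensors(sims, config, n_target = config$kt)
  scale <- stats::sd(c(dt$X, dt$Y))
  if (!is.finite(scale) || scale == 0) scale <- 1   # degenerate archives
  X <- dt$X / scale
  Y <- dt$Y / scale
  model <- build_surrogate(config, seed = derive_seed(seed, "init"))
  model$scale <- scale
  opt <- adam_init(model$params)
  n_val <- max(1L, floor(config$val_frac * n))
  ord <- with_seed_if(derive_seed(seed, "split"), sample.int(n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  if (length(tr_idx) < 1L) stop("no training simulations left", call. = FALSE)
  best_val <- Inf
  best <- NULL
  log <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr0 /
      if (ep > config$lr_drop_epoch) config$lr_drop_factor else 1
    border <- with_seed_if(derive_seed(seed, paste0("epoch", ep)),
                           sample(tr_idx))
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, length(border), by = config$batch)) {
      bi <- border[b0:min(b0 + config$batch - 1L, length(border))]
      Xb <- X[, , bi, , drop = FALSE]
      Yb <- Y[, , bi, , drop = FALSE]
      fw <- surrogate_forward(model$params, model$bn_run, config, Xb,
                              n_pred = config$kt, n_dec = config$kt,
                              train = TRUE, keep_caches = TRUE,
                              teacher = if (config$teacher_forcing) Yb)
      model$bn_run <- fw$bn_run
      loss <- mean((fw$preds - Yb)^2)
      if (!is.finite(loss)) {
        stop(sprintf("divergent training loss at epoch %d", ep),
             call. = FALSE)
      }
      grads <- surrogate_bwd(fw, Yb, model$params, config)
      upd <- adam_step(model$params, grads, opt, lr, config$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
    }
    vl <- surrogate_loss(model, X[, , val_idx, , drop = FALSE],
                         Y[, , val_idx, , drop = FALSE])
    if (vl < best_val) {
      best_val <- vl
      best <- list(params = model$params, bn_run = model$bn_run)
    }
    log[[ep]] <- c(epoch = ep, train_loss = ep_loss / nb, val_loss = vl,
                   lr = lr)
    if (verbose) {
      message(sprintf("epoch %4d  train %.5g  val %.5g", ep, ep_loss / nb, vl))
    }
  }
  model$params <- best$params
  model$bn_run <- best$bn_run
  model$train_log <- as.data.frame(do.call(rbind, log))
  model$val_idx <- val_idx
  model
}

# evaluation-mode loss over the first kt frames (standardised scale)
surrogate_loss <- function(model, X, Y, chunk = 16L) {
  cfg <- model$config
  n <- dim(X)[3]
  tot <- 0
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    fw <- surrogate_forward(model$params, model$bn_run, cfg,
                            X[, , bi, , drop = FALSE],
                            n_pred = cfg$kt, n_dec = cfg$kt, train = FALSE)
    tot <- tot + sum((fw$preds - Y[, , bi, , drop = FALSE])^2)
  }
  tot / length(Y)
}

# internal: standardised rollout on (H, W, N, kb) input
rollout_internal <- function(model, Xint, n_pred, n_dec = n_pred) {
  surrogate_forward(model$params, model$bn_run, model$config,
                    Xint / model$scale, n_pred = n_pred, n_dec = n_dec,
                    train = FALSE)
}

#' Roll the trained surrogate forward
#'
#' @param model A trained `epk_surrogate`.
#' @param inputs `kb` input frames: array (H, W, kb) for one simulation or
#'   (H, W, kb, N) for a batch.
#' @param k_out Number of predicted frames (default `config$k_out`).
#' @return Array (H, W, k_out) or (H, W, k_out, N) of predicted frames on the
#'   original scale.
#' @export
predict_rollout <- function(model, inputs, k_out = model$config$k_out) {
  stopifnot(inherits(model, "epk_surrogate"))
  cfg <- model$config
  single <- length(dim(inputs)) == 3L
  if (single) dim(inputs) <- c(dim(inputs), 1L)
  d <- dim(inputs)
  if (d[3] != cfg$kb || d[1] != cfg$input_size) {
    stop(sprintf("expected %d frames of side %d, got %d of side %d",
                 cfg$kb, cfg$input_size, d[3], d[1]), call. = FALSE)
  }
  fw <- rollout_internal(model, aperm(inputs, c(1, 2, 4, 3)), k_out)
  out <- aperm(fw$preds, c(1, 2, 4, 3)) * model$scale
  if (!all(is.finite(out))) stop("non-finite prediction", call. = FALSE)
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Capture the recurrent activity over a full rollout
#'
#' Runs the surrogate on `kb` input frames and returns the ConvLSTM activity
#' (hidden state by default, see `latent_state` in [surrogate_config()]) at
#' each of the `k_out` rollout steps, concatenated along the channel axis.
#'
#' @param model A trained `epk_surrogate`.
#' @param inputs Array (H, W, kb) or (H, W, kb, N).
#' @return Array (H/8, W/8, k_out * lstm_channels, N).
#' @export
extract_latents <- function(model, inputs) {
  stopifnot(inherits(model, "epk_surrogate"))
  cfg <- model$config
  if (length(dim(inputs)) == 3L) dim(inputs) <- c(dim(inputs), 1L)
  fw <- rollout_internal(model, aperm(inputs, c(1, 2, 4, 3)), cfg$k_out,
                         n_dec = 0L)
  aperm(do.call(abind4, fw$hs), c(1, 2, 4, 3))
}

#' Evaluate a surrogate against held-out simulations
#'
#' Computes the per-simulation MSE over all `k_out` predicted frames, the
#' matching last-input-baseline MSE (the final observed frame repeated as
#' every prediction), the per-step normalised MSE, and a two-sided Wilcoxon
#' signed-rank test on the paired per-simulation MSEs.
#'
#' @param model A trained `epk_surrogate`.
#' @param sims List of simulations (elements with a `frames` array) or an
#'   archive with a `sims` element.
#' @param chunk Simulations per forward batch.
#' @return An object of class `epk_eval` with `mse_per_sim`,
#'   `baseline_mse_per_sim`, `nmse_per_step`, `wilcoxon_p`.
#' @export
evaluate_surrogate <- function(model, sims, chunk = 8L) {
  if (!is.null(sims$sims)) sims <- sims$sims
  n <- length(sims)
  if (n < 1L) stop("empty test set", call. = FALSE)
  cfg <- model$config
  dt <- archive_tensors(sims, cfg, n_target = cfg$k_out)
  mse <- numeric(n)
  bmse <- numeric(n)
  nmse_mat <- matrix(0, n, cfg$k_out)
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    fw <- rollout_internal(model, dt$X[, , bi, , drop = FALSE], cfg$k_out)
    pred <- fw$preds * model$scale
    for (j in seq_along(bi)) {
      i <- bi[j]
      targ <- dt$Y[, , i, ]
      perr <- (pred[, , j, ] - targ)^2
      berr <- (targ - c(dt$X[, , i, cfg$kb]))^2   # frame recycled over steps
      mse[i] <- mean(perr)
      bmse[i] <- mean(berr)
      for (r in seq_len(cfg$k_out)) {
        den <- if (cfg$nmse_denominator == "meansq") {
          mean(targ[, , r]^2)
        } else {
          sqrt(sum(targ[, , r]^2))
        }
        nmse_mat[i, r] <- mean(perr[, , r]) / den
      }
    }
  }
  wp <- stats::wilcox.test(mse, bmse, paired = TRUE,
                           alternative = "two.sided", exact = n < 50)$p.value
  structure(list(mse_per_sim = mse, baseline_mse_per_sim = bmse,
                 nmse_per_step = colMeans(nmse_mat), wilcoxon_p = wp),
            class = "epk_eval")
}

#' k-fold cross-validation of the surrogate
#'
#' Partitions the archive's simulations into `config$folds` folds; each fold
#' is held out in turn while the surrogate is trained on the remainder (with
#' its own validation split) and evaluated on the fold.
#'
#' @param archive Archive from [batch_simulate()].
#' @param config An `epk_surrogate_config`.
#' @param seed Master seed for fold assignment and per-fold training.
#' @return List with `folds` (per-fold `epk_eval`), `fold_assignment`, and
#'   `aggregate_mse` (fold-size-weighted mean of fold MSEs).
#' @export
crossvalidate_surrogate <- function(archive, config, seed = config$seed) {
  sims <- archive$sims
  n <- length(sims)
  k <- config$folds
  if (n < k) stop("fewer simulations than folds", call. = FALSE)
  fold <- with_seed_if(derive_seed(seed, "folds"),
                       sample(rep(seq_len(k), length.out = n)))
  evals <- vector("list", k)
  for (f in seq_len(k)) {
    m <- train_surrogate(list(sims = sims[fold != f]), config,
                         seed = derive_seed(seed, paste0("fold", f)))
    evals[[f]] <- evaluate_surrogate(m, sims[fold == f])
  }
  sizes <- tabulate(fold, k)
  agg <- sum(vapply(evals, function(e) mean(e$mse_per_sim), 0) * sizes) /
    sum(sizes)
  list(folds = evals, fold_assignment = fold, aggregate_mse = agg)
}

#' @export
print.epk_surrogate <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, 0))
  cat(sprintf(
    "<epk_surrogate> %dx%d frames, kb=%d kt=%d k_out=%d, %s parameters%s\n",
    cfg$input_size, cfg$input_size, cfg$kb, cfg$kt, cfg$k_out,
    format(np, big.mark = ","),
    if (is.null(x$train_log)) " (untrained)" else ""))
  invisible(x)
}
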