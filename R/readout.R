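#' Configuration for the parameter-readout network
#'
#' A small convolutional regressor that maps the surrogate's recurrent
#' activity (all rollout steps concatenated along channels, on the 8x8
#' latent grid) to the six scenario parameters `d0`, `d1`, `d0_scar`,
#' `d1_scar`, `theta`, `beta`. Two strided convolutions are followed by one
#' fully connected linear layer. The boundary orientation is axial (defined
#' modulo pi), so internally `theta` is regressed as `(sin 2*theta,
#' cos 2*theta)` and mapped back before any correlation is computed; the
#' remaining targets are standardised on the training split.
#'
#' @param conv_channels Channels of the two convolutions (default 128, 64).
#' @param conv_filter,conv_stride Filter size (6) and stride (2).
#' @param lr,epochs,batch,weight_decay Training hyper-parameters.
#' @param val_frac Fraction of pairs used for validation-based model choice.
#' @param seed Default seed.
#' @return An object of class `epk_readout_config`.
#' @export
readout_config <- function(conv_channels = c(128L, 64L), conv_filter = 6L,
                           conv_stride = 2L, lr = 1e-3, epochs = 60L,
                           batch = 16L, weight_decay = 1e-4,
                           val_frac = 0.2, seed = 1L) {
  if (length(conv_channels) != 2L) stop("exactly two convolutional layers",
                                        call. = FALSE)
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_filter = as.integer(conv_filter),
                 conv_stride = as.integer(conv_stride),
                 lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), weight_decay = weight_decay,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "epk_readout_config")
}

readout_target_names <- c("d0", "d1", "d0_scar", "d1_scar", "theta", "beta")

# scenarios -> raw target matrix (n x 6)
scenario_targets <- function(scenarios) {
  t(vapply(scenarios, function(s) {
    c(s$d0, s$d1, s$d0_scar, s$d1_scar, s$theta, s$beta)
  }, numeric(6)))
}

# internal 7-output encoding: 4 diffusivities + beta standardised,
# theta -> (sin 2t, cos 2t)
encode_targets <- function(raw, stats = NULL) {
  lin <- raw[, c(1:4, 6), drop = FALSE]
  if (is.null(stats)) {
    stats <- list(mu = colMeans(lin), sd = apply(lin, 2, stats::sd))
    stats$sd[stats$sd == 0] <- 1
  }
  linz <- sweep(sweep(lin, 2, stats$mu, "-"), 2, stats$sd, "/")
  cbind(linz, sin(2 * raw[, 5]), cos(2 * raw[, 5]))
}
decode_targets <- function(enc, stats) {
  lin <- sweep(sweep(enc[, 1:5, drop = FALSE], 2, stats$sd, "*"), 2,
               stats$mu, "+")
  theta <- atan2(enc[, 6], enc[, 7]) / 2
  theta <- theta %% pi
  cbind(lin[, 1:4, drop = FALSE], theta = theta, beta = lin[, 5])
}

readout_geometry <- function(cfg, hh) {
  k <- cfg$conv_filter; s <- cfg$conv_stride; p <- 2L
  o1 <- (hh + 2L * p - k) %/% s + 1L
  o2 <- (o1 + 2L * p - k) %/% s + 1L
  if (o2 < 1L || (hh + 2L * p - k) %% s != 0L || (o1 + 2L * p - k) %% s != 0L) {
    stop("latent grid incompatible with readout filter/stride", call. = FALSE)
  }
  list(p = p, o1 = o1, o2 = o2)
}

#' Build an untrained readout network
#'
#' @param config An `epk_readout_config`.
#' @param in_channels Latent channels (rollout steps x LSTM channels).
#' @param latent_hw Latent grid side (default 8).
#' @param seed Seed for initialisation.
#' @return An object of class `epk_readout`.
#' @export
build_readout <- function(config, in_channels, latent_hw = 8L,
                          seed = config$seed) {
  cc <- config$conv_channels
  k <- config$conv_filter
  geo <- readout_geometry(config, latent_hw)
  n_feat <- geo$o2^2 * cc[2]
  params <- with_seed_if(seed, list(
    conv1_W = conv_init(k, in_channels, cc[1]), conv1_b = rep(0, cc[1]),
    conv2_W = conv_init(k, cc[1], cc[2]), conv2_b = rep(0, cc[2]),
    fc_W = matrix(stats::rnorm(n_feat * 7, sd = sqrt(1 / n_feat)), n_feat, 7),
    fc_b = rep(0, 7)
  ))
  structure(list(params = params, config = config,
                 in_channels = in_channels, latent_hw = latent_hw,
                 target_stats = NULL, train_log = NULL),
            class = "epk_readout")
}

# latents in channel-last layout (hh, hh, N, C)
readout_fwd <- function(params, cfg, L, keep = FALSE) {
  k <- cfg$conv_filter; s <- cfg$conv_stride
  c1 <- conv_fwd(L, params$conv1_W, params$conv1_b, k, s, 2L)
  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1$out, params$conv2_W, params$conv2_b, k, s, 2L)
  r2 <- relu_fwd(c2$out)
  d <- dim(r2$out)
  # flatten to (N, features): features ordered (pixel, channel)
  Xf <- aperm(r2$out, c(1, 2, 4, 3))
  dim(Xf) <- c(d[1] * d[2] * d[4], d[3])
  fc <- dense_fwd(t(Xf), params$fc_W, params$fc_b)
  list(out = fc$out,
       cache = if (keep) list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                              r2 = r2$cache, fc = fc$cache, dr2 = d))
}

readout_bwd <- function(dY, cache, params, cfg) {
  grads <- list()
  fb <- dense_bwd(dY, cache$fc, params$fc_W)
  grads$fc_W <- fb$dW; grads$fc_b <- fb$db
  d <- cache$dr2
  dXf <- t(fb$dX)
  dim(dXf) <- c(d[1], d[2], d[4], d[3])
  cur <- aperm(dXf, c(1, 2, 4, 3))
  cur <- relu_bwd(cur, cache$r2)
  cb2 <- conv_bwd(cur, cache$c2, params$conv2_W)
  grads$conv2_W <- cb2$dW; grads$conv2_b <- cb2$db
  cur <- relu_bwd(cb2$dX, cache$r1)
  cb1 <- conv_bwd(cur, cache$c1, params$conv1_W, need_dx = FALSE)
  grads$conv1_W <- cb1$dW; grads$conv1_b <- cb1$db
  grads
}

# accept latents as (hh, hh, C, N) [public] and convert to channel-last
latents_internal <- function(latents) {
  if (length(dim(latents)) == 3L) dim(latents) <- c(dim(latents), 1L)
  aperm(latents, c(1, 2, 4, 3))
}

# per-channel mean/sd over (hh, hh, training samples)
latent_stats <- function(L, idx) {
  d <- dim(L)
  Lm <- matrix(L[, , idx, , drop = FALSE], ncol = d[4])
  mu <- colMeans(Lm)
  sd <- sqrt(colMeans(sweep(Lm, 2, mu, "-")^2))
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
standardise_latents <- function(L, stats) {
  d <- dim(L)
  nr <- prod(d[1:3])
  Lm <- L
  dim(Lm) <- c(nr, d[4])
  Lm <- (Lm - rep(stats$mu, each = nr)) * rep(1 / stats$sd, each = nr)
  dim(Lm) <- d
  Lm
}

#' Train the readout on latent/parameter pairs
#'
#' Minimises the MSE of the standardised targets (with the orientation
#' encoded as sine/cosine of the doubled angle) using Adam; the returned
#' model keeps the weights of the best validation epoch.
#'
#' @param latents Array (hh, hh, C, N) from [extract_latents()].
#' @param scenarios List of `epk_scenario` ground truths, length N.
#' @param config An `epk_readout_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @param verbose Print per-epoch losses.
#' @return A trained `epk_readout`.
#' @export
train_readout <- function(latents, scenarios, config = readout_config(),
                          seed = config$seed, verbose = FALSE) {
  L <- latents_internal(latents)
  n <- dim(L)[3]
  if (n != length(scenarios)) stop("latents and scenarios are not paired",
                                   call. = FALSE)
  raw <- scenario_targets(scenarios)
  model <- build_readout(config, in_channels = dim(L)[4],
                         latent_hw = dim(L)[1],
                         seed = derive_seed(seed, "init"))
  n_val <- max(1L, floor(config$val_frac * n))
  ord <- with_seed_if(derive_seed(seed, "split"), sample.int(n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  # standardise each latent channel on the training split
  lstats <- latent_stats(L, tr_idx)
  model$latent_stats <- lstats
  L <- standardise_latents(L, lstats)
  lin <- raw[tr_idx, c(1:4, 6), drop = FALSE]
  stats <- list(mu = colMeans(lin), sd = apply(lin, 2, stats::sd))
  stats$sd[stats$sd == 0] <- 1
  Yall <- encode_targets(raw, stats)
  opt <- adam_init(model$params)
  best_val <- Inf; best <- NULL
  log <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    border <- with_seed_if(derive_seed(seed, paste0("epoch", ep)),
                           sample(tr_idx))
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(border), by = config$batch)) {
      bi <- border[b0:min(b0 + config$batch - 1L, length(border))]
      fw <- readout_fwd(model$params, config, L[, , bi, , drop = FALSE],
                        keep = TRUE)
      err <- fw$out - Yall[bi, , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss)) stop("divergent readout loss", call. = FALSE)
      grads <- readout_bwd(2 * err / length(err), fw$cache, model$params,
                           config)
      upd <- adam_step(model$params, grads, opt, config$lr,
                       config$weight_decay)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    pv <- readout_fwd(model$params, config, L[, , val_idx, , drop = FALSE])
    vl <- mean((pv$out - Yall[val_idx, , drop = FALSE])^2)
    if (vl < best_val) { best_val <- vl; best <- model$params }
    log[[ep]] <- c(epoch = ep, train_loss = ep_loss / nb, val_loss = vl)
    if (verbose) message(sprintf("readout epoch %3d train %.4g val %.4g",
                                 ep, ep_loss / nb, vl))
  }
  model$params <- best
  model$target_stats <- stats
  model$train_log <- as.data.frame(do.call(rbind, log))
  model
}

#' Predict scenario parameters from latents
#'
#' @param model A trained `epk_readout`.
#' @param latents Array (hh, hh, C, N).
#' @return n x 6 matrix with columns `d0`, `d1`, `d0_scar`, `d1_scar`,
#'   `theta` (in `[0, pi)`), `beta`.
#' @export
predict_readout <- function(model, latents) {
  stopifnot(inherits(model, "epk_readout"))
  if (is.null(model$target_stats)) stop("readout is untrained", call. = FALSE)
  L <- latents_internal(latents)
  if (!is.null(model$latent_stats)) {
    L <- standardise_latents(L, model$latent_stats)
  }
  out <- readout_fwd(model$params, model$config, L)$out
  pred <- decode_targets(out, model$target_stats)
  colnames(pred) <- readout_target_names
  pred
}

#' Per-parameter correlation between predicted and true scenario parameters
#'
#' Pearson correlation for each of the six parameters. The orientation is
#' axial: the predicted angle is first unwrapped to the representative
#' (theta + k*pi) closest to the truth so that the correlation is not
#' destroyed by the wrap-around at 0/pi.
#'
#' @param model A trained `epk_readout`.
#' @param latents Array (hh, hh, C, N) of held-out latents.
#' @param scenarios Matching ground-truth scenarios.
#' @return List with `correlations` (named length-6 vector; `NA` when a
#'   truth has zero variance) and `scatter` (data frame of truth/prediction
#'   pairs for plotting).
#' @export
evaluate_readout <- function(model, latents, scenarios) {
  pred <- predict_readout(model, latents)
  truth <- scenario_targets(scenarios)
  colnames(truth) <- readout_target_names
  # axial unwrap of the predicted orientation
  cand <- sweep(outer(pred[, "theta"], c(-pi, 0, pi), "+"), 1,
                truth[, "theta"], "-")
  shift <- c(-pi, 0, pi)[apply(abs(cand), 1, which.min)]
  pred[, "theta"] <- pred[, "theta"] + shift
  cors <- vapply(seq_len(6), function(j) {
    if (stats::sd(truth[, j]) == 0 || stats::sd(pred[, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(truth[, j], pred[, j])
  }, 0)
  names(cors) <- readout_target_names
  scatter <- data.frame(
    parameter = rep(readout_target_names, each = nrow(pred)),
    truth = as.vector(truth), prediction = as.vector(pred))
  list(correlations = cors, scatter = scatter)
}
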