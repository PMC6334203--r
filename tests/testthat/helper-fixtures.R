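# Shared fixtures: everything is generated in code at test time.

# small surrogate configuration on 16x16 frames for fast training tests
tiny_surrogate_config <- function(...) {
  args <- utils::modifyList(
    list(kb = 2L, kt = 2L, k_out = 7L, input_size = 16L,
         enc_channels = c(6L, 4L, 4L), enc_filter = 3L,
         lstm_channels = 4L, lstm_filter = 3L,
         dec_channels = c(4L, 6L), dec_filter = 4L,
         epochs = 3L, batch = 4L, lr0 = 2e-3, folds = 3L, seed = 7L),
    list(...))
  do.call(surrogate_config, args)
}

# archive of small simulations (32x32 solver, 16x16 frames)
tiny_archive <- function(n = 6L, seed = 99L, n_frames = 14L) {
  batch_simulate(n, seed = seed, n_frames = n_frames,
                 frame_interval = 4e-3, grid = grid_spec(32L), out_n = 16L,
                 gen_resolution = 64L)
}

# central-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

expect_close <- function(a, b, tol = 1e-7) {
  expect_lt(max(abs(a - b)), tol)
}
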