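test_that("homogeneous isotropic diffusion matches the analytic heat kernel", {
  g <- grid_spec(128L)
  sc <- diffusion_scenario(theta = 0, beta = 0, gamma = 1, lam = 1, d_max = 1)
  s0 <- 0.3
  tt <- 0.01
  v0 <- outer(g$xc, g$yc, function(x, y) exp(-(x^2 + y^2) / (2 * s0^2)))
  fr <- simulate_frames(sc, v0, n_frames = 14L, frame_interval = tt / 13,
                        grid = g, out_n = 128L)
  s2 <- s0^2 + 2 * tt
  va <- outer(g$xc, g$yc,
              function(x, y) (s0^2 / s2) * exp(-(x^2 + y^2) / (2 * s2)))
  rel <- sqrt(sum((fr$frames[, , 14] - va)^2) / sum(va^2))
  expect_lt(rel, 0.01)
})

test_that("the solver converges at second order under grid refinement", {
  s0 <- 0.35
  tt <- 0.008
  err_at <- function(nx) {
    g <- grid_spec(nx)
    sc <- diffusion_scenario(theta = 0, beta = 0, gamma = 1, lam = 1,
                             d_max = 1)
    v0 <- outer(g$xc, g$yc, function(x, y) exp(-(x^2 + y^2) / (2 * s0^2)))
    fr <- simulate_frames(sc, v0, n_frames = 14L, frame_interval = tt / 13,
                          grid = g, out_n = nx)
    s2 <- s0^2 + 2 * tt
    va <- outer(g$xc, g$yc,
                function(x, y) (s0^2 / s2) * exp(-(x^2 + y^2) / (2 * s2)))
    sqrt(mean((fr$frames[, , 14] - va)^2))
  }
  e <- vapply(c(32L, 64L, 128L), err_at, 0)
  expect_gt(e[1] / e[2], 2.5)   # ~4 for exact second order
  expect_gt(e[2] / e[3], 2.5)
})

test_that("single steps respect stability checks and fixed points", {
  g <- grid_spec(32L)
  sc <- sample_scenario(seed = 3)
  df <- rasterise_field(sc, g)
  z <- matrix(0, 32, 32)
  expect_identical(diffusion_step(z, df, 1e-5, g), z)
  dmax <- max(df$d0, df$d1)
  lim <- min(g$dx, g$dy)^2 / (4 * dmax)
  expect_error(diffusion_step(z, df, lim * 1.01, g), "admissible|stability|dt")
  # L2 norm non-increasing for an admissible step
  set.seed(1)
  v <- matrix(rnorm(32 * 32), 32, 32)
  v2 <- diffusion_step(v, df, lim / 3, g)
  expect_lte(sum(v2^2), sum(v^2))
})

test_that("simulated sequences obey the discrete maximum principle and
           boundary decay", {
  arch <- tiny_archive(n = 2L)
  for (sim in arch$sims) {
    m <- apply(abs(sim$frames), 3, max)
    expect_true(all(diff(m) <= 1e-12))
    expect_true(all(is.finite(sim$frames)))
  }
  # zero initial condition stays zero
  g <- grid_spec(32L)
  sc <- sample_scenario(seed = 8)
  fr <- simulate_frames(sc, matrix(0, 32, 32), n_frames = 14L,
                        frame_interval = 1e-3, grid = g, out_n = 16L)
  expect_identical(max(abs(fr$frames)), 0)
})

test_that("frames have the requested observable resolution and count", {
  g <- grid_spec(128L)
  sc <- sample_scenario(seed = 2)
  cfg <- sample_spectrum_config(seed = 2)
  v0 <- interpolate_to_mesh(generate_initial_field(cfg, seed = 2), g)
  fr <- simulate_frames(sc, v0, n_frames = 14L, frame_interval = 1e-3,
                        grid = g, out_n = 64L)
  expect_identical(dim(fr$frames), c(64L, 64L, 14L))
  expect_error(simulate_frames(sc, v0, n_frames = 10L, grid = g), ">= 14")
})

test_that("strong scar heterogeneity slows the scar region's evolution", {
  g <- grid_spec(64L)
  sc <- diffusion_scenario(theta = pi / 2, beta = 0, gamma = 1, lam = 7,
                           d_max = 3.5, scar_side = 1)
  cfg <- spectrum_config(gen_resolution = 64L)
  v0 <- interpolate_to_mesh(generate_initial_field(cfg, seed = 4), g)
  fr <- simulate_frames(sc, v0, n_frames = 14L, frame_interval = 2e-3,
                        grid = g, out_n = 64L)
  scar <- rasterise_field(sc, grid_spec(64L))$scar
  rel_change <- function(a, b, mask) {
    mean(abs(b[mask] - a[mask])) / (mean(abs(a[mask])) + 1e-12)
  }
  ch_scar <- rel_change(fr$frames[, , 1], fr$frames[, , 10], scar)
  ch_heal <- rel_change(fr$frames[, , 1], fr$frames[, , 10], !scar)
  expect_lt(ch_scar, ch_heal)
})

test_that("batch simulation is deterministic, archivable and resumable", {
  a1 <- tiny_archive(n = 3L, seed = 123L)
  a2 <- tiny_archive(n = 3L, seed = 123L)
  expect_identical(a1$sims, a2$sims)
  # resume reproduces an uninterrupted run bit-identically
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  full <- batch_simulate(4L, seed = 5L, out = tmp, n_frames = 14L,
                         grid = grid_spec(32L), out_n = 16L,
                         gen_resolution = 64L)
  unlink(tmp)
  part <- batch_simulate(2L, seed = 5L, out = tmp, n_frames = 14L,
                         grid = grid_spec(32L), out_n = 16L,
                         gen_resolution = 64L)
  expect_error(batch_simulate(4L, seed = 5L, out = tmp, n_frames = 14L,
                              grid = grid_spec(32L), out_n = 16L,
                              gen_resolution = 64L), "resume")
  res <- batch_simulate(4L, seed = 5L, out = tmp, resume = TRUE,
                        n_frames = 14L, grid = grid_spec(32L), out_n = 16L,
                        gen_resolution = 64L)
  expect_identical(res$sims, full$sims)
})
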