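test_that("spectrum config sampling draws from the stated discrete sets", {
  cfgs <- lapply(seq_len(3000), function(i) sample_spectrum_config(seed = i))
  alphas <- vapply(cfgs, `[[`, 0, "alpha")
  f0s <- vapply(cfgs, `[[`, 0, "f_0")
  expect_true(all(alphas %in% c(-1, -2)))
  expect_true(all(f0s %in% c(8, 12, 16)))
  expect_true(all(vapply(cfgs, `[[`, 0, "f_c") == 3))
  # frequencies within 3 sigma of uniform sampling
  n <- length(alphas)
  expect_lt(abs(mean(alphas == -1) - 0.5), 3 * sqrt(0.25 / n))
  for (f in c(8, 12, 16)) {
    expect_lt(abs(mean(f0s == f) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
  }
  # determinism under a fixed seed
  expect_identical(sample_spectrum_config(seed = 42),
                   sample_spectrum_config(seed = 42))
})

test_that("generated initial fields are real, windowed and normalised", {
  for (s in 1:5) {
    cfg <- sample_spectrum_config(seed = s)
    f <- generate_initial_field(cfg, seed = s)
    expect_lt(f$imag_residual, 1e-10)
    n <- cfg$gen_resolution
    ring <- c(f$values[c(1, n), ], f$values[, c(1, n)])
    expect_lt(max(abs(ring)), 1e-6 * max(abs(f$values)))
    expect_equal(max(abs(f$values)), cfg$contrast)
    # bit-identical regeneration
    expect_identical(f$values,
                     generate_initial_field(cfg, seed = s)$values)
  }
})

test_that("spectrum cut-off removes power beyond f0 before windowing", {
  cfg <- spectrum_config(alpha = -2, f_0 = 8, gen_resolution = 128L)
  f <- generate_initial_field(cfg, seed = 3)
  P <- Mod(stats::fft(f$unwindowed))^2
  n <- 128L
  k <- c(0:(n / 2), -((n / 2 - 1):1))
  f2 <- outer(k^2, k^2, "+")
  expect_lt(sum(P[f2 >= 64]) / sum(P), 1e-8)
})

test_that("sub-Nyquist generation resolution is rejected", {
  expect_error(spectrum_config(f_0 = 16, gen_resolution = 24L), "Nyquist")
})

test_that("scenario ratio constraints hold exactly and forced cases match", {
  sc <- diffusion_scenario(theta = 1, beta = 0.2, gamma = 2, lam = 4,
                           d_max = 3.6, fast_axis = "horizontal")
  expect_identical(c(sc$d0, sc$d1, sc$d0_scar, sc$d1_scar),
                   c(3.6, 1.8, 0.9, 0.45))
  iso <- diffusion_scenario(theta = 1, beta = 0, gamma = 1, lam = 3,
                            d_max = 3.5)
  expect_identical(iso$d0, iso$d1)
  expect_identical(iso$d0_scar, iso$d1_scar)
  eps4 <- 4 * .Machine$double.eps
  for (s in 1:200) {
    sc <- sample_scenario(seed = s)
    expect_lt(abs(max(sc$d0, sc$d1) / min(sc$d0, sc$d1) / sc$gamma - 1), eps4)
    expect_lt(abs(max(sc$d0_scar, sc$d1_scar) /
                    min(sc$d0_scar, sc$d1_scar) / sc$gamma - 1), eps4)
    expect_lt(abs(sc$d0 / sc$d0_scar / sc$lam - 1), eps4)
    expect_lt(abs(sc$d1 / sc$d1_scar / sc$lam - 1), eps4)
  }
})

test_that("sampled scenario parameters stay within the stated intervals and
           pass a uniformity check", {
  draws <- t(vapply(1:2000, function(s) {
    sc <- sample_scenario(seed = s)
    c(sc$theta, sc$beta, sc$gamma, sc$lam, sc$d_max)
  }, numeric(5)))
  lo <- c(0, -1, 1, 2, 3.2)
  hi <- c(pi, 1, 3, 7, 3.8)
  for (j in 1:5) {
    expect_true(all(draws[, j] >= lo[j] & draws[, j] <= hi[j]))
    ks <- stats::ks.test(draws[, j], "punif", lo[j], hi[j])
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("rasterisation partitions the grid as the line dictates", {
  g <- grid_spec(64L)
  sc <- diffusion_scenario(theta = 0, beta = 0, gamma = 2, lam = 3,
                           d_max = 3.5, scar_side = 1)
  df <- rasterise_field(sc, g)
  expect_equal(mean(df$scar), 0.5, tolerance = 1 / 64)
  expect_true(all(df$d0 %in% c(sc$d0, sc$d0_scar)))
  expect_true(all((df$d0 == sc$d0_scar) == (df$d1 == sc$d1_scar)))
  # line fully outside the domain -> one region
  out <- diffusion_scenario(theta = 0.7, beta = 2.9, gamma = 2, lam = 3,
                            d_max = 3.5, scar_side = 1)
  expect_equal(sum(rasterise_field(out, g)$scar), 0)
  # partition covers every cell
  rnd <- sample_scenario(seed = 5)
  dfr <- rasterise_field(rnd, g)
  expect_identical(sum(dfr$scar) + sum(!dfr$scar), length(dfr$scar))
})

test_that("bilinear interpolation reproduces ramps exactly and the identity
           on shared nodes", {
  cfg <- spectrum_config(gen_resolution = 64L)
  f <- generate_initial_field(cfg, seed = 1)
  # identity: target nodes = source nodes
  xs <- seq(-2, 2, length.out = 64)
  same <- epmodkit:::interp_bilinear(xs, xs, f$values, xs, xs)
  expect_close(same, f$values, 1e-12)
  # affine field interpolates exactly
  ramp <- outer(xs, xs, function(x, y) 0.3 * x - 1.1 * y + 0.5)
  g <- grid_spec(32L)
  got <- epmodkit:::interp_bilinear(xs, xs, ramp, g$xc, g$yc)
  want <- outer(g$xc, g$yc, function(x, y) 0.3 * x - 1.1 * y + 0.5)
  expect_close(got, want, 1e-12)
  # constant in, constant out
  konst <- epmodkit:::interp_bilinear(xs, xs, ramp * 0 + 2, g$xc, g$yc)
  expect_close(konst, want * 0 + 2, 1e-12)
  # out-of-extent target rejected
  expect_error(epmodkit:::interp_bilinear(xs, xs, ramp, c(0, 3), c(0, 0)),
               "extent")
})
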