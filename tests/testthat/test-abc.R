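# Gaussian toy problem: two unknown means with unit-variance observation
# noise. With a flat prior over the support, the posterior given the observed
# sample mean is N(obs_mean, sigma^2 / n_obs) per dimension -- an analytic
# oracle for the ABC engine.
toy_setup <- function(n_obs = 25L, seed = 11L) {
  truth <- c(mu1 = 1.2, mu2 = -0.7)
  obs_mean <- withr::with_seed(seed, {
    colMeans(matrix(rnorm(2 * n_obs, mean = rep(truth, each = n_obs)),
                    n_obs, 2))
  })
  observed <- list(m = data.frame(protocol = "m", x = 1:2, y = obs_mean))
  model_fn <- function(th) {
    y <- colMeans(matrix(stats::rnorm(2 * n_obs, mean = rep(th, each = n_obs)),
                         n_obs, 2))
    list(m = data.frame(protocol = "m", x = 1:2, y = y))
  }
  prior <- prior_spec(c(mu1 = -5, mu2 = -5), c(mu1 = 5, mu2 = 5))
  list(truth = truth, obs_mean = obs_mean, observed = observed,
       model_fn = model_fn, prior = prior, n_obs = n_obs)
}

test_that("prior sampling respects bounds, uniformity and seeding", {
  pr <- channel_prior()
  th <- sample_prior(pr, 10000L, seed = 1L)
  expect_true(all(sweep(th, 2, pr$lo, ">=") & sweep(th, 2, pr$hi, "<=")))
  for (j in seq_along(pr$lo)) {
    ks <- stats::ks.test(th[, j], "punif", pr$lo[j], pr$hi[j])
    expect_gt(ks$p.value, 0.01)
  }
  expect_identical(th, sample_prior(pr, 10000L, seed = 1L))
  expect_error(prior_spec(c(a = 1), c(a = 1)), "lo < hi")
})

test_that("the curve distance is an RMS averaged over curves", {
  p <- channel_params()
  cv <- steady_state_curves(p)
  expect_identical(curve_distance(cv, cv), 0)
  off <- cv
  off$activation$y <- off$activation$y + 0.3
  expect_equal(curve_distance(off["activation"], cv["activation"]), 0.3,
               tolerance = 1e-12)
  # brute-force recomputation on random pairs
  set.seed(2)
  a <- list(x = data.frame(x = 1:7, y = rnorm(7)),
            z = data.frame(x = 1:5, y = rnorm(5)))
  b <- list(x = data.frame(x = 1:7, y = rnorm(7)),
            z = data.frame(x = 1:5, y = rnorm(5)))
  brute <- mean(c(sqrt(mean((a$x$y - b$x$y)^2)),
                  sqrt(mean((a$z$y - b$z$y)^2))))
  expect_equal(curve_distance(a, b), brute, tolerance = 1e-12)
  bad <- list(x = data.frame(x = 2:8, y = rnorm(7)), z = b$z)
  expect_error(curve_distance(bad, b), "x-grids")
})

test_that("generation 0 at infinite tolerance accepts everything with
           uniform weights", {
  ts <- toy_setup()
  pop <- withr::with_seed(3L, {
    run_generation(NULL, ts$prior, ts$model_fn, ts$observed, Inf, 200L)
  })
  expect_identical(pop$accept_rate, 1)
  expect_identical(pop$weights, rep(1 / 200, 200))
  expect_equal(sum(pop$weights), 1)
  expect_equal(pop$ess, 200)
})

test_that("ABC-SMC recovers the analytic Gaussian posterior", {
  ts <- toy_setup()
  pop <- run_abcsmc(ts$prior, ts$model_fn, ts$observed, n_particles = 300L,
                    max_gens = 6L, seed = 21L)
  s <- posterior_summary(pop)
  se <- s$sd / sqrt(min(pop$ess[length(pop$ess)], 300))
  for (j in 1:2) {
    expect_lt(abs(s$mean[j] - ts$obs_mean[j]), 3 * se[j])
  }
  # posterior variance approaches the analytic value (sigma^2/n plus the
  # residual ABC broadening) and is far below the prior variance
  ana_var <- 1 / ts$n_obs
  expect_lt(max(s$sd^2), 6 * ana_var)
  expect_gt(min(s$sd^2), ana_var / 6)
  expect_lt(max(s$sd^2), (10^2 / 12) / 20)
  # tolerances decrease monotonically; weights stay normalised
  expect_true(all(diff(pop$epsilons) <= 0))
  for (g in pop$generations) {
    expect_equal(sum(g$weights), 1)
    expect_false(any(is.na(g$weights)))
  }
})

test_that("a full ABC run is bit-identical under the same seed", {
  ts <- toy_setup()
  p1 <- run_abcsmc(ts$prior, ts$model_fn, ts$observed, n_particles = 60L,
                   max_gens = 3L, seed = 9L)
  p2 <- run_abcsmc(ts$prior, ts$model_fn, ts$observed, n_particles = 60L,
                   max_gens = 3L, seed = 9L)
  expect_identical(p1$theta, p2$theta)
  expect_identical(p1$weights, p2$weights)
  expect_identical(p1$epsilons, p2$epsilons)
})

test_that("posterior summaries order min <= mean <= max and handle a single
           particle", {
  ts <- toy_setup()
  pop <- run_abcsmc(ts$prior, ts$model_fn, ts$observed, n_particles = 50L,
                    max_gens = 2L, seed = 5L)
  s <- posterior_summary(pop)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  one <- pop
  one$theta <- pop$theta[1, , drop = FALSE]
  one$weights <- 1
  s1 <- posterior_summary(one)
  expect_identical(s1$mean, s1$min)
  expect_identical(s1$mean, s1$max)
})

test_that("the weighted KDE integrates to one and is symmetric for a
           symmetric population", {
  set.seed(8)
  n <- 4000
  th <- cbind(a = rnorm(n), b = rnorm(n))
  pop <- list(theta = th, weights = rep(1 / n, n))
  kde <- posterior_kde(pop, c("a", "b"), gridsize = 96L)
  dx <- diff(kde$x[1:2]); dy <- diff(kde$y[1:2])
  expect_equal(sum(kde$z) * dx * dy, 1, tolerance = 0.01)
  # symmetry of the estimate under reflection of a symmetric sample
  pop2 <- list(theta = rbind(th, -th), weights = rep(1 / (2 * n), 2 * n))
  k2 <- posterior_kde(pop2, c("a", "b"), gridsize = 64L)
  expect_equal(k2$z, k2$z[rev(seq_along(k2$x)), rev(seq_along(k2$y))],
               tolerance = 1e-8)
  # KDE against a histogram oracle on the same sample
  hx <- hist(th[, 1], breaks = seq(-6, 6, length.out = 51), plot = FALSE)
  kx_marg <- rowSums(kde$z) * dy
  approx_at <- stats::approx(kde$x, kx_marg, xout = hx$mids)$y
  expect_lt(max(abs(approx_at - hx$density), na.rm = TRUE), 0.05)
  dg <- list(theta = cbind(a = rep(1, 20), b = rep(2, 20)),
             weights = rep(0.05, 20))
  expect_error(posterior_kde(dg, c("a", "b")), "degenerate")
})

test_that("posterior predictive envelopes bracket the median pointwise", {
  ts <- toy_setup()
  pop <- run_abcsmc(ts$prior, ts$model_fn, ts$observed, n_particles = 80L,
                    max_gens = 3L, seed = 13L)
  env <- posterior_predictive(pop, ts$model_fn, n_samples = 100L, seed = 1L)
  expect_length(attr(env, "samples"), 100L)
  expect_true(all(env$m$lo <= env$m$median & env$m$median <= env$m$hi))
  # degenerate single-particle population with a deterministic model
  det_fn <- function(th) list(m = data.frame(protocol = "m", x = 1:2,
                                             y = unname(th)))
  one <- list(theta = pop$theta[1, , drop = FALSE], weights = 1)
  e1 <- posterior_predictive(one, det_fn, n_samples = 20L, seed = 2L)
  expect_identical(max(e1$m$hi - e1$m$lo), 0)
})
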