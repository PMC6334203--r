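#' Uniform prior specification for ABC
#'
#' @param lo,hi Named numeric vectors of lower/upper bounds (same names, same
#'   order); `lo < hi` elementwise.
#' @return An object of class `epk_prior`.
#' @export
prior_spec <- function(lo, hi) {
  stopifnot(length(lo) == length(hi), !is.null(names(lo)),
            identical(names(lo), names(hi)))
  if (any(lo >= hi)) stop("every prior must have lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi, names = names(lo),
                 log_density = -sum(log(hi - lo))),
            class = "epk_prior")
}

#' Prior bounds for the nine sodium-channel parameters
#' @return An `epk_prior` built from [channel_prior_table()].
#' @export
channel_prior <- function() {
  tb <- channel_prior_table()
  prior_spec(stats::setNames(tb$prior_lo, tb$name),
             stats::setNames(tb$prior_hi, tb$name))
}

#' Draw parameter vectors from a uniform prior
#'
#' @param prior An `epk_prior`.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return n x d matrix with named columns.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  d <- length(prior$lo)
  with_seed_if(seed, {
    u <- matrix(stats::runif(n * d), n, d)
    th <- sweep(sweep(u, 2, prior$hi - prior$lo, "*"), 2, prior$lo, "+")
    colnames(th) <- prior$names
    th
  })
}

in_prior_support <- function(theta, prior) {
  all(theta >= prior$lo & theta <= prior$hi)
}

#' Distance between two sets of summary curves
#'
#' Root-mean-square difference of the `y` values per curve, averaged over
#' curves with equal weight. Curves are matched by name (or position) and
#' must share `x` grids.
#'
#' @param simulated,observed Lists of curve data frames (columns `x`, `y`).
#' @return Non-negative scalar; zero iff all curves are identical.
#' @export
curve_distance <- function(simulated, observed) {
  if (length(simulated) != length(observed)) {
    stop("curve sets have different lengths", call. = FALSE)
  }
  nm <- names(observed)
  if (!is.null(nm) && !is.null(names(simulated))) {
    simulated <- simulated[nm]
  }
  ds <- vapply(seq_along(observed), function(i) {
    s <- simulated[[i]]; o <- observed[[i]]
    if (nrow(s) != nrow(o) || max(abs(s$x - o$x)) > 1e-9) {
      stop("curve x-grids do not match", call. = FALSE)
    }
    sqrt(mean((s$y - o$y)^2))
  }, 0)
  mean(ds)
}

# log density of N(0, Sigma) evaluated via a cholesky factor, vectorised over
# rows of the deviation matrix
mvn_logdens <- function(dev, chol_sigma) {
  z <- backsolve(chol_sigma, t(dev), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) -
    0.5 * ncol(dev) * log(2 * pi)
}

#' Run one ABC-SMC generation
#'
#' Generation 0 draws `n` particles straight from the prior (all accepted,
#' uniform weights). Later generations resample the previous population by
#' weight, perturb with a multivariate Gaussian kernel whose covariance is
#' twice the weighted empirical covariance of the previous generation, reject
#' proposals outside the prior support, and accept candidates whose distance
#' to the observations is at most `epsilon`. Importance weights are the prior
#' density over the kernel mixture density.
#'
#' @param prev Previous population (list with `theta`, `weights`) or `NULL`
#'   for generation 0.
#' @param prior An `epk_prior`.
#' @param model_fn Function mapping a named parameter vector to a list of
#'   summary curves.
#' @param observed Observed summary curves.
#' @param epsilon Acceptance tolerance (may be `Inf`).
#' @param n Number of particles to accept.
#' @param max_trials Abort if more proposals than this are needed.
#' @param min_accept_rate Abort (with diagnostics) if the running acceptance
#'   rate after 20 * n trials falls below this floor.
#' @return List with `theta` (n x d), `weights`, `distances`, `trials`,
#'   `accept_rate`, `ess`.
#' @export
run_generation <- function(prev, prior, model_fn, observed, epsilon, n,
                           max_trials = 2e5, min_accept_rate = 0.001) {
  d <- length(prior$lo)
  theta <- matrix(0, n, d, dimnames = list(NULL, prior$names))
  dist <- numeric(n)
  gen0 <- is.null(prev)
  if (!gen0) {
    cv <- 2 * weighted_cov(prev$theta, prev$weights)
    # regularise degenerate directions so the kernel stays proper
    diag(cv) <- diag(cv) + 1e-12 * (prior$hi - prior$lo)^2
    ch <- chol(cv)
  }
  acc <- 0L
  trials <- 0L
  while (acc < n) {
    if (trials > max_trials) {
      stop(sprintf(
        "ABC generation exceeded %d proposals (%d/%d accepted, eps=%g)",
        max_trials, acc, n, epsilon), call. = FALSE)
    }
    if (trials >= 20L * n && acc / trials < min_accept_rate) {
      stop(sprintf(
        "ABC acceptance rate %.4f below floor %.4f at eps=%g (%d trials)",
        acc / trials, min_accept_rate, epsilon, trials), call. = FALSE)
    }
    if (gen0) {
      cand <- drop(sample_prior(prior, 1L))
    } else {
      i <- sample.int(nrow(prev$theta), 1L, prob = prev$weights)
      cand <- prev$theta[i, ] + drop(stats::rnorm(d) %*% ch)
      if (!in_prior_support(cand, prior)) {
        trials <- trials + 1L
        next
      }
    }
    dd <- curve_distance(model_fn(cand), observed)
    trials <- trials + 1L
    if (dd <= epsilon) {
      acc <- acc + 1L
      theta[acc, ] <- cand
      dist[acc] <- dd
    }
  }
  if (gen0) {
    w <- rep(1 / n, n)
  } else {
    logw <- vapply(seq_len(n), function(i) {
      dev <- sweep(prev$theta, 2, theta[i, ], "-")
      lk <- mvn_logdens(dev, ch) + log(prev$weights)
      prior$log_density - logsumexp(lk)
    }, 0)
    w <- exp(logw - max(logw))
    w <- w / sum(w)
  }
  list(theta = theta, weights = w, distances = dist, trials = trials,
       accept_rate = n / trials, ess = 1 / sum(w^2))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

weighted_cov <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu, "-")
  cv <- crossprod(Xc * sqrt(w), Xc * sqrt(w)) / (1 - sum(w^2))
  (cv + t(cv)) / 2
}

#' Approximate Bayesian computation by sequential Monte Carlo
#'
#' Generation 0 is a plain prior sample; the first tolerance is the
#' `eps_quantile` quantile of its distances and each later tolerance is the
#' median of the previous generation's accepted distances, so the tolerance
#' sequence is non-increasing. Stops at `max_gens`, when the tolerance drops
#' below `eps_target`, or when the acceptance rate falls below
#' `min_accept_rate` (the last completed generation is returned). With
#' `adapt_population = TRUE` the population is doubled for the next
#' generation whenever the effective sample size falls below half the
#' particle count.
#'
#' @param prior An `epk_prior`.
#' @param model_fn Function mapping a named parameter vector to summary
#'   curves.
#' @param observed Observed summary curves.
#' @param n_particles Particles per generation (default 500).
#' @param max_gens Maximum number of generations after generation 0.
#' @param eps_quantile Quantile of generation-0 distances used as the first
#'   tolerance.
#' @param eps_target Stop once the tolerance falls below this.
#' @param min_accept_rate Acceptance-rate floor.
#' @param adapt_population ESS-triggered population doubling (default off).
#' @param seed Seed for the whole run.
#' @param verbose Print per-generation diagnostics.
#' @return An object of class `epk_posterior`: list with `theta`, `weights`,
#'   `distances` (final generation), `epsilons`, `accept_rates`, `ess`,
#'   `generations` (per-generation particle matrices), `prior`, `seed`.
#' @export
run_abcsmc <- function(prior, model_fn, observed, n_particles = 500L,
                       max_gens = 8L, eps_quantile = 0.5, eps_target = 1e-4,
                       min_accept_rate = 0.01, adapt_population = FALSE,
                       seed = NULL, verbose = FALSE) {
  with_seed_if(seed, {
    n <- as.integer(n_particles)
    pop <- run_generation(NULL, prior, model_fn, observed, Inf, n)
    epsilons <- numeric()
    accept_rates <- pop$accept_rate
    ess <- pop$ess
    gens <- list(pop)
    eps <- unname(stats::quantile(pop$distances, eps_quantile))
    for (g in seq_len(max_gens)) {
      if (eps < eps_target) break
      nxt <- tryCatch(
        run_generation(pop, prior, model_fn, observed, eps, n,
                       min_accept_rate = min_accept_rate),
        error = function(e) e)
      if (inherits(nxt, "error")) {
        if (verbose) message("stopping: ", conditionMessage(nxt))
        break
      }
      pop <- nxt
      epsilons <- c(epsilons, eps)
      accept_rates <- c(accept_rates, pop$accept_rate)
      ess <- c(ess, pop$ess)
      gens[[length(gens) + 1L]] <- pop
      if (verbose) {
        message(sprintf("gen %d: eps=%.5g acc=%.3f ess=%.1f", g, eps,
                        pop$accept_rate, pop$ess))
      }
      if (adapt_population && pop$ess < n / 2) n <- 2L * n
      eps <- stats::median(pop$distances)
    }
    structure(list(theta = pop$theta, weights = pop$weights,
                   distances = pop$distances, epsilons = epsilons,
                   accept_rates = accept_rates, ess = ess,
                   generations = gens, prior = prior, seed = seed),
              class = "epk_posterior")
  })
}

#' Posterior summary table (weighted mean, min, max per parameter)
#'
#' @param pop An `epk_posterior`.
#' @param orig Optional named vector of reference ("original") values to
#'   include as a column.
#' @return Data frame with columns `name`, (`orig`,) `prior_lo`, `prior_hi`,
#'   `mean`, `min`, `max`, `sd`.
#' @export
posterior_summary <- function(pop, orig = NULL) {
  w <- pop$weights / sum(pop$weights)
  mu <- colSums(pop$theta * w)
  sdv <- sqrt(pmax(0, colSums(pop$theta^2 * w) - mu^2))
  out <- data.frame(name = pop$prior$names,
                    prior_lo = unname(pop$prior$lo),
                    prior_hi = unname(pop$prior$hi),
                    mean = unname(mu),
                    min = unname(apply(pop$theta, 2, min)),
                    max = unname(apply(pop$theta, 2, max)),
                    sd = unname(sdv),
                    stringsAsFactors = FALSE)
  if (!is.null(orig)) {
    out <- cbind(out[1], orig = unname(orig[out$name]), out[-1])
  }
  out
}

#' Weighted two-dimensional kernel density of a posterior parameter pair
#'
#' Weighted Gaussian product-kernel estimate on a regular grid; bandwidths
#' follow Scott's rule scaled by the effective sample size.
#'
#' @param pop An `epk_posterior`.
#' @param pair Character or integer vector of two parameter names/indices.
#' @param gridsize Grid points per axis.
#' @param expand Fraction by which the particle range is padded.
#' @return List with `x`, `y`, `z` (density matrix), `pair`.
#' @export
posterior_kde <- function(pop, pair, gridsize = 64L, expand = 0.15) {
  th <- pop$theta[, pair, drop = FALSE]
  if (nrow(th) < 10L) stop("need at least 10 particles", call. = FALSE)
  w <- pop$weights / sum(pop$weights)
  ess <- 1 / sum(w^2)
  sds <- sqrt(pmax(colSums(th^2 * w) - colSums(th * w)^2, 0))
  if (any(sds == 0)) stop("degenerate (zero-variance) population",
                          call. = FALSE)
  bw <- sds * ess^(-1 / 6)
  rngs <- lapply(1:2, function(j) {
    r <- range(th[, j])
    pad <- expand * diff(r) + 4 * bw[j]
    seq(r[1] - pad, r[2] + pad, length.out = gridsize)
  })
  kx <- outer(rngs[[1]], th[, 1], function(g, t) stats::dnorm(g, t, bw[1]))
  ky <- outer(rngs[[2]], th[, 2], function(g, t) stats::dnorm(g, t, bw[2]))
  # z[i, j] = sum_t w_t Kx(x_i | t) Ky(y_j | t)
  z <- (kx * rep(w, each = gridsize)) %*% t(ky)
  list(x = rngs[[1]], y = rngs[[2]], z = z, pair = pair)
}

#' Posterior predictive envelope of summary curves
#'
#' Draws `n_samples` parameter vectors from the weighted posterior, pushes
#' each through the forward model, and summarises each curve pointwise by the
#' median and a 95% interval.
#'
#' @param pop An `epk_posterior`.
#' @param model_fn Forward model (named parameter vector to curve list).
#' @param n_samples Number of posterior draws (default 100).
#' @param seed Optional seed.
#' @return Named list of data frames with columns `x`, `median`, `lo`, `hi`
#'   (2.5% and 97.5% quantiles), plus attribute `"samples"` holding all
#'   simulated curve sets.
#' @export
posterior_predictive <- function(pop, model_fn, n_samples = 100L,
                                 seed = NULL) {
  with_seed_if(seed, {
    idx <- sample.int(nrow(pop$theta), n_samples, replace = TRUE,
                      prob = pop$weights)
    sims <- lapply(idx, function(i) model_fn(pop$theta[i, ]))
    proto <- sims[[1]]
    out <- lapply(seq_along(proto), function(ci) {
      ys <- vapply(sims, function(s) s[[ci]]$y, numeric(nrow(proto[[ci]])))
      ys <- matrix(ys, nrow = nrow(proto[[ci]]))
      data.frame(x = proto[[ci]]$x,
                 median = apply(ys, 1, stats::median),
                 lo = apply(ys, 1, stats::quantile, 0.025),
                 hi = apply(ys, 1, stats::quantile, 0.975))
    })
    names(out) <- names(proto)
    attr(out, "samples") <- sims
    out
  })
}

#' @export
print.epk_posterior <- function(x, ...) {
  cat(sprintf(
    "<epk_posterior> %d particles, %d refinement generations, final eps %s\n",
    nrow(x$theta), length(x$epsilons),
    if (length(x$epsilons)) format(x$epsilons[length(x$epsilons)],
                                   digits = 4) else "-"))
  print(posterior_summary(x), digits = 4)
  invisible(x)
}
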