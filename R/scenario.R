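#' Spectrum configuration for smoothed-noise initial conditions
#'
#' Describes the random spatial-frequency spectrum from which initial fields
#' are synthesised: a power-law amplitude envelope
#' \eqn{(f_x^2 + f_y^2 + f_c)^{\alpha/2}} with a sharp cut-off at
#' \eqn{f_x^2 + f_y^2 \ge f_0^2}. Frequencies are measured in cycles per
#' domain length.
#'
#' @param alpha Spectral exponent; sampled values are -1 or -2.
#' @param f_c Corner frequency (cycles per domain length), default 3.
#' @param f_0 Cut-off frequency; sampled values are 8, 12 or 16.
#' @param gen_resolution Pixels per side of the generation grid (default 128).
#' @param contrast Target peak amplitude of the normalised field (default 1).
#' @param margin_frac Fraction of the half-domain over which the field is
#'   tapered to zero towards the boundary (default 0.1).
#' @return An object of class `epk_spectrum_config`.
#' @export
spectrum_config <- function(alpha = -2, f_c = 3, f_0 = 8,
                            gen_resolution = 128L, contrast = 1,
                            margin_frac = 0.1) {
  check_scalar(alpha, "alpha")
  check_scalar(f_c, "f_c", lo = 0)
  check_scalar(f_0, "f_0", lo = 0)
  check_scalar(contrast, "contrast", lo = 0)
  check_scalar(margin_frac, "margin_frac", lo = 0, hi = 0.5)
  gen_resolution <- as.integer(gen_resolution)
  if (gen_resolution < 2 * f_0) {
    stop(sprintf(
      "gen_resolution (%d) below the Nyquist requirement 2*f_0 (%g)",
      gen_resolution, 2 * f_0), call. = FALSE)
  }
  structure(list(alpha = alpha, f_c = f_c, f_0 = f_0,
                 gen_resolution = gen_resolution, contrast = contrast,
                 margin_frac = margin_frac),
            class = "epk_spectrum_config")
}

#' Sample a spectrum configuration
#'
#' Draws `alpha` uniformly from \{-1, -2\} and `f_0` uniformly from
#' \{8, 12, 16\}; the corner frequency `f_c` is fixed at 3.
#'
#' @param seed Optional integer seed; if `NULL` the ambient RNG stream is used.
#' @param ... Overrides forwarded to [spectrum_config()] (e.g. `gen_resolution`).
#' @return An `epk_spectrum_config`.
#' @export
sample_spectrum_config <- function(seed = NULL, ...) {
  with_seed_if(seed, {
    alpha <- sample(c(-1, -2), 1L)
    f_0 <- sample(c(8, 12, 16), 1L)
    spectrum_config(alpha = alpha, f_c = 3, f_0 = f_0, ...)
  })
}

# Node-based generation grid over [-2, 2]; boundary nodes sit exactly on the
# domain edge so the taper reaches zero there.
gen_grid_axis <- function(n) seq(-2, 2, length.out = n)

# Raised-cosine taper: 1 inside, smoothly to 0 at |x| = 2 over the outer
# margin_frac of the half-width.
boundary_window <- function(x, margin_frac) {
  half <- 2
  x0 <- half * (1 - margin_frac)
  w <- rep(1, length(x))
  idx <- abs(x) > x0
  w[idx] <- 0.5 * (1 + cos(pi * (abs(x[idx]) - x0) / (half - x0)))
  w
}

#' Generate a smoothed-noise initial field
#'
#' Builds a random two-dimensional spectrum with amplitude envelope
#' \eqn{(f_x^2+f_y^2+f_c)^{\alpha/2}}, zeroed where
#' \eqn{f_x^2+f_y^2 \ge f_0^2}, multiplied by standard Gaussian amplitude
#' noise with phases uniform on \eqn{[0, 2\pi)}. Conjugate symmetry is imposed
#' so the inverse transform is real. The spatial field is tapered to zero
#' towards the domain boundary and normalised so that its peak absolute value
#' equals `config$contrast`.
#'
#' @param config An `epk_spectrum_config`.
#' @param seed Optional integer seed.
#' @return An object of class `epk_initial_field` with elements `values`
#'   (gen_resolution x gen_resolution matrix on a node grid over
#'   \eqn{[-2,2]^2}), `unwindowed` (pre-window, pre-normalisation field, for
#'   spectral diagnostics), `config` and `seed`.
#' @export
generate_initial_field <- function(config, seed = NULL) {
  stopifnot(inherits(config, "epk_spectrum_config"))
  n <- config$gen_resolution
  if (n < 2 * config$f_0) stop("gen_resolution below Nyquist for f_0")
  with_seed_if(seed, {
    # FFT-layout integer frequencies in cycles per domain length
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[seq_len(n)]
    fx <- matrix(k, n, n)
    fy <- t(fx)
    f2 <- fx^2 + fy^2
    env <- (f2 + config$f_c)^(config$alpha / 2)
    env[f2 >= config$f_0^2] <- 0
    amp <- matrix(stats::rnorm(n * n), n, n)
    phase <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
    spec <- env * amp * exp(1i * phase)
    # conjugate symmetrisation: average each bin with the conjugate of its
    # mirror bin so the inverse transform is purely real
    mirror <- function(i) ((n - (i - 1)) %% n) + 1
    spec_sym <- (spec + Conj(spec[mirror(seq_len(n)), mirror(seq_len(n))])) / 2
    v <- stats::fft(spec_sym, inverse = TRUE) / n^2
    imag_resid <- max(abs(Im(v))) / max(abs(Re(v)))
    v <- Re(v)
    x <- gen_grid_axis(n)
    w <- outer(boundary_window(x, config$margin_frac),
               boundary_window(x, config$margin_frac))
    vw <- v * w
    vw <- vw * (config$contrast / max(abs(vw)))
    structure(list(values = vw,
                   unwindowed = v,
                   config = config,
                   seed = seed,
                   imag_residual = imag_resid),
              class = "epk_initial_field")
  })
}

#' Construct a diffusion scenario
#'
#' A scenario is a partition of the square domain \eqn{[-2,2]^2} into a
#' healthy and a scarred region by a straight line with orientation `theta`
#' and signed offset `beta` from the centre, plus per-region diagonal
#' diffusivities obeying the anisotropy constraint
#' \eqn{\max(d_0,d_1)/\min(d_0,d_1) = \gamma} within each region and the
#' heterogeneity constraint \eqn{d_0/d_{0,scar} = d_1/d_{1,scar} = \lambda}.
#'
#' @param theta Boundary-line orientation, radians in `[0, pi)`.
#' @param beta Signed perpendicular distance of the line from the centre.
#' @param gamma Anisotropy ratio (>= 1).
#' @param lam Heterogeneity ratio (> 0).
#' @param d_max Diffusivity along the fast axis of the healthy region.
#' @param fast_axis `"horizontal"` or `"vertical"`.
#' @param scar_side `+1` or `-1`: which side of the line (by signed distance)
#'   is scar.
#' @param seed Optional seed recorded in metadata.
#' @return An object of class `epk_scenario` with fields `d0`, `d1`,
#'   `d0_scar`, `d1_scar` derived exactly from `gamma`, `lam`, `d_max`.
#' @export
diffusion_scenario <- function(theta, beta, gamma, lam, d_max,
                               fast_axis = c("horizontal", "vertical"),
                               scar_side = 1, seed = NULL) {
  fast_axis <- match.arg(fast_axis)
  check_scalar(theta, "theta", lo = 0, hi = pi)
  check_scalar(beta, "beta")
  check_scalar(gamma, "gamma", lo = 1)
  check_scalar(lam, "lam", lo = .Machine$double.eps)
  check_scalar(d_max, "d_max", lo = .Machine$double.eps)
  stopifnot(scar_side %in% c(-1, 1))
  d_fast <- d_max
  d_slow <- d_max / gamma
  if (fast_axis == "horizontal") {
    d0 <- d_fast; d1 <- d_slow
  } else {
    d0 <- d_slow; d1 <- d_fast
  }
  structure(list(theta = theta, beta = beta, gamma = gamma, lam = lam,
                 d_max = d_max, fast_axis = fast_axis, scar_side = scar_side,
                 d0 = d0, d1 = d1, d0_scar = d0 / lam, d1_scar = d1 / lam,
                 seed = seed),
            class = "epk_scenario")
}

#' Sample a random diffusion scenario
#'
#' Draws `theta ~ U[0, pi)`, `beta ~ U[-1, 1]`, `gamma ~ U[1, 3]`,
#' `lam ~ U[2, 7]`, the fast-axis diffusivity from `U[3.2, 3.8]`, the fast
#' axis uniformly from \{horizontal, vertical\} and the scar side uniformly
#' from the two sides of the line.
#'
#' @param seed Optional integer seed.
#' @return An `epk_scenario`.
#' @export
sample_scenario <- function(seed = NULL) {
  with_seed_if(seed, {
    diffusion_scenario(
      theta = stats::runif(1, 0, pi),
      beta = stats::runif(1, -1, 1),
      gamma = stats::runif(1, 1, 3),
      lam = stats::runif(1, 2, 7),
      d_max = stats::runif(1, 3.2, 3.8),
      fast_axis = sample(c("horizontal", "vertical"), 1L),
      scar_side = sample(c(-1, 1), 1L),
      seed = seed
    )
  })
}

#' Rasterise a scenario's diffusivity field onto a solver grid
#'
#' Each cell takes the scar diffusivity pair iff its centre lies on the scar
#' side of the partition line; otherwise the healthy pair.
#'
#' @param scenario An `epk_scenario`.
#' @param grid An `epk_grid` from [grid_spec()].
#' @return A list with matrices `d0` and `d1` (nx x ny, horizontal and
#'   vertical diffusivities per cell) and logical matrix `scar`.
#' @export
rasterise_field <- function(scenario, grid) {
  stopifnot(inherits(scenario, "epk_scenario"), inherits(grid, "epk_grid"))
  xc <- grid$xc
  yc <- grid$yc
  # line direction (cos theta, sin theta); normal (-sin, cos); signed distance
  sd <- outer(-sin(scenario$theta) * xc, cos(scenario$theta) * yc, "+") -
    scenario$beta
  scar <- (sd * scenario$scar_side) > 0
  d0 <- matrix(scenario$d0, grid$nx, grid$ny)
  d1 <- matrix(scenario$d1, grid$nx, grid$ny)
  d0[scar] <- scenario$d0_scar
  d1[scar] <- scenario$d1_scar
  list(d0 = d0, d1 = d1, scar = scar)
}

#' Bilinearly interpolate a generated field onto solver-grid points
#'
#' @param field An `epk_initial_field` (node grid over \eqn{[-2,2]^2}).
#' @param grid An `epk_grid`; the field is evaluated at cell centres.
#' @return An nx x ny matrix.
#' @export
interpolate_to_mesh <- function(field, grid) {
  stopifnot(inherits(field, "epk_initial_field"), inherits(grid, "epk_grid"))
  interp_bilinear(gen_grid_axis(field$config$gen_resolution),
                  gen_grid_axis(field$config$gen_resolution),
                  field$values, grid$xc, grid$yc)
}

# Bilinear interpolation of Z (length(xs) x length(ys), Z[i,j] = f(xs[i], ys[j]))
# at the tensor grid (xp, yp). Reproduces affine functions exactly and is the
# identity on shared nodes.
interp_bilinear <- function(xs, ys, Z, xp, yp) {
  if (min(xp) < min(xs) - 1e-12 || max(xp) > max(xs) + 1e-12 ||
      min(yp) < min(ys) - 1e-12 || max(yp) > max(ys) + 1e-12) {
    stop("target grid lies outside the source field extent", call. = FALSE)
  }
  # pracma::interp2 expects Z as length(y)-rows x length(x)-cols
  xq <- rep(xp, times = length(yp))
  yq <- rep(yp, each = length(xp))
  z <- pracma::interp2(xs, ys, t(Z), pmin(pmax(xq, min(xs)), max(xs)),
                       pmin(pmax(yq, min(ys)), max(ys)), method = "linear")
  matrix(z, length(xp), length(yp))
}

#' @export
print.epk_scenario <- function(x, ...) {
  cat(sprintf(
    "<epk_scenario> theta=%.3f beta=%+.3f gamma=%.3f lambda=%.3f\n",
    x$theta, x$beta, x$gamma, x$lam))
  cat(sprintf("  healthy d=(%.3f, %.3f)  scar d=(%.4f, %.4f)  fast axis: %s\n",
              x$d0, x$d1, x$d0_scar, x$d1_scar, x$fast_axis))
  invisible(x)
}
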