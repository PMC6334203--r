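#' Cell-centred grid specification over the square domain
#'
#' The computational domain is \eqn{\Omega = [-2,2]^2}. Cells are squares of
#' side `4/nx` by `4/ny`; cell centres lie strictly inside the domain and the
#' homogeneous Dirichlet condition \eqn{v = 0} is imposed on the domain edge
#' (half a cell beyond the outermost centres).
#'
#' @param nx,ny Interior cell counts per side (>= 16).
#' @return An object of class `epk_grid` with spacings `dx`, `dy` and centre
#'   coordinates `xc`, `yc`.
#' @export
grid_spec <- function(nx = 128L, ny = nx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 16L || ny < 16L) stop("nx, ny must be >= 16", call. = FALSE)
  dx <- 4 / nx
  dy <- 4 / ny
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 xc = -2 + (seq_len(nx) - 0.5) * dx,
                 yc = -2 + (seq_len(ny) - 0.5) * dy),
            class = "epk_grid")
}

# admissible explicit time step for a diffusivity field (interior bound)
cfl_limit <- function(grid, d_max) min(grid$dx, grid$dy)^2 / (4 * d_max)

#' One explicit time step of the heterogeneous anisotropic diffusion equation
#'
#' Advances \eqn{\partial v/\partial t = \nabla\cdot(D \nabla v)} by one
#' explicit Euler step in flux-conservative form. `D` is diagonal with
#' per-cell entries `d0` (horizontal) and `d1` (vertical); face diffusivities
#' are arithmetic means of the adjacent cells. The boundary condition is
#' homogeneous Dirichlet, applied at the domain edge half a cell beyond the
#' outermost centres.
#'
#' @param v nx x ny matrix of cell values.
#' @param d_field List with matrices `d0`, `d1` as from [rasterise_field()].
#' @param dt Time increment; must satisfy
#'   `dt <= min(dx,dy)^2 / (4 * max(d))`.
#' @param grid An `epk_grid`.
#' @return Updated nx x ny matrix.
#' @export
diffusion_step <- function(v, d_field, dt, grid) {
  d_max <- max(d_field$d0, d_field$d1)
  lim <- cfl_limit(grid, d_max)
  if (dt > lim * (1 + 1e-12)) {
    stop(sprintf("dt = %g violates the explicit stability bound; use dt <= %g",
                 dt, lim), call. = FALSE)
  }
  v + dt * diffusion_rhs(v, d_field, grid)
}

# flux-conservative RHS nabla.(D nabla v) with zero Dirichlet edges
diffusion_rhs <- function(v, d_field, grid) {
  nx <- grid$nx; ny <- grid$ny
  d0 <- d_field$d0; d1 <- d_field$d1
  # x-direction: interior face coefficients (arithmetic mean), boundary faces
  # use the adjacent cell's diffusivity over the half-cell distance (factor 2)
  gxi <- 0.5 * (d0[-1, , drop = FALSE] + d0[-nx, , drop = FALSE]) *
    (v[-1, , drop = FALSE] - v[-nx, , drop = FALSE])       # (nx-1) x ny
  fx <- rbind(2 * d0[1, ] * v[1, ],                         # left edge flux*dx
              gxi,
              -2 * d0[nx, ] * v[nx, ])
  # divergence over faces: (F_{i+1/2} - F_{i-1/2}) / dx^2, F in gradient*dx units
  lx <- (fx[-1, , drop = FALSE] - fx[-(nx + 1), , drop = FALSE]) / grid$dx^2
  gyi <- 0.5 * (d1[, -1, drop = FALSE] + d1[, -ny, drop = FALSE]) *
    (v[, -1, drop = FALSE] - v[, -ny, drop = FALSE])
  fy <- cbind(2 * d1[, 1] * v[, 1], gyi, -2 * d1[, ny] * v[, ny])
  ly <- (fy[, -1, drop = FALSE] - fy[, -(ny + 1), drop = FALSE]) / grid$dy^2
  lx + ly
}

# 2x2 (or fxf) block-average restriction used to sample the solver grid onto
# the observable grid
restrict_field <- function(v, out_n) {
  n <- nrow(v)
  f <- n / out_n
  if (f != round(f)) stop("solver grid must be an integer multiple of out_n")
  f <- as.integer(f)
  if (f == 1L) return(v)
  idx <- rep(seq_len(out_n), each = f)
  rs <- rowsum(v, idx)              # sum rows in blocks
  t(rowsum(t(rs), idx)) / f^2
}

#' Simulate a scenario and return frames on the observable grid
#'
#' Runs the explicit solver with automatic sub-stepping under the stability
#' bound and stores `n_frames` snapshots `frame_interval` time units apart,
#' each restricted to an `out_n` x `out_n` grid by block averaging. The first
#' stored frame is the initial condition itself.
#'
#' @param scenario An `epk_scenario`.
#' @param v0 Initial condition on the solver grid (nx x ny matrix).
#' @param n_frames Number of stored frames (>= 14).
#' @param frame_interval Time between stored frames (default 1e-3).
#' @param grid Solver grid (default 128 x 128).
#' @param out_n Observable grid side (default 64).
#' @param safety Fraction of the stability limit used for sub-steps.
#' @return An object of class `epk_frames`: list with `frames` (array
#'   out_n x out_n x n_frames), `frame_interval`, `t0`, `scenario`.
#' @export
simulate_frames <- function(scenario, v0, n_frames = 20L,
                            frame_interval = 1e-3, grid = grid_spec(128L),
                            out_n = 64L, safety = 0.9) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 14L) stop("n_frames must be >= 14", call. = FALSE)
  simulate_frames_core(scenario, v0, n_frames, frame_interval, grid, out_n,
                       safety)
}

# core without the minimum-sequence-length contract; also used to produce
# short input-only windows (e.g. readout training pairs)
simulate_frames_core <- function(scenario, v0, n_frames, frame_interval,
                                 grid, out_n, safety = 0.9) {
  stopifnot(nrow(v0) == grid$nx, ncol(v0) == grid$ny)
  df <- rasterise_field(scenario, grid)
  d_max <- max(df$d0, df$d1)
  # the Dirichlet edge closure doubles the boundary-face coefficient, so
  # sub-step under the stricter corner bound min(dx,dy)^2 / (6 d_max)
  dt_stab <- safety * min(grid$dx, grid$dy)^2 / (6 * d_max)
  n_sub <- max(1L, ceiling(frame_interval / dt_stab))
  dt <- frame_interval / n_sub
  frames <- array(0, dim = c(out_n, out_n, n_frames))
  v <- v0
  frames[, , 1] <- restrict_field(v, out_n)
  for (k in 2:n_frames) {
    for (s in seq_len(n_sub)) v <- v + dt * diffusion_rhs(v, df, grid)
    if (!all(is.finite(v))) stop("solver produced non-finite values")
    frames[, , k] <- restrict_field(v, out_n)
  }
  structure(list(frames = frames, frame_interval = frame_interval, t0 = 0,
                 scenario = scenario, grid = grid, out_n = out_n),
            class = "epk_frames")
}

#' Generate and simulate a batch of random scenarios
#'
#' Draws `n` independent scenarios and initial fields (each from its own seed
#' derived from `seed`), simulates them, and collects the frame sequences in
#' an archive. With `out` set, the archive is serialised to disk (RDS) and
#' interrupted runs can be resumed bit-identically with `resume = TRUE`
#' because each simulation re-derives its own seed.
#'
#' @param n Number of simulations.
#' @param seed Master seed.
#' @param out Optional path for the serialised archive.
#' @param resume Continue a partial archive at `out` instead of refusing.
#' @param n_frames,frame_interval,grid,out_n Forwarded to [simulate_frames()].
#' @param gen_resolution Generation-grid resolution for initial fields.
#' @return An archive: list with `sims` (each holding `scenario` and `frames`)
#'   and `meta`.
#' @export
batch_simulate <- function(n, seed, out = NULL, resume = FALSE,
                           n_frames = 20L, frame_interval = 1e-3,
                           grid = grid_spec(128L), out_n = 64L,
                           gen_resolution = 128L) {
  sims <- vector("list", n)
  done <- 0L
  if (!is.null(out) && file.exists(out)) {
    if (!resume) stop(sprintf(
      "archive '%s' already exists; pass resume = TRUE to continue it", out),
      call. = FALSE)
    prev <- readRDS(out)
    done <- min(length(prev$sims), n)
    if (done > 0L) sims[seq_len(done)] <- prev$sims[seq_len(done)]
  }
  for (k in seq_len(n)) {
    if (k <= done) next
    sim_seed <- derive_seed(seed, paste0("sim", k))
    sc <- sample_scenario(seed = derive_seed(sim_seed, "scenario"))
    cfg <- sample_spectrum_config(seed = derive_seed(sim_seed, "spectrum"),
                                  gen_resolution = gen_resolution)
    fld <- generate_initial_field(cfg, seed = derive_seed(sim_seed, "field"))
    v0 <- interpolate_to_mesh(fld, grid)
    fr <- simulate_frames(sc, v0, n_frames = n_frames,
                          frame_interval = frame_interval, grid = grid,
                          out_n = out_n)
    sims[[k]] <- list(scenario = sc, frames = fr$frames, seed = sim_seed,
                      spectrum = cfg[c("alpha", "f_c", "f_0")])
    if (!is.null(out)) {
      saveRDS(list(sims = sims[seq_len(k)],
                   meta = archive_meta(n, seed, n_frames, frame_interval,
                                       grid, out_n)),
              out)
    }
  }
  arch <- list(sims = sims,
               meta = archive_meta(n, seed, n_frames, frame_interval, grid,
                                   out_n))
  if (!is.null(out)) saveRDS(arch, out)
  arch
}

archive_meta <- function(n, seed, n_frames, frame_interval, grid, out_n) {
  list(n = n, seed = seed, n_frames = n_frames,
       frame_interval = frame_interval, solver_nx = grid$nx, out_n = out_n)
}

#' @export
print.epk_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<epk_frames> %d frames of %dx%d, interval %g\n",
              d[3], d[1], d[2], x$frame_interval))
  invisible(x)
}
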