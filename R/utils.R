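#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic stage of a pipeline draws its own seed deterministically
#' from the run's master seed plus a short stage name, so that stages can be
#' re-run or resumed independently while the whole pipeline stays reproducible.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"sim3"`, `"train"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(master) %% m
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% m
  as.integer(h)
}

# Run `expr` under a local RNG seed when `seed` is non-NULL, otherwise use the
# ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# scalar checks used by constructors
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite scalar in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
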