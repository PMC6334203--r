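# Run configuration, reporting and provenance glue.

epk_default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    paths = list(out = "epmodkit_out"),
    scenario = list(n = 1600L, gen_resolution = 128L),
    simulate = list(n_frames = 20L, frame_interval = 1e-3,
                    solver_n = 128L, out_n = 64L),
    surrogate = list(kb = 3L, kt = 4L, k_out = 11L, epochs = 1000L,
                     batch = 64L, lr0 = 5e-4, weight_decay = 1e-5,
                     folds = 5L, val_frac = 0.2),
    readout = list(epochs = 60L, batch = 16L, lr = 1e-3),
    abc = list(n_particles = 500L, max_gens = 8L, eps_quantile = 0.5,
               eps_target = 1e-4, min_accept_rate = 0.01,
               adapt_population = FALSE)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected with the offending key named; missing keys are
#' filled with package defaults. The result round-trips losslessly through
#' [save_run_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list of class `epk_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(epk_default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "epk_run_config")
}

#' Save a run configuration to YAML
#' @param config An `epk_run_config` (or plain list).
#' @param path Output path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a machine-readable report bundle
#'
#' Emits `report.json` with all scalar metrics plus seed/config provenance,
#' one CSV per table, and (optionally) figures rendered by supplied closures.
#'
#' @param metrics Named list of scalar metrics (may be empty).
#' @param tables Named list of data frames written as `<name>.csv`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration embedded for provenance.
#' @param figures Optional named list of zero-argument functions; each is
#'   rendered to `<name>.png`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(metrics = list(), tables = list(), out_dir,
                         config = NULL, figures = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir),
                                 call. = FALSE)
  paths <- character()
  report <- list(package = "epmodkit",
                 version = as.character(utils::packageVersion("epmodkit")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 metrics = metrics,
                 config = if (!is.null(config)) unclass(config))
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, jp)
  for (nm in names(tables)) {
    tp <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  for (nm in names(figures)) {
    fp <- file.path(out_dir, paste0(nm, ".png"))
    grDevices::png(fp, width = 900, height = 700, res = 120)
    tryCatch(figures[[nm]](), finally = grDevices::dev.off())
    paths <- c(paths, fp)
  }
  invisible(paths)
}

#' Plot a posterior kernel density estimate
#' @param kde Output of [posterior_kde()].
#' @param truth Optional length-2 reference point drawn as cross-hairs.
#' @param ... Passed to [graphics::image()].
#' @export
plot_posterior_kde <- function(kde, truth = NULL, ...) {
  graphics::image(kde$x, kde$y, kde$z, col = grDevices::hcl.colors(64),
                  xlab = kde$pair[1], ylab = kde$pair[2], ...)
  graphics::contour(kde$x, kde$y, kde$z, add = TRUE, col = "grey30",
                    drawlabels = FALSE)
  if (!is.null(truth)) graphics::abline(v = truth[1], h = truth[2],
                                        lty = 2, col = "red")
  invisible(NULL)
}

#' Plot a posterior predictive envelope against observations
#' @param env One element of [posterior_predictive()] output.
#' @param observed Optional observed curve (data frame with `x`, `y`).
#' @param main Plot title.
#' @export
plot_predictive_envelope <- function(env, observed = NULL, main = "") {
  graphics::plot(env$x, env$median, type = "l", lwd = 2, col = "steelblue",
                 ylim = range(env$lo, env$hi, observed$y),
                 xlab = "x", ylab = "normalised response", main = main)
  graphics::polygon(c(env$x, rev(env$x)), c(env$lo, rev(env$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(env$x, env$median, lwd = 2, col = "steelblue")
  if (!is.null(observed)) graphics::points(observed$x, observed$y, pch = 4)
  invisible(NULL)
}
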