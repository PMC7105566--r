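#' Reproducible run configuration
#'
#' A serialisable record of everything a pipeline run depends on: seeds,
#' stimulation protocol, filter band, FDR settings, integration steps and
#' optimiser budgets.  Two runs with identical configurations produce
#' identical result files.
#'
#' @param seed master integer seed.
#' @param protocol a [stim_protocol()].
#' @param band filter band (Hz) or `NULL` for automatic selection.
#' @param q,lambda FDR level and Storey tuning parameter.
#' @param dt_coarse,dt_fine integration steps (s) for search/reporting.
#' @param n_trials blocks per synthetic experiment.
#' @param n_restarts,budget optimiser settings.
#' @param out_dir output directory for result tables.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, protocol = stim_protocol(), band = NULL,
                       q = 0.05, lambda = 0.05, dt_coarse = 1e-3,
                       dt_fine = 2.5e-4, n_trials = 120L,
                       n_restarts = 50L, budget = 40L,
                       out_dir = "results") {
  structure(list(seed = as.integer(seed), protocol = protocol,
                 band = band, q = q, lambda = lambda,
                 dt_coarse = dt_coarse, dt_fine = dt_fine,
                 n_trials = as.integer(n_trials),
                 n_restarts = as.integer(n_restarts),
                 budget = as.integer(budget), out_dir = out_dir),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `load_run_config()` returns the [run_config()];
#'   `save_run_config()` invisibly returns `path`.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  flat <- unclass(cfg)
  flat$protocol <- unclass(flat$protocol)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  flat <- yaml::read_yaml(path)
  proto <- do.call(stim_protocol, flat$protocol)
  flat$protocol <- NULL
  do.call(run_config, c(flat, list(protocol = proto)))
}
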