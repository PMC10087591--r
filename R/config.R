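#' Load and validate a run configuration
#'
#' Run configurations are YAML files with up to four sections:
#' `simulation` (the [sim_params()] fields), `sweep` (grids `betas` and
#' `ds`, plus `replicates` and `base_seed`), `estimator` (`weighting`,
#' `unanimity`) and top-level `output_dir` / `log_level`. Every omitted
#' field receives the package default; every present field is validated
#' against its owning module's ranges before any computation starts, and
#' unknown keys are errors (typo safety). A commented example ships at
#' `system.file("extdata", "example_config.yaml", package = "conformity")`.
#'
#' @param path Path to a YAML configuration file.
#' @return A fully populated list of class `run_config` with elements
#'   `simulation` (a `sim_params`), `sweep`, `estimator`, `output_dir`,
#'   `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("no such config file: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("simulation", "sweep", "estimator", "output_dir", "log_level")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim_fields <- names(formals(sim_params))
  sim_raw <- raw$simulation
  if (is.null(sim_raw)) sim_raw <- list()
  unknown <- setdiff(names(sim_raw), sim_fields)
  if (length(unknown)) {
    stop("unknown [simulation] key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim <- do.call(sim_params, sim_raw) # validates ranges, fills defaults
  sweep_fields <- c("betas", "ds", "replicates", "base_seed")
  sweep_raw <- raw$sweep
  if (is.null(sweep_raw)) sweep_raw <- list()
  unknown <- setdiff(names(sweep_raw), sweep_fields)
  if (length(unknown)) {
    stop("unknown [sweep] key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sweep <- list(
    betas = if (is.null(sweep_raw$betas)) sim$beta else as.numeric(sweep_raw$betas),
    ds = if (is.null(sweep_raw$ds)) sim$d else as.numeric(sweep_raw$ds),
    replicates = check_count(
      if (is.null(sweep_raw$replicates)) 20 else sweep_raw$replicates,
      "replicates"),
    base_seed = check_count(
      if (is.null(sweep_raw$base_seed)) sim$seed else sweep_raw$base_seed,
      "base_seed", 0))
  if (any(!is.finite(sweep$betas))) stop("non-finite value in `betas`", call. = FALSE)
  if (any(sweep$ds < 0 | sweep$ds > 1)) {
    stop("`ds` values must lie in [0, 1]", call. = FALSE)
  }
  est_fields <- c("weighting", "unanimity")
  est_raw <- raw$estimator
  if (is.null(est_raw)) est_raw <- list()
  unknown <- setdiff(names(est_raw), est_fields)
  if (length(unknown)) {
    stop("unknown [estimator] key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  estimator <- list(
    weighting = match.arg(if (is.null(est_raw$weighting)) "binomial" else est_raw$weighting,
                          c("binomial", "ols")),
    unanimity = match.arg(if (is.null(est_raw$unanimity)) "correct" else est_raw$unanimity,
                          c("correct", "drop")))
  log_level <- if (is.null(raw$log_level)) "info" else raw$log_level
  if (!log_level %in% c("quiet", "info", "debug")) {
    stop("`log_level` must be one of quiet, info, debug; got ", log_level,
         call. = FALSE)
  }
  structure(list(simulation = sim, sweep = sweep, estimator = estimator,
                 output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Serialise a run configuration back to YAML
#'
#' Writes every effective value (defaults included), so that
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  sim <- unclass(config$simulation)
  yaml::write_yaml(list(simulation = sim, sweep = config$sweep,
                        estimator = config$estimator,
                        output_dir = config$output_dir,
                        log_level = config$log_level), path)
  invisible(path)
}
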