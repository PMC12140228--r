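#' Write and read run configurations
#'
#' Human-edited configuration files are YAML with two top-level blocks:
#' `params` (any subset of [model_params()] arguments) and the remaining
#' [run_config()] arguments. Unknown keys are rejected with the offending
#' name, and every invariant of the config is re-validated on load, so a
#' round trip `write_run_config()` then `read_run_config()` is the
#' identity.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a validated [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  par_args <- raw$params
  raw$params <- NULL
  allowed_p <- names(formals(model_params))
  bad <- setdiff(names(par_args), allowed_p)
  if (length(bad) > 0) {
    stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "))
  }
  allowed_c <- setdiff(names(formals(run_config)), "params")
  bad <- setdiff(names(raw), allowed_c)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  params <- do.call(model_params, par_args)
  do.call(run_config, c(list(params = params), raw))
}

#' Write a run manifest
#'
#' JSON record of everything needed to reproduce a run: the full
#' configuration (every model constant, every design-decision switch such
#' as the adhesion law, the process-counting flag and the mismatch
#' permutation interval), the base seed and per-trial seeds, and the
#' package version.
#'
#' @param config A [run_config()].
#' @param path Output path (`.json`).
#' @param trials Trial indices covered by the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, trials = seq_len(config$n_trials)) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  manifest <- list(
    package = "chainmig",
    version = as.character(utils::packageVersion("chainmig")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    trials = trials,
    trial_seeds = config$base_seed + trials)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write and read trajectory / sample tables as CSV
#'
#' Plain CSV with typed headers; the largest in-scope runs are a few
#' hundred agents over a few hundred frames, so no binary format is
#' needed. `read_trajectory()` restores the column types used by the
#' evaluation layer.
#'
#' @param trajectory A trajectory or sample tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
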