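#' Load a structured run configuration
#'
#' Reads a YAML configuration shared by the command-line subcommands:
#' variable roles, model specifications, strategy stages, number of
#' imputations and seed. Keys: `roles` (outcome, covariates, auxiliary,
#' weight_predictors), `analysis` (outcome, terms, intercept), `block`,
#' `missing_code`, `stage1`, `stage2`, `imputer.stage1` (block,
#' conditionals), `imputer.stage2` (outcome, terms), `weightmodel.stage1`
#' / `weightmodel.stage2` (predictors, link), `M`, `seed`.
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The `yaml` package is required to read configuration files.")
  }
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  ## keep YAML-1.1 boolean-like scalars (Y, N, yes, no) as plain strings:
  ## they are far more likely to be variable names here
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(v) v,
    "bool#no" = function(v) v
  ))
}

#' Write a run manifest
#'
#' Records everything needed to replay a command: the seed, the command
#' line, md5 digests of the input files, an md5 of the configuration
#' content, the package version and a timestamp. Every command-line run
#' writes exactly one manifest alongside its outputs.
#'
#' @param path Output path for the manifest (JSON).
#' @param seed Integer seed used for the run.
#' @param command Character vector: the command line as invoked.
#' @param inputs Character vector of input file paths to digest.
#' @param config Optional configuration list to digest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, command, inputs = character(),
                               config = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("The `jsonlite` package is required to write manifests.")
  }
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  cfg_digest <- NULL
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(paste(deparse(config), collapse = "\n"), tf)
    cfg_digest <- unname(tools::md5sum(tf))
  }
  manifest <- list(
    package = "ipwmi",
    version = as.character(utils::packageVersion("ipwmi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    command = paste(command, collapse = " "),
    inputs = digests,
    config_md5 = cfg_digest
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
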