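.model_keys <- c(
  "k", "kP", "kb", "kd", "rho", "beta", "delta_sigma", "mode",
  "eta_birth_target", "Pstar", "width_dynamics"
)
.protocol_keys <- c(
  "n_cells", "k_pre", "k_post", "t_start", "t_end", "burn_in",
  "bin_min", "dt", "record_dt"
)
.io_keys <- c("out_dir", "prefix")

#' Read and write run configuration files
#'
#' Run configurations are YAML with up to four top-level sections:
#' `model` ([model_params()] fields), `protocol` ([protocol()] fields),
#' `io` (`out_dir`, `prefix`) and a scalar `seed`. Unknown keys anywhere
#' are rejected before any computation; omitted keys take the package
#' defaults, so an empty file is a valid configuration. A configuration
#' round-trips identically through `write_run_config()` /
#' `read_run_config()`.
#'
#' @param path File path.
#' @param config A list as returned by `read_run_config()`.
#' @return `read_run_config()` returns a validated list with elements
#'   `model`, `protocol`, `io`, `seed`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_run_config(list(model = list(k = 1), seed = 7), f)
#' read_run_config(f)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  unknown <- setdiff(names(config), c("model", "protocol", "io", "seed"))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  check_keys <- function(section, allowed, name) {
    if (is.null(section)) {
      return(list())
    }
    bad <- setdiff(names(section), allowed)
    if (length(bad)) {
      stop(sprintf(
        "unknown key(s) in config section '%s': %s",
        name, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    section
  }
  list(
    model = check_keys(config$model, .model_keys, "model"),
    protocol = check_keys(config$protocol, .protocol_keys, "protocol"),
    io = check_keys(config$io, .io_keys, "io"),
    seed = if (is.null(config$seed)) NULL else as.integer(config$seed)
  )
}

#' Build model parameters and a protocol from a configuration
#'
#' @param config A validated run configuration.
#' @return `config_model_params()` returns a [model_params()];
#'   `config_protocol()` a [protocol()].
#' @rdname read_run_config
#' @export
config_model_params <- function(config) {
  do.call(model_params, config$model)
}

#' @rdname read_run_config
#' @export
config_protocol <- function(config) {
  do.call(protocol, config$protocol)
}

# polynomial rolling hash (mod a 26-bit prime, exact in doubles) of the
# YAML serialisation; identifies a config in output headers without
# pulling in a hashing dependency
config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  h <- 17
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 67108859
  }
  sprintf("%08x", as.integer(h))
}

#' Write a simulation output CSV with a provenance header
#'
#' Writes `df` as CSV preceded by `#`-comment lines recording the seed and
#' a hash of the run configuration, so an output file identifies the run
#' that produced it. [read_output_csv()] skips the comment lines.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param seed Integer seed of the run (may be `NULL`).
#' @param config Run configuration list (may be `NULL`).
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", if (is.null(seed)) "NA" else seed), con)
  writeLines(sprintf(
    "# config_hash: %s",
    if (is.null(config)) "NA" else config_hash(config)
  ), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_output_csv
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
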