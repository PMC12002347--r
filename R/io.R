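#' Load a run configuration
#'
#' Reads a YAML (or JSON; YAML is a superset) run configuration, fills every
#' unset field from the model's reference defaults, and rejects unknown keys
#' with their full key path. An empty file therefore yields the complete
#' default configuration (ultrafast variant, gK = 9 nS, V1/2 = 15 mV,
#' lam = 0).
#'
#' Top-level sections: `parameters` (overrides of [model_parameters()]
#' fields), `noise` (`lam`, `bin_ms`), `protocol` (`plateau_ms`, `isi_ms`,
#' `t_total`, `t_first`), `seed`, `n_seeds`, `dt_out`.
#'
#' @param path configuration file path.
#' @return an `exp2_config` list with elements `parameters`
#'   (an `exp2_parameters` object), `noise`, `protocol`, `seed`, `n_seeds`,
#'   `dt_out`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  template <- list(
    parameters = as.list(formals(model_parameters)),
    noise = list(lam = 0, bin_ms = 1),
    protocol = list(plateau_ms = 250, isi_ms = 250, t_total = 5000,
                    t_first = 100),
    seed = 1L, n_seeds = 3L, dt_out = 0.5
  )
  check_keys <- function(got, allowed, prefix) {
    unknown <- setdiff(names(got), allowed)
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(prefix, unknown, collapse = ", "))
  }
  check_keys(raw, names(template), "")
  for (sect in c("parameters", "noise", "protocol"))
    if (!is.null(raw[[sect]]))
      check_keys(raw[[sect]], names(template[[sect]]), paste0(sect, "."))

  merged <- template
  for (k in names(raw)) {
    if (is.list(template[[k]]) && is.list(raw[[k]])) {
      for (kk in names(raw[[k]])) merged[[k]][[kk]] <- raw[[k]][[kk]]
    } else {
      merged[[k]] <- raw[[k]]
    }
  }
  cfg <- list(
    parameters = do.call(model_parameters, merged$parameters),
    noise = merged$noise,
    protocol = merged$protocol,
    seed = as.integer(merged$seed),
    n_seeds = as.integer(merged$n_seeds),
    dt_out = as.numeric(merged$dt_out)
  )
  class(cfg) <- "exp2_config"
  cfg
}

#' Write a resolved configuration next to run outputs
#'
#' @param cfg an `exp2_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- list(parameters = unclass(cfg$parameters), noise = cfg$noise,
              protocol = cfg$protocol, seed = cfg$seed,
              n_seeds = cfg$n_seeds, dt_out = cfg$dt_out)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Condition table CSV round trip
#'
#' Writes an experiment condition table as tidy CSV with a stable column
#' order and fixed floating-point precision (6 significant decimals); a
#' re-read equals the original to that precision.
#'
#' @param table an `exp2_conditions` data frame (or any data frame).
#' @param path file path.
#' @return `write_condition_table()` returns `path` invisibly;
#'   `read_condition_table()` returns the data frame.
#' @export
write_condition_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 6))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  read.csv(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the resolved
#' configuration, the seeds actually used, and the package version.
#'
#' @param path output JSON path.
#' @param config a list or `exp2_config` describing the run.
#' @param seeds integer vector of seeds used.
#' @param extra optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seeds, extra = NULL) {
  manifest <- c(list(
    package = "exp2plateau",
    version = as.character(utils::packageVersion("exp2plateau")),
    config = if (inherits(config, "exp2_config"))
      list(parameters = unclass(config$parameters), noise = config$noise,
           protocol = config$protocol, seed = config$seed,
           n_seeds = config$n_seeds, dt_out = config$dt_out) else config,
    seeds = as.integer(seeds)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
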