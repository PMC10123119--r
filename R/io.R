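#' Load model parameters from a YAML file
#'
#' Flat key-value parameter files, one per model variant, with a \code{model}
#' key selecting \code{"translation"} or \code{"degradation"}. Unknown keys
#' are rejected by the parameter constructors. Shipped defaults live under
#' \code{system.file("extdata", package = "mirburden")}.
#'
#' @param path YAML file path.
#' @return A [translation_params()] or [degradation_params()] object.
#' @examples
#' p <- load_params(system.file("extdata", "translation_default.yaml",
#'                              package = "mirburden"))
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  model <- raw$model
  if (is.null(model) || !model %in% c("translation", "degradation"))
    stop("parameter file must carry model: translation or degradation",
         call. = FALSE)
  raw$model <- NULL
  ctor <- if (model == "translation") translation_params else
    degradation_params
  unknown <- setdiff(names(raw), names(formals(ctor)))
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(ctor, raw)
}

#' Write model parameters to a YAML file
#' @param params a parameter object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  model <- if (inherits(params, "translation_params")) "translation" else
    "degradation"
  yaml::write_yaml(c(list(model = model), unclass(params)), path)
  invisible(path)
}

# allowed run-config keys and their defaults; t_end/tolerances follow the
# steady-state simulation protocol
RUN_CONFIG_DEFAULTS <- list(
  model = "translation",
  t_end = 10000, atol = 1e-9, rtol = 1e-6,
  sigma = c(0, 1),
  eta_min = 0.01, eta_max = 100, eta_n = 20,
  decay_eta = c(0, 1, 2, 4), decay_t_max = 12,
  lambda = 0.001,
  free = c("eta_unit", "lambda_TQ", "kappa_ratio"),
  noise_cv = 0,
  seed = 1,
  out_dir = ".",
  log_level = "info"
)

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, applies defaults (integration horizon
#' 10000 h, tolerances 1e-9/1e-6, seed 1), and rejects unknown keys by
#' name. The configuration round-trips exactly through
#' [write_run_config()].
#'
#' @param path YAML file path.
#' @return A named list of class \code{"run_config"}.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw),
                     c(names(RUN_CONFIG_DEFAULTS), "params_file"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, raw)
  if (!cfg$model %in% c("translation", "degradation"))
    stop("config key 'model' must be translation or degradation",
         call. = FALSE)
  if (!cfg$log_level %in% c("debug", "info", "warn", "quiet"))
    stop("config key 'log_level' must be one of debug/info/warn/quiet",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config a \code{"run_config"}.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}

#' Write run results and a manifest
#'
#' Serialises supported result objects into deterministic file names under
#' \code{out_dir} (long-format CSV for tables, JSON for fits), plus a
#' \code{manifest.json} recording the seed, package version, the files
#' written, a hash of the configuration, and the wall time.
#'
#' @param result an \code{"eta_sweep"}, a list of \code{"decay_profile"}s,
#'   a \code{"foldchange_fit"}, a fold-change data frame, or a
#'   \code{"steady_state_summary"}.
#' @param out_dir output directory (created if absent).
#' @param config optional \code{"run_config"} to hash into the manifest.
#' @param seed seed recorded in the manifest.
#' @return Character vector of files written (manifest last), invisibly.
#' @export
write_results <- function(result, out_dir, config = NULL, seed = NA) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (inherits(result, "eta_sweep")) {
    put_csv(as.data.frame(result), "sweep.csv")
  } else if (inherits(result, "foldchange_fit")) {
    f <- file.path(out_dir, "fit.json")
    jsonlite::write_json(list(coefficients = as.list(coef(result)),
                              loss = result$loss,
                              lambda = result$problem$lambda,
                              seed = result$seed,
                              iterations = result$iterations,
                              converged = result$converged),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    put_csv(summary(result)$table, "fit_table.csv")
  } else if (inherits(result, "steady_state_summary")) {
    put_csv(as.data.frame(result), "steady_state.csv")
  } else if (is.list(result) && length(result) &&
             all(vapply(result, inherits, logical(1), "decay_profile"))) {
    put_csv(do.call(rbind, lapply(result, as.data.frame)),
            "decay_profiles.csv")
  } else if (is.data.frame(result)) {
    put_csv(result, "table.csv")
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  manifest <- list(
    package = "mirburden",
    version = as.character(utils::packageVersion("mirburden")),
    seed = seed,
    config_hash = if (is.null(config)) NA else config_hash(config),
    files = basename(files),
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

# order-independent hash of a config list (no external digest dependency)
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  s <- paste(deparse(x), collapse = "")
  # simple 31-bit polynomial rolling hash over the serialised text
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
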