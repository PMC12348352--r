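# Run configuration: JSON (primary) or YAML, validated against the module
# schemas with unknown keys rejected by name.

.CONFIG_SCHEMA <- list(
  master_seed = NULL,
  output_dir = NULL,
  verbosity = NULL,
  field = c("axis", "sign", "strength"),
  landscape = c("saddle_rise_max", "transverse_stiffness"),
  fts = c("n_images", "max_iterations", "string_step", "displacement_cap",
          "smoothing_lambda", "convergence_tol", "convergence_window",
          "tensor_mode"),
  sampler = c("time_step", "mobility", "temperature", "n_steps",
              "burn_in_fraction", "spring"),
  pmf = c("n_refine", "n_windows", "window_n_steps", "refine_n_steps"),
  field_scan = c("seed", "phase", "noise_fraction"),
  kinetics = c("input_csv"),
  competition = c("proton_barriers", "conf_barriers", "labels"),
  grid = c("resolution")
)

#' Read and validate a run configuration
#'
#' JSON (`.json`) or YAML (`.yaml`/`.yml`). Unknown keys anywhere in the
#' file are rejected with a message naming the offending key.
#'
#' @param path Configuration file.
#' @return Validated configuration list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' Validate a run-configuration list
#'
#' @param cfg Named list of configuration sections.
#' @return `cfg` with class `"run_config"`; stops on unknown keys.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping of sections")
  unknown_top <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown_top))
    stop("unknown config key: ", unknown_top[1])
  for (sec in names(cfg)) {
    allowed <- .CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next  # scalar section
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown config key: ", sec, ".", bad[1])
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

# Build module objects out of a validated config (with defaults).
.config_field <- function(cfg) {
  f <- cfg$field
  if (is.null(f)) return(NULL)
  field_spec(axis = f$axis %||% "x", sign = f$sign %||% 1L,
             strength = f$strength %||% 0)
}

.config_landscape <- function(cfg) {
  l <- cfg$landscape
  build_default_landscape(saddle_rise_max = l$saddle_rise_max %||% 4.8)
}

.config_sampler <- function(cfg, seed) {
  s <- cfg$sampler
  sampler_config(time_step = s$time_step %||% 1e-3,
                 mobility = s$mobility %||% 1.0,
                 temperature = s$temperature %||% 298.15,
                 n_steps = s$n_steps %||% 2e4,
                 burn_in_fraction = s$burn_in_fraction %||% 0.1,
                 seed = seed,
                 spring = s$spring %||% 100.0)
}

.config_fts <- function(cfg, seed) {
  f <- cfg$fts
  fts_config(n_images = f$n_images %||% 20L,
             max_iterations = f$max_iterations %||% 100L,
             string_step = f$string_step %||% 15,
             displacement_cap = f$displacement_cap %||% 3,
             smoothing_lambda = f$smoothing_lambda %||% 0.1,
             convergence_tol = f$convergence_tol %||% 0.3,
             convergence_window = f$convergence_window %||% 5L,
             sampler = .config_sampler(cfg, seed),
             tensor_mode = f$tensor_mode %||% "identity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
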