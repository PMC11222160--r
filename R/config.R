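#' Pipeline configuration
#'
#' Validated configuration for a full membrane-processing run: input/output
#' paths, one parameter block per stage mirroring the stage's configuration
#' type, a global RNG seed and a log level. Unknown keys are rejected so
#' typos fail loudly; every run should write the resolved configuration next
#' to its outputs with [write_pipeline_config()].
#'
#' Stored on disk as YAML.
#'
#' @param paths named list of input/output paths.
#' @param templates,detect,curve,weaken,surface named lists of per-stage
#'   parameters (defaults applied per stage).
#' @param seed global integer seed for all stochastic stages.
#' @param log_level one of `"debug"`, `"info"`, `"warning"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), templates = list(),
                            detect = list(), curve = list(),
                            weaken = list(), surface = list(),
                            seed = 1, log_level = "info") {
  log_level <- match.arg(log_level, c("debug", "info", "warning"))
  known <- list(
    templates = c("kappa_min", "kappa_max", "n_templates", "length",
                  "image_size", "pixel_size"),
    detect = c("angle_step", "threshold", "nms_radius"),
    curve = c("angle_step", "search_radius"),
    weaken = c("mask_scale", "soft_edge", "along_window", "lambda"),
    surface = c("threshold", "bandwidth", "grid_spacing", "sigma",
                "thickness"))
  blocks <- list(templates = templates, detect = detect, curve = curve,
                 weaken = weaken, surface = surface)
  for (b in names(blocks)) {
    bad <- setdiff(names(blocks[[b]]), known[[b]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s' block: %s", b,
                   paste(bad, collapse = ", ")))
  }
  structure(c(list(paths = paths), blocks,
              list(seed = as.integer(seed), log_level = log_level)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_known <- c("paths", "templates", "detect", "curve", "weaken",
                 "surface", "seed", "log_level")
  bad <- setdiff(names(raw), top_known)
  if (length(bad))
    stop("unknown top-level key(s) in config: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write the resolved pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Log a timestamped message to standard error
#'
#' @param stage short stage tag.
#' @param ... message parts, passed to [paste0()].
#' @param level message level.
#' @param min_level suppress messages below this level.
#' @return invisibly, the formatted line.
#' @export
log_msg <- function(stage, ..., level = "info", min_level = "info") {
  levels <- c(debug = 1, info = 2, warning = 3)
  if (levels[[level]] < levels[[min_level]]) return(invisible(NULL))
  line <- sprintf("[%s] %s %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  toupper(level), stage, paste0(...))
  message(line)
  invisible(line)
}
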