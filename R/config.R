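# Run configuration: canonical parameter set, YAML load/save, validation.

#' Default run configuration
#'
#' The canonical parameter set of the pipeline: forward-beam delay
#' \code{delta = 10} and filter length \code{h = 21} (enforcing
#' \code{h = 2*delta + 1}), sample rate 32 kHz, 100 ms analysis frames with a
#' 12 kHz ceiling (\code{K = 1200} bins of 10 Hz; a 60 s scene gives
#' \code{L = 600} frames), 12 sub-bands of 1 kHz, low-frequency cutoff bin
#' \code{kL = 20}, floating-threshold factor \code{gamma1 = 20} (linear),
#' global-threshold ratio \code{epsilon = 1e5}, entropy guard
#' \code{xi = 1e-7}, subspace energy fraction \code{zeta = 0.95}, branch
#' count \code{Q = 3}, array spacing 1.06 cm with c = 340 m/s, 60 s scenes
#' at INR 40 dB with the interference at 150 degrees.
#'
#' @return An object of class \code{"run_config"} (named list).
#' @export
default_config <- function() {
  cfg <- list(
    delta = 10L, h = 21L,
    fs = 32000, d = 0.0106, c = 340,
    duration = 60, frame_len = 0.1, fmax = 12000,
    K = 1200L, L = 600L,
    I = 12L, B = 1000, kL = 20L, gamma1 = 20,
    epsilon = 1e5, xi = 1e-7, zeta = 0.95, Q = 3L,
    inr_db = 40, interference_angle = 150,
    seed = 1L)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Enforces the structural constraints: \code{h = 2*delta + 1}; all numeric
#' fields finite and positive where required; \code{K} and \code{L}
#' consistent with the frame length, ceiling and duration; no unknown keys.
#'
#' @param cfg a named list of parameters.
#' @return The validated \code{run_config}, invisibly classed.
#' @export
validate_config <- function(cfg) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  miss <- setdiff(known, names(cfg))
  if (length(miss))
    stop("missing configuration keys: ", paste(miss, collapse = ", "))
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1L &&
                  is.finite(v), logical(1))
  if (!all(num))
    stop("non-numeric or non-finite configuration values: ",
         paste(names(cfg)[!num], collapse = ", "))
  pos <- c("h", "fs", "d", "c", "duration", "frame_len", "fmax", "K", "L",
           "I", "B", "kL", "gamma1", "epsilon", "xi", "zeta", "Q")
  bad <- pos[vapply(pos, function(k) cfg[[k]] <= 0, logical(1))]
  if (length(bad))
    stop("configuration values must be positive: ", paste(bad, collapse = ", "))
  if (cfg$h != 2 * cfg$delta + 1)
    stop("validation error: h must equal 2*delta + 1 (got h = ", cfg$h,
         ", delta = ", cfg$delta, ")")
  if (cfg$zeta <= 0 || cfg$zeta > 1) stop("zeta must lie in (0, 1]")
  params <- spectrogram_params(cfg$fs, cfg$frame_len, cfg$fmax)
  if (cfg$K != params$K)
    stop("K = ", cfg$K, " inconsistent with frame_len/fmax (expected ",
         params$K, ")")
  if (cfg$L != as.integer(cfg$duration / cfg$frame_len))
    stop("L = ", cfg$L, " inconsistent with duration/frame_len (expected ",
         as.integer(cfg$duration / cfg$frame_len), ")")
  for (k in c("delta", "h", "K", "L", "I", "kL", "Q", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Missing keys fall back to \code{\link{default_config}}; unknown keys are
#' rejected; the merged configuration is validated. An empty file yields the
#' full default set.
#'
#' @param path path to a YAML file (possibly empty).
#' @return A validated \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config file must contain a key-value mapping")
  cfg <- unclass(default_config())
  extra <- setdiff(names(user), names(cfg))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg a \code{run_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.integer(v)) as.integer(v) else as.numeric(v)), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Geometry implied by a configuration
config_geometry <- function(cfg) array_geometry(cfg$d, cfg$c, cfg$fs)

# Short content hash of a configuration, for run logs
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf), add = TRUE)
  save_config(cfg, tf)
  unname(tools::md5sum(tf))
}
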