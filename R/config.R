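default_config <- function() {
  list(
    fps = 24,
    seed = 0,
    window = "full",
    window_seconds = NULL,
    arena = list(
      count = 1,
      precropped = FALSE,
      radius_range = NULL,
      diameter_mm = 11,
      mm_per_px = NULL
    ),
    seg = list(
      bg_window_px = 61,
      threshold = NULL,
      min_obj_px = 20,
      wing_divisor = 80,
      open_radius = 1,
      close_radius = 2
    ),
    identity = list(
      min_fly_area = 150,
      sc_sigma = 8,
      sc_max_points = 400,
      refresh_every = 24,
      dice_threshold = 1.6,
      tol_frac = 0.3,
      ecc_skip = c(0.5, 0.99),
      area_skip = c(0.5, 2),
      male_hint = NULL
    ),
    behavior = list(
      singing_deg = 30,
      orient_ext = 2.5,
      orient_halfangle = 10,
      contact_mm = 1,
      ecc_factor = 0.9,
      cop_seconds = 30,
      calib_mode = "auto",
      calib_frame = NULL,
      calib_window_s = 30,
      tap_skel_prune = 5,
      tap_erode_radius = 2,
      tap_denoise_px = 10
    ),
    filter = list(window = 12, min_hits = 5, none_gap = 12)
  )
}

#' Pipeline configuration
#'
#' Returns the full configuration with every behavioral-definition and
#' image-processing threshold at its rig default, overridden by the named
#' arguments. Overrides use the nested structure of the defaults (e.g.
#' `behavior = list(singing_deg = 35)`); unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param ... Named overrides of the default configuration sections.
#' @return A `flycourt_config` list.
#' @export
flycourt_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  cfg <- merge_config(cfg, over, path = "")
  structure(cfg, class = "flycourt_config")
}

merge_config <- function(base, over, path) {
  if (length(over) == 0) return(base)
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) stop("config overrides must be named", call. = FALSE)
  for (k in nm) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(base)) stop("unknown config key: ", full, call. = FALSE)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(over[[k]])) {
      base[[k]] <- merge_config(base[[k]], over[[k]], full)
    } else {
      base[k] <- list(over[[k]])
    }
  }
  base
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @return A `flycourt_config` (read); `path` invisibly (write).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(flycourt_config, raw)
}

#' @rdname read_config
#' @param cfg A `flycourt_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
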