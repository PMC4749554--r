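#' Analysis configuration
#'
#' Bundles the acquisition metadata and algorithm parameters used throughout
#' the pipeline. Defaults correspond to the standard high-resolution live-cell
#' acquisition (0.21 um pixels, 5 min frame interval) and the published
#' analysis settings: CMACs larger than 0.05 um^2 retained, moving-window MSD
#' over 24 frames fitted on the first 12 lags, membrane dynamics sampled over
#' 1..15-frame windows, cross-correlation lags of +/- 12 frames, and 100
#' permutations for correlation-difference nulls.
#'
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param frame_interval_min time between consecutive frames in minutes (> 0).
#' @param cmac_min_area_um2 CMACs with area less than or equal to this are
#'   discarded (um^2).
#' @param msd_window_frames moving-window length for MSD profiles (frames).
#' @param msd_fit_lags number of positive lags fitted; must not exceed half the
#'   window.
#' @param xcov_max_lag_frames maximum lag (frames) for protrusion-retraction
#'   cross-correlation profiles.
#' @param dynamics_windows integer vector of time-window sizes (frames) for
#'   membrane dynamics.
#' @param n_permutations permutations used for correlation-difference nulls.
#' @param rng_seed integer seed recorded with the configuration; `NULL` leaves
#'   the RNG untouched.
#' @return An object of class `cellmig_config` (a named list).
#' @examples
#' cfg <- cellmig_config()
#' cfg$pixel_size_um
#' @export
cellmig_config <- function(pixel_size_um = 0.21,
                           frame_interval_min = 5,
                           cmac_min_area_um2 = 0.05,
                           msd_window_frames = 24L,
                           msd_fit_lags = 12L,
                           xcov_max_lag_frames = 12L,
                           dynamics_windows = 1:15,
                           n_permutations = 100L,
                           rng_seed = NULL) {
  stopifnot(pixel_size_um > 0, frame_interval_min > 0, cmac_min_area_um2 > 0,
            msd_window_frames > 0, msd_fit_lags > 0, xcov_max_lag_frames > 0,
            all(dynamics_windows >= 1), n_permutations > 0)
  if (msd_fit_lags > msd_window_frames / 2)
    stop("msd_fit_lags must be <= msd_window_frames / 2")
  structure(list(
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min,
    cmac_min_area_um2 = cmac_min_area_um2,
    msd_window_frames = as.integer(msd_window_frames),
    msd_fit_lags = as.integer(msd_fit_lags),
    xcov_max_lag_frames = as.integer(xcov_max_lag_frames),
    dynamics_windows = as.integer(dynamics_windows),
    n_permutations = as.integer(n_permutations),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "cellmig_config")
}

#' @export
print.cellmig_config <- function(x, ...) {
  cat("cellmig analysis configuration\n")
  cat(sprintf("  pixel size        : %g um\n", x$pixel_size_um))
  cat(sprintf("  frame interval    : %g min\n", x$frame_interval_min))
  cat(sprintf("  CMAC min area     : %g um^2\n", x$cmac_min_area_um2))
  cat(sprintf("  MSD window / lags : %d frames / %d lags\n",
              x$msd_window_frames, x$msd_fit_lags))
  cat(sprintf("  xcov max lag      : %d frames\n", x$xcov_max_lag_frames))
  cat(sprintf("  dynamics windows  : %s frames\n",
              paste(range(x$dynamics_windows), collapse = "..")))
  cat(sprintf("  permutations      : %d\n", x$n_permutations))
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a JSON or YAML file whose keys mirror the arguments of
#' [cellmig_config()]; unknown keys are rejected.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `cellmig_config` object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml, got: ", ext)
  )
  known <- names(formals(cellmig_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(cellmig_config, vals)
}
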