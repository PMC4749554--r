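# Nearest-neighbour tracking of cells and CMACs, trajectory smoothing,
# CMAC filtering and lifetime.

# Per-frame region properties of a label image. Coordinates are 0-based pixel
# indices converted to um at pixel centers; x = column, y = row.
.regionprops <- function(frame, pixel_size_um) {
  idx <- which(frame != 0L)
  if (!length(idx))
    return(data.frame(label_id = integer(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), area_um2 = numeric()))
  rc <- arrayInd(idx, dim(frame))
  lab <- frame[idx]
  npx <- tapply(lab, lab, length)
  cy <- tapply(rc[, 1] - 1L, lab, mean) * pixel_size_um
  cx <- tapply(rc[, 2] - 1L, lab, mean) * pixel_size_um
  labels <- as.integer(names(npx))
  o <- order(labels)   # tapply sorts level names as character
  data.frame(label_id = labels[o],
             centroid_x_um = as.numeric(cx)[o],
             centroid_y_um = as.numeric(cy)[o],
             area_um2 = as.numeric(npx)[o] * pixel_size_um^2)
}

#' Exclude cells touching the image border
#'
#' Any label with at least one pixel on the image boundary in a given frame is
#' removed from that frame (set to background). Applied per frame, so a cell
#' may be present in some frames and excluded in others.
#'
#' @param movie a cell-layer [label_movie()].
#' @return A `label_movie` with border-touching labels zeroed per frame.
#' @export
exclude_border_cells <- function(movie) {
  stopifnot(inherits(movie, "label_movie"))
  frames <- lapply(movie$frames, function(f) {
    border <- unique(c(f[1, ], f[nrow(f), ], f[, 1], f[, ncol(f)]))
    border <- setdiff(border, 0L)
    if (length(border)) f[f %in% border] <- 0L
    f
  })
  label_movie(frames, movie$pixel_size_um, movie$frame_interval_min,
              movie$layer)
}

# Mutual-nearest-neighbour links between two centroid sets within a gate.
# Returns integer pairs (i = index into prev, j = index into curr).
.mutual_nearest_links <- function(prev, curr, gate_um) {
  if (!nrow(prev) || !nrow(curr)) return(cbind(i = integer(), j = integer()))
  dx <- outer(prev$centroid_x_um, curr$centroid_x_um, "-")
  dy <- outer(prev$centroid_y_um, curr$centroid_y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  # ties broken by smaller distance then lower label id (order() is stable on
  # the label-sorted frames)
  nn_fwd <- apply(d, 1, which.min)
  nn_bwd <- apply(d, 2, which.min)
  i <- seq_len(nrow(prev))
  j <- nn_fwd
  mutual <- nn_bwd[j] == i
  within <- d[cbind(i, j)] <= gate_um[i]
  keep <- mutual & within
  cbind(i = i[keep], j = j[keep])
}

#' Track labelled objects across frames
#'
#' Frame-to-frame nearest-neighbour tracking: an object is linked to the
#' object in the next frame whose centroid is nearest, provided the two are
#' mutually nearest and within a distance gate. Unmatched objects terminate or
#' start tracks; there is no gap closing, so every track covers strictly
#' consecutive frames.
#'
#' The default gate is 3 object radii (radius from area, `sqrt(A/pi)`) for the
#' cell layer and 2 um for the CMAC layer.
#'
#' @param movie a [label_movie()].
#' @param max_displacement_um scalar gate in um, or `NULL` for the
#'   layer-specific default.
#' @return A track table `data.frame` with columns track_id, layer, frame,
#'   label_id, centroid_x_um, centroid_y_um, smoothed_x_um, smoothed_y_um,
#'   area_um2. Frames are numbered from 0. Smoothed coordinates are filled by
#'   [smooth_tracks()]; here they equal the raw centroids.
#' @export
track_objects <- function(movie, max_displacement_um = NULL) {
  stopifnot(inherits(movie, "label_movie"))
  props <- lapply(movie$frames, .regionprops, pixel_size_um = movie$pixel_size_um)
  out <- list()
  next_id <- 1L
  open <- data.frame(track_id = integer(), label_id = integer(),
                     centroid_x_um = numeric(), centroid_y_um = numeric(),
                     area_um2 = numeric())
  for (t in seq_along(props)) {
    curr <- props[[t]]
    assigned <- rep(NA_integer_, nrow(curr))
    if (nrow(open)) {
      gate <- if (!is.null(max_displacement_um)) {
        rep(max_displacement_um, nrow(open))
      } else if (movie$layer == "cell") {
        3 * sqrt(open$area_um2 / pi)
      } else rep(2, nrow(open))
      links <- .mutual_nearest_links(open, curr, gate)
      assigned[links[, "j"]] <- open$track_id[links[, "i"]]
    }
    new <- is.na(assigned)
    if (any(new)) {
      assigned[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    if (nrow(curr))
      out[[t]] <- data.frame(track_id = assigned, layer = movie$layer,
                             frame = t - 1L, label_id = curr$label_id,
                             centroid_x_um = curr$centroid_x_um,
                             centroid_y_um = curr$centroid_y_um,
                             smoothed_x_um = curr$centroid_x_um,
                             smoothed_y_um = curr$centroid_y_um,
                             area_um2 = curr$area_um2)
    open <- if (nrow(curr)) cbind(track_id = assigned, curr) else open[0, ]
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(track_id = integer(), layer = character(),
                         frame = integer(), label_id = integer(),
                         centroid_x_um = numeric(), centroid_y_um = numeric(),
                         smoothed_x_um = numeric(), smoothed_y_um = numeric(),
                         area_um2 = numeric())
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Smooth a single trajectory with a cubic smoothing spline
#'
#' The smoothing parameter `p` follows the penalized-spline convention on
#' `[0, 1]`: `p = 1` reproduces the input exactly (pure interpolation),
#' `p = 0` yields the least-squares straight line, intermediate values trade
#' fidelity against curvature (internally `lambda = (1 - p) / p` for
#' [stats::smooth.spline()]). With `p = NULL` the penalty is chosen by
#' generalized cross-validation. Trajectories with fewer than 4 points are
#' passed through unchanged and flagged.
#'
#' @param x,y coordinates (um), ordered by time.
#' @param t time values (defaults to equal spacing).
#' @param p smoothing parameter in `[0, 1]`, or `NULL` for GCV.
#' @return list with `x`, `y` (smoothed) and `smoothed` flag.
#' @export
smooth_trajectory <- function(x, y, t = seq_along(x), p = NULL) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite coordinates")
  stopifnot(length(x) == length(y), length(t) == length(x))
  if (length(x) < 4)
    return(list(x = x, y = y, smoothed = FALSE))
  fit1 <- function(v) {
    if (!is.null(p)) {
      stopifnot(p >= 0, p <= 1)
      if (p == 1) return(v)
      if (p == 0) return(as.vector(stats::fitted(stats::lm(v ~ t))))
      # csaps-style balance: smooth.spline rescales t to [0,1], so the
      # penalty is put on the scale of the cube of the mean knot spacing
      h <- 1 / (length(t) - 1)
      lam <- (1 - p) / p * h^3 / 6
      as.vector(stats::predict(stats::smooth.spline(t, v, lambda = lam,
                                                    all.knots = TRUE), t)$y)
    } else {
      as.vector(stats::predict(stats::smooth.spline(t, v, cv = FALSE), t)$y)
    }
  }
  list(x = fit1(x), y = fit1(y), smoothed = TRUE)
}

#' Smooth all cell trajectories in a track table
#'
#' Fills `smoothed_x_um` / `smoothed_y_um` per track. By default only the cell
#' layer is smoothed; CMAC trajectories keep raw centroids.
#'
#' @param tracks a track table from [track_objects()].
#' @param p smoothing parameter (see [smooth_trajectory()]).
#' @param layers layers to smooth.
#' @return The track table with smoothed coordinates filled in.
#' @export
smooth_tracks <- function(tracks, p = NULL, layers = "cell") {
  for (id in unique(tracks$track_id[tracks$layer %in% layers])) {
    sel <- which(tracks$track_id == id & tracks$layer %in% layers)
    sm <- smooth_trajectory(tracks$centroid_x_um[sel],
                            tracks$centroid_y_um[sel],
                            t = tracks$frame[sel], p = p)
    tracks$smoothed_x_um[sel] <- sm$x
    tracks$smoothed_y_um[sel] <- sm$y
  }
  tracks
}

#' Filter CMAC tracks and compute lifetimes
#'
#' Applies the published CMAC quality rules: observations with area at or
#' below `cmac_min_area_um2` (default 0.05 um^2) are removed; tracks (or the
#' consecutive runs remaining after area filtering) shorter than 3 consecutive
#' frames are removed; lifetime is `n_frames * frame_interval_min` and is
#' undefined (NA) for tracks present in the first or last frame of the
#' sequence, which are excluded from lifetime statistics only.
#'
#' @param cmac_tracks a CMAC-layer track table.
#' @param config a [cellmig_config()].
#' @param n_frames_total number of frames in the movie (needed to detect
#'   tracks touching the sequence end; defaults to `max(frame) + 1`).
#' @return list with `tracks` (filtered track table, re-labelled so every
#'   track is gap-free) and `summary` (data.frame: track_id, n_frames,
#'   lifetime_min, touches_boundary).
#' @export
filter_cmacs <- function(cmac_tracks, config = cellmig_config(),
                         n_frames_total = NULL) {
  if (is.null(n_frames_total)) n_frames_total <- max(cmac_tracks$frame) + 1L
  keep <- cmac_tracks$area_um2 > config$cmac_min_area_um2
  tr <- cmac_tracks[keep, , drop = FALSE]
  if (nrow(tr)) {
    tr <- tr[order(tr$track_id, tr$frame), , drop = FALSE]
    # split at frame gaps introduced by area filtering
    new_run <- c(TRUE, diff(tr$frame) != 1L | diff(tr$track_id) != 0L)
    tr$track_id <- cumsum(new_run)
  }
  runs <- if (nrow(tr)) table(tr$track_id) else integer(0)
  long <- as.integer(names(runs))[runs >= 3L]
  tr <- tr[tr$track_id %in% long, , drop = FALSE]
  summ <- do.call(rbind, lapply(long, function(id) {
    fr <- tr$frame[tr$track_id == id]
    touches <- min(fr) == 0L || max(fr) == n_frames_total - 1L
    data.frame(track_id = id, n_frames = length(fr),
               lifetime_min = if (touches) NA_real_
                              else length(fr) * config$frame_interval_min,
               touches_boundary = touches)
  }))
  if (is.null(summ))
    summ <- data.frame(track_id = integer(), n_frames = integer(),
                       lifetime_min = numeric(), touches_boundary = logical())
  list(tracks = tr, summary = summ)
}
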