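# Per-(cell, frame) organizational features, CMAC intensity correction and
# standardization, and assembly of the feature table.

# 4-connected boundary pixels of a binary mask.
.boundary_pixels <- function(mask) {
  m <- mask
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
              pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  m & !(interior & m)
}

# Perimeter estimate: count 4-connected exposed pixel edges and apply the
# pi/4 staircase correction (the Manhattan perimeter of a convex digital
# region overestimates the Euclidean contour by 4/pi), so digital disks score
# compactness near 1.
.perimeter_px <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  exposed <- sum(pad[2:(h + 1L), 2:(w + 1L)] & !pad[1:h, 2:(w + 1L)]) +
             sum(pad[2:(h + 1L), 2:(w + 1L)] & !pad[3:(h + 2L), 2:(w + 1L)]) +
             sum(pad[2:(h + 1L), 2:(w + 1L)] & !pad[2:(h + 1L), 1:w]) +
             sum(pad[2:(h + 1L), 2:(w + 1L)] & !pad[2:(h + 1L), 3:(w + 2L)])
  exposed * pi / 4
}

# Exact Euclidean distance (um) from each TRUE pixel of `from` to the nearest
# pixel of `to`; brute force over boundary pixels (masks are single cells, so
# boundary sets are small).
.dist_to_set_um <- function(px_rc, set_rc, pixel_size_um) {
  if (!nrow(set_rc)) return(rep(NA_real_, nrow(px_rc)))
  d2 <- outer(px_rc[, 1], set_rc[, 1], "-")^2 +
        outer(px_rc[, 2], set_rc[, 2], "-")^2
  sqrt(apply(d2, 1, min)) * pixel_size_um
}

#' Cell shape features from a single-cell mask
#'
#' Area is the pixel count times the pixel area. Compactness is
#' `4 * pi * area / perimeter^2`, which equals 1 for a circle and decreases
#' for elongated or ruffled outlines; the perimeter comes from a
#' corrected edge-count contour-length estimate.
#'
#' @param mask logical (or 0/1) matrix, a single cell footprint.
#' @param pixel_size_um pixel size in um.
#' @return list with `area_um2` and `compactness`.
#' @export
compute_cell_shape <- function(mask, pixel_size_um = 0.21) {
  mask <- mask != 0
  npx <- sum(mask)
  if (npx == 0) stop("empty mask")
  area <- npx * pixel_size_um^2
  per <- .perimeter_px(mask) * pixel_size_um
  list(area_um2 = area, compactness = min(1, 4 * pi * area / per^2))
}

#' Per-cell CMAC aggregates
#'
#' Counts the CMACs assigned to a cell and summarizes their areas and their
#' centroid distances to the nearest cell-boundary pixel. With zero CMACs the
#' aggregates are undefined (`NA`), never 0.
#'
#' @param cell_mask logical matrix, the cell footprint.
#' @param cmac_masks list of logical matrices (same shape), one per CMAC.
#' @param pixel_size_um pixel size in um.
#' @return list with `cmac_count`, `cmac_area_median_um2`,
#'   `cmac_area_total_um2`, `cmac_distance_to_border_median_um`.
#' @export
compute_cmac_aggregates <- function(cell_mask, cmac_masks, pixel_size_um = 0.21) {
  n <- length(cmac_masks)
  if (n == 0)
    return(list(cmac_count = 0L, cmac_area_median_um2 = NA_real_,
                cmac_area_total_um2 = NA_real_,
                cmac_distance_to_border_median_um = NA_real_))
  areas <- vapply(cmac_masks, function(m) sum(m != 0), numeric(1)) * pixel_size_um^2
  boundary <- which(.boundary_pixels(cell_mask != 0), arr.ind = TRUE)
  cents <- t(vapply(cmac_masks, function(m) {
    rc <- which(m != 0, arr.ind = TRUE)
    c(mean(rc[, 1]), mean(rc[, 2]))
  }, numeric(2)))
  d <- .dist_to_set_um(cents, boundary, pixel_size_um)
  list(cmac_count = n,
       cmac_area_median_um2 = stats::median(areas),
       cmac_area_total_um2 = sum(areas),
       cmac_distance_to_border_median_um = stats::median(d))
}

# Disk-shaped structuring-element dilation of a mask by radius_px pixels
# (Euclidean), brute force via distance to mask pixels on a bounding box.
.dilate_disk <- function(mask, radius_px) {
  rc <- which(mask, arr.ind = TRUE)
  if (!nrow(rc)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(radius_px)
  rows <- max(1, min(rc[, 1]) - r):min(h, max(rc[, 1]) + r)
  cols <- max(1, min(rc[, 2]) - r):min(w, max(rc[, 2]) + r)
  out <- mask
  cand <- as.matrix(expand.grid(row = rows, col = cols))
  d2 <- outer(cand[, 1], rc[, 1], "-")^2 + outer(cand[, 2], rc[, 2], "-")^2
  hit <- apply(d2, 1, min) <= radius_px^2
  out[cand[hit, , drop = FALSE]] <- TRUE
  out
}

#' Background-corrected CMAC intensity
#'
#' Mean intensity over the CMAC footprint minus the mean intensity in a 1 um
#' annulus around it, excluding pixels belonging to any other segmented CMAC.
#' If the annulus is empty (fully occupied by other CMACs or outside the
#' image) the corrected value is undefined and flagged.
#'
#' @param cmac_mask logical matrix for the CMAC of interest.
#' @param intensity numeric matrix, same shape.
#' @param all_cmac_mask logical matrix marking every segmented CMAC pixel
#'   (including this one).
#' @param pixel_size_um pixel size in um.
#' @param annulus_um annulus radius (um), default 1.
#' @return list with `corrected` (NA if undefined) and `undefined` flag.
#' @export
correct_cmac_intensity <- function(cmac_mask, intensity, all_cmac_mask,
                                   pixel_size_um = 0.21, annulus_um = 1) {
  cmac_mask <- cmac_mask != 0
  if (!sum(cmac_mask)) stop("empty CMAC mask")
  if (!all(dim(cmac_mask) == dim(intensity)))
    stop("mask/intensity shape mismatch")
  dil <- .dilate_disk(cmac_mask, annulus_um / pixel_size_um)
  annulus <- dil & !cmac_mask & !(all_cmac_mask != 0)
  if (!sum(annulus))
    return(list(corrected = NA_real_, undefined = TRUE))
  list(corrected = mean(intensity[cmac_mask]) - mean(intensity[annulus]),
       undefined = FALSE)
}

#' Standardize corrected CMAC intensities per repeat
#'
#' Corrected intensities are divided, per experimental repeat, by the median
#' corrected intensity of reference-size CMACs (area in `[0.15, 0.2]` um^2) of
#' the reference condition in that repeat. The reference set's median maps to
#' 1 and the result is invariant to global linear intensity scaling within a
#' repeat.
#'
#' @param values numeric corrected intensities to standardize.
#' @param repeat_id repeat identifier per value.
#' @param ref a data.frame of reference CMACs with columns `repeat_id`,
#'   `area_um2`, `corrected` (typically the reference condition's CMACs).
#' @param size_range reference area window in um^2.
#' @return numeric vector of standardized values.
#' @export
standardize_intensity <- function(values, repeat_id, ref,
                                  size_range = c(0.15, 0.2)) {
  stopifnot(length(values) == length(repeat_id))
  out <- rep(NA_real_, length(values))
  for (rep_id in unique(repeat_id)) {
    rsel <- ref$repeat_id == rep_id &
      ref$area_um2 >= size_range[1] & ref$area_um2 <= size_range[2] &
      is.finite(ref$corrected)
    if (!any(rsel))
      stop("no reference-size CMACs (", size_range[1], "-", size_range[2],
           " um^2) in repeat: ", rep_id)
    med <- stats::median(ref$corrected[rsel])
    if (med <= 0) stop("non-positive reference median in repeat: ", rep_id)
    out[repeat_id == rep_id] <- values[repeat_id == rep_id] / med
  }
  out
}

# ---- feature registry -------------------------------------------------------

.feature_registry <- new.env(parent = emptyenv())

#' Register a custom organizational feature
#'
#' The built-in feature set covers a named representative subset of the full
#' organizational catalogue; additional features can be plugged in. The
#' function receives the per-observation context list (`cell_mask`,
#' `cmac_masks`, `intensity`, `pixel_size_um`) and must return a scalar.
#'
#' @param name feature (column) name.
#' @param fn function of one argument (the context list).
#' @return `name`, invisibly.
#' @export
register_feature <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .feature_registry)
  invisible(name)
}

#' @rdname register_feature
#' @export
registered_features <- function() ls(.feature_registry)

#' Assemble the per-(cell, frame) feature table
#'
#' Joins per-observation organizational features, behavioral features (speed)
#' and mode labels into one row per (cell, frame), dropping observations whose
#' mode is `null`. CMAC aggregates stay `NA` (not 0) where a cell has no
#' CMACs. Feature values are carried over unchanged from the inputs.
#'
#' @param observations data.frame keyed by (cell_track_id, frame) with feature
#'   columns.
#' @param mode_labels a mode-label table (cell_track_id, frame, mode,
#'   condition, repeat_id).
#' @param speed optional data.frame (cell_track_id, frame,
#'   cell_speed_um_per_min).
#' @return A feature table data.frame (keys first, then features).
#' @export
assemble_feature_table <- function(observations, mode_labels, speed = NULL) {
  key <- function(d) paste(d$cell_track_id, d$frame, sep = "\r")
  mk <- key(mode_labels)
  ok <- key(observations)
  missing <- setdiff(ok, mk)
  if (length(missing))
    stop("observations without mode labels for keys: ",
         paste(utils::head(gsub("\r", ":", missing), 5), collapse = ", "))
  m <- mode_labels[match(ok, mk), c("mode", "condition", "repeat_id")]
  out <- cbind(observations[c("cell_track_id", "frame")], m,
               observations[setdiff(names(observations),
                                    c("cell_track_id", "frame"))])
  if (!is.null(speed)) {
    sk <- key(speed)
    out$cell_speed_um_per_min <- speed$cell_speed_um_per_min[match(ok, sk)]
  }
  out <- out[out$mode != "null", , drop = FALSE]
  rownames(out) <- NULL
  out
}
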