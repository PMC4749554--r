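# Data model and I/O: label/intensity movies, feature and mode-label tables,
# blinding manifests and mode-frequency summaries.

#' Construct a label movie
#'
#' A label movie is an ordered list of 2-D integer label images (one per time
#' frame) plus its acquisition metadata. Label 0 is background; pixel indices
#' are 0-based (row, col) and physical coordinates are `index * pixel_size_um`
#' at pixel centers.
#'
#' @param frames list of integer matrices, all of identical shape.
#' @param pixel_size_um pixel size in micrometres.
#' @param frame_interval_min frame interval in minutes.
#' @param layer `"cell"` or `"cmac"`.
#' @return A `label_movie` object.
#' @export
label_movie <- function(frames, pixel_size_um = 0.21, frame_interval_min = 5,
                        layer = c("cell", "cmac")) {
  layer <- match.arg(layer)
  stopifnot(is.list(frames), length(frames) > 0,
            pixel_size_um > 0, frame_interval_min > 0)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1)
    stop("format error: frames have mixed shapes")
  if (!all(vapply(frames, function(f) all(f == round(f)) && all(f >= 0),
                  logical(1))))
    stop("format error: label frames must contain non-negative integers")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min, layer = layer),
            class = "label_movie")
}

#' @export
print.label_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("label_movie [%s layer]: %d frames of %dx%d px (%g um/px, %g min/frame)\n",
              x$layer, length(x$frames), d[1], d[2],
              x$pixel_size_um, x$frame_interval_min))
  cat("objects per frame:", paste(object_counts(x), collapse = " "), "\n")
  invisible(x)
}

#' Number of distinct labelled objects per frame
#' @param movie a `label_movie`.
#' @return Integer vector, one count per frame.
#' @export
object_counts <- function(movie) {
  vapply(movie$frames, function(f) length(setdiff(unique(as.vector(f)), 0L)),
         integer(1))
}

#' Read a label movie from a multi-page TIFF
#'
#' @param path multi-page TIFF of integer label images.
#' @param config a [cellmig_config()] supplying pixel size and frame interval.
#' @param layer `"cell"` or `"cmac"`.
#' @return A `label_movie`; object counts per frame are available via
#'   [object_counts()].
#' @export
read_label_movie <- function(path, config = cellmig_config(),
                             layer = c("cell", "cmac")) {
  frames <- read_tiff_stack(path)
  if (!all(vapply(frames, function(f) all(f == round(f)), logical(1))))
    stop("format error: non-integer pixel type in label TIFF: ", path)
  label_movie(frames, pixel_size_um = config$pixel_size_um,
              frame_interval_min = config$frame_interval_min,
              layer = match.arg(layer))
}

#' Construct / read an intensity movie aligned to a label movie
#'
#' @param frames list of numeric matrices.
#' @param channel `"paxillin"`, `"lifeact"` or `"other"`.
#' @return An `intensity_movie` object.
#' @export
intensity_movie <- function(frames, channel = c("paxillin", "lifeact", "other")) {
  channel <- match.arg(channel)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stop("format error: frames have mixed shapes")
  structure(list(frames = frames, channel = channel), class = "intensity_movie")
}

#' @rdname intensity_movie
#' @param path multi-page TIFF of intensity images.
#' @export
read_intensity_movie <- function(path, channel = c("paxillin", "lifeact", "other")) {
  intensity_movie(read_tiff_stack(path), channel = match.arg(channel))
}

# ---- tables -----------------------------------------------------------------

.mode_levels <- c("Discontinuous", "Continuous", "null")

.required_cols <- list(
  mode_labels = c("cell_track_id", "frame", "mode", "condition", "repeat_id"),
  features = c("cell_track_id", "frame", "condition", "repeat_id", "mode"),
  tracks = c("track_id", "layer", "frame", "label_id",
             "centroid_x_um", "centroid_y_um")
)

.check_table <- function(df, schema, path = "<data.frame>") {
  req <- .required_cols[[schema]]
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  keycols <- if (schema == "tracks") c("track_id", "frame")
             else c("cell_track_id", "frame")
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  if (anyDuplicated(key))
    stop("schema error in ", path, ": duplicate (", paste(keycols, collapse = ", "),
         ") keys")
  df
}

#' Read / write pipeline tables as CSV
#'
#' CSV is the canonical table format. `schema` selects the required columns:
#' `"mode_labels"` (cell_track_id, frame, mode, condition, repeat_id),
#' `"features"` (the same keys plus feature columns) or `"tracks"`.
#' Writing uses full float precision (15 significant digits) so a
#' write-then-read round trip is an identity at >= 12 significant digits.
#'
#' @param path CSV file path.
#' @param schema one of `"mode_labels"`, `"features"`, `"tracks"`.
#' @return `read_table_csv`: a `data.frame`; `write_table_csv`: `path`,
#'   invisibly.
#' @export
read_table_csv <- function(path, schema = c("features", "mode_labels", "tracks")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_table(df, schema, path)
}

#' @rdname read_table_csv
#' @param table data.frame to write.
#' @export
write_table_csv <- function(table, path,
                            schema = c("features", "mode_labels", "tracks")) {
  schema <- match.arg(schema)
  .check_table(table, schema)
  num <- vapply(table, is.double, logical(1))
  out <- table
  out[num] <- lapply(table[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- blinding ---------------------------------------------------------------

#' Blind and randomize a set of observation sequences
#'
#' Supports blinded manual mode classification: maps each sequence id to an
#' anonymous code and returns a randomized presentation order, with no
#' condition metadata in the manifest. The mapping is a seed-deterministic
#' bijection; the same `(ids, seed)` always reproduces the same manifest.
#'
#' @param sequence_ids character or integer vector of unique sequence ids.
#' @param seed integer RNG seed.
#' @return A list with `manifest` (data.frame: blinded_code, presentation_order)
#'   and `key` (data.frame: blinded_code, sequence_id) — keep `key` away from
#'   the assessor.
#' @export
blind_randomize <- function(sequence_ids, seed) {
  if (length(sequence_ids) == 0) stop("sequence_ids must be non-empty")
  if (anyDuplicated(sequence_ids)) stop("duplicate sequence ids")
  n <- length(sequence_ids)
  ord <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    list(code = sample.int(n), present = sample.int(n))
  })
  codes <- sprintf("OBS%0*d", max(3L, nchar(n)), ord$code)
  list(
    manifest = data.frame(blinded_code = codes,
                          presentation_order = ord$present,
                          stringsAsFactors = FALSE),
    key = data.frame(blinded_code = codes,
                     sequence_id = sequence_ids,
                     stringsAsFactors = FALSE)
  )
}

# ---- mode frequencies -------------------------------------------------------

#' Mode frequencies per condition
#'
#' Fraction of Discontinuous and Continuous observations per group, after
#' excluding null observations (dead cells / sustained contact) from the
#' denominator. Groups with zero non-null observations are returned with `NA`
#' fractions and flagged, never as 0/0.
#'
#' @param labels a mode-label table (see [read_table_csv()], schema
#'   `"mode_labels"`).
#' @param group_by column name to group by (default `"condition"`).
#' @return data.frame with columns group, n_obs, frac_discontinuous,
#'   frac_continuous, undefined.
#' @export
mode_frequencies <- function(labels, group_by = "condition") {
  .check_table(labels, "mode_labels")
  bad <- setdiff(unique(labels$mode), .mode_levels)
  if (length(bad)) stop("unknown mode labels: ", paste(bad, collapse = ", "))
  groups <- unique(labels[[group_by]])
  res <- lapply(groups, function(g) {
    sub <- labels[labels[[group_by]] == g & labels$mode != "null", , drop = FALSE]
    n <- nrow(sub)
    if (n == 0)
      return(data.frame(group = g, n_obs = 0L, frac_discontinuous = NA_real_,
                        frac_continuous = NA_real_, undefined = TRUE))
    data.frame(group = g, n_obs = n,
               frac_discontinuous = sum(sub$mode == "Discontinuous") / n,
               frac_continuous = sum(sub$mode == "Continuous") / n,
               undefined = FALSE)
  })
  do.call(rbind, res)
}
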