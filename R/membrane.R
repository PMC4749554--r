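# Membrane protrusion/retraction dynamics: event areas over multiple time
# windows, size probability distributions and their differences, lagged
# protrusion-retraction cross-correlation, and mode comparison statistics.

#' Protrusion and retraction areas between two masks
#'
#' Protrusion is the area of pixels gained by the cell segment (`B \ A`),
#' retraction the area of pixels lost (`A \ B`), both in um^2. By symmetry
#' `protrusion(A, B) == retraction(B, A)`.
#'
#' @param maskA cell mask at the earlier frame (logical or 0/1 matrix).
#' @param maskB cell mask at the later frame.
#' @param pixel_size_um pixel size in um.
#' @return list with `protrusion_um2`, `retraction_um2`.
#' @export
protrusion_retraction <- function(maskA, maskB, pixel_size_um = 0.21) {
  if (!all(dim(maskA) == dim(maskB))) stop("mask shape mismatch")
  a <- maskA != 0; b <- maskB != 0
  px <- pixel_size_um^2
  list(protrusion_um2 = sum(b & !a) * px,
       retraction_um2 = sum(a & !b) * px)
}

#' Membrane event series over multiple time windows
#'
#' For each window size `w` (default 1..15 frames, i.e. 5..75 min at 5-min
#' frames) and each start frame `t`, events are computed between the raw masks
#' at `t` and `t + w` with the same criteria as for consecutive frames, so the
#' `w = 1` series equals the pairwise consecutive-frame result. Tracks shorter
#' than `w + 1` frames yield an empty, flagged series for that window.
#'
#' @param masks list of cell masks along one track, in frame order.
#' @param windows integer vector of window sizes (frames).
#' @param pixel_size_um pixel size in um.
#' @return A list (one element per window) with `window_frames`,
#'   `protrusion_um2`, `retraction_um2` (vectors over start frames) and an
#'   `empty` flag.
#' @export
multiwindow_series <- function(masks, windows = 1:15, pixel_size_um = 0.21) {
  n <- length(masks)
  lapply(windows, function(w) {
    if (n < w + 1)
      return(list(window_frames = w, protrusion_um2 = numeric(),
                  retraction_um2 = numeric(), empty = TRUE))
    pr <- vapply(seq_len(n - w), function(t) {
      e <- protrusion_retraction(masks[[t]], masks[[t + w]], pixel_size_um)
      c(e$protrusion_um2, e$retraction_um2)
    }, numeric(2))
    list(window_frames = w, protrusion_um2 = pr[1, ],
         retraction_um2 = pr[2, ], empty = FALSE)
  })
}

#' Default event-size histogram edges
#'
#' Fixed 1 um^2 bins from 0 up to the 99.5th percentile of the pooled events;
#' the top bin is open (larger events are counted into it).
#'
#' @param pooled_events numeric vector of event areas (um^2).
#' @param width bin width (um^2).
#' @return numeric vector of bin edges.
#' @export
default_bin_edges <- function(pooled_events, width = 1) {
  top <- stats::quantile(pooled_events, 0.995, names = FALSE)
  seq(0, max(width, ceiling(top / width) * width), by = width)
}

#' Event-size probability distribution
#'
#' Normalized histogram of event areas on shared bin edges; events beyond the
#' outermost edges are counted into the first/last (open-ended) bins.
#'
#' @param events numeric vector of event areas (>= 1 event).
#' @param bin_edges strictly increasing numeric edges.
#' @return list of class `size_distribution` with `bin_edges`, `probability`.
#' @export
size_probability_distribution <- function(events, bin_edges) {
  if (!length(events)) stop("zero events")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  k <- length(bin_edges) - 1L
  idx <- findInterval(events, bin_edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), k)   # open end bins
  counts <- tabulate(idx, nbins = k)
  structure(list(bin_edges = bin_edges, probability = counts / length(events)),
            class = "size_distribution")
}

#' Difference of two size distributions
#'
#' Per-bin probability difference `P - Q` on identical edges; the differences
#' sum to zero and `distribution_difference(P, Q) == -distribution_difference(Q, P)`.
#'
#' @param P,Q `size_distribution` objects with identical bin edges.
#' @return numeric vector of per-bin differences.
#' @export
distribution_difference <- function(P, Q) {
  if (!isTRUE(all.equal(P$bin_edges, Q$bin_edges)))
    stop("distributions have mismatched bin edges")
  P$probability - Q$probability
}

#' Protrusion-retraction cross-correlation profile
#'
#' Mean-removed, coefficient-normalized cross-covariance between a cell's
#' protrusion and retraction series at lags `-max_lag .. +max_lag` frames.
#' Sign convention: the value at lag `l` correlates `p(t)` with `r(t - l)`, so
#' a peak at a negative lag means protrusion leads retraction and a peak at a
#' positive lag means retraction leads protrusion. Missing values are imputed
#' by the series mean before computation. A constant series (zero variance)
#' yields an undefined, flagged profile.
#'
#' @param p,r numeric series of equal length (protrusion and retraction areas).
#' @param max_lag maximum lag in frames (default 12, i.e. +/- 60 min).
#' @return list of class `xcov_profile` with `lag` (frames), `value`,
#'   `undefined` flag.
#' @export
protrusion_retraction_xcov <- function(p, r, max_lag = 12) {
  stopifnot(length(p) == length(r))
  p[is.na(p)] <- mean(p, na.rm = TRUE)
  r[is.na(r)] <- mean(r, na.rm = TRUE)
  n <- length(p)
  lags <- seq(-max_lag, max_lag)
  pd <- p - mean(p); rd <- r - mean(r)
  denom <- sqrt(sum(pd^2) * sum(rd^2))
  if (denom == 0 || !is.finite(denom))
    return(structure(list(lag = lags, value = rep(NA_real_, length(lags)),
                          undefined = TRUE), class = "xcov_profile"))
  val <- vapply(lags, function(l) {
    t <- seq_len(n)
    ok <- t + l >= 1 & t + l <= n
    sum(pd[t[ok] + l] * rd[t[ok]]) / denom
  }, numeric(1))
  structure(list(lag = lags, value = val, undefined = FALSE),
            class = "xcov_profile")
}

#' @export
plot.xcov_profile <- function(x, ...) {
  graphics::plot(x$lag, x$value, type = "h", xlab = "lag (frames)",
                 ylab = "cross-correlation", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Mean absolute cross-correlation summaries per window
#'
#' For each cell and window size, the absolute cross-correlation values at all
#' lags are averaged; cells are then averaged per condition with a 95%
#' (t-based) confidence interval per window. Cells are weighted equally.
#'
#' @param profiles a data.frame with columns `cell`, `window_frames`,
#'   `mean_abs_xcov` (one row per cell x window), or a list of per-cell lists
#'   of `xcov_profile`s named by window.
#' @return data.frame: window_frames, n_cells, mean, ci_low, ci_high
#'   (`NA` CI when a single cell).
#' @export
mean_abs_xcov_summary <- function(profiles) {
  if (!is.data.frame(profiles)) {
    rows <- list()
    for (cell in names(profiles))
      for (w in names(profiles[[cell]])) {
        pr <- profiles[[cell]][[w]]
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cell, window_frames = as.integer(w),
          mean_abs_xcov = if (pr$undefined) NA_real_ else mean(abs(pr$value)))
      }
    profiles <- do.call(rbind, rows)
  }
  out <- lapply(sort(unique(profiles$window_frames)), function(w) {
    v <- profiles$mean_abs_xcov[profiles$window_frames == w]
    v <- v[is.finite(v)]
    n <- length(v)
    m <- mean(v)
    half <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
            else NA_real_
    data.frame(window_frames = w, n_cells = n, mean = m,
               ci_low = m - half, ci_high = m + half)
  })
  do.call(rbind, out)
}

#' Friedman test for mode differences across time windows
#'
#' Compares per-mode summaries (e.g. mean absolute cross-correlation) across
#' the sampled window sizes: modes are the treatments, window sizes the
#' blocks, one value per (mode, window).
#'
#' @param summary_matrix numeric matrix, rows = modes (>= 2), columns =
#'   windows (blocks, >= 3).
#' @return list with `statistic` (chi-square), `df`, `p_value`.
#' @export
friedman_mode_comparison <- function(summary_matrix) {
  if (ncol(summary_matrix) < 3) stop("need at least 3 blocks (windows)")
  ft <- stats::friedman.test(t(summary_matrix))
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) { stat <- 0; p <- 1 }   # complete ties in every block
  list(statistic = stat, df = unname(ft$parameter), p_value = p)
}
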