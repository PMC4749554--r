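# Cell motion: instantaneous speed, moving-window MSD, Furth-model fitting
# and quantile binning of motion measures.

#' Instantaneous cell speed
#'
#' Frame-to-frame displacement of the (smoothed) trajectory divided by the
#' frame interval, in um/min. Divide by 60 for um/s display units.
#'
#' @param x,y coordinates (um) ordered by frame.
#' @param frame_interval_min frame interval in minutes.
#' @return numeric vector of length `length(x) - 1` (empty for single-frame
#'   tracks); `speed[t]` is the speed between frames `t` and `t + 1`.
#' @export
instantaneous_speed <- function(x, y, frame_interval_min = 5) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2) / frame_interval_min
}

# MSD over one coordinate window: mean over all overlapping in-window pairs
# (t, t + k) of squared displacement, k = 1..max_lag.
.msd_window <- function(x, y, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(k) {
    i <- seq_len(n - k)
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
}

#' Moving-window mean squared displacement
#'
#' MSD profiles computed in a moving window (default 24 frames = 2 h at 5-min
#' frames) over the first `max_lag` time lags (default 12, up to 1 h).
#' Windows are centered on the reported frame; truncated windows at the track
#' ends are dropped. Averaging uses all overlapping pairs within the window.
#'
#' @param x,y smoothed coordinates (um) ordered by frame.
#' @param frame integer frame numbers (consecutive).
#' @param window window length in frames.
#' @param max_lag number of lags (frames).
#' @param frame_interval_min frame interval (min).
#' @return data.frame with columns center_frame, lag_frames, lag_min, msd_um2;
#'   zero rows (flagged via attribute `short_track`) when the track is shorter
#'   than the window.
#' @export
msd_moving_window <- function(x, y, frame = seq_along(x) - 1L, window = 24,
                              max_lag = 12, frame_interval_min = 5) {
  stopifnot(max_lag <= window / 2)
  n <- length(x)
  if (n < window) {
    out <- data.frame(center_frame = integer(), lag_frames = integer(),
                      lag_min = numeric(), msd_um2 = numeric())
    attr(out, "short_track") <- TRUE
    return(out)
  }
  starts <- seq_len(n - window + 1L)
  out <- do.call(rbind, lapply(starts, function(s) {
    i <- s:(s + window - 1L)
    data.frame(center_frame = frame[s] + (window - 1L) %/% 2L,
               lag_frames = seq_len(max_lag),
               lag_min = seq_len(max_lag) * frame_interval_min,
               msd_um2 = .msd_window(x[i], y[i], max_lag))
  }))
  attr(out, "short_track") <- FALSE
  out
}

#' Furth model MSD
#'
#' `MSD(t) = 4 M (t - t_p (1 - exp(-t / t_p)))`, the persistent-random-walk
#' MSD with migration coefficient `M` (um^2/min) and persistence time `t_p`
#' (min). The `t_p -> 0` limit is pure diffusion, `MSD = 4 M t`.
#'
#' @param t_min lag times (min).
#' @param M migration coefficient (um^2/min).
#' @param t_p persistence time (min).
#' @return numeric MSD values (um^2).
#' @export
furth_msd <- function(t_min, M, t_p) {
  if (t_p <= 1e-12) return(4 * M * t_min)
  4 * M * (t_min - t_p * (1 - exp(-t_min / t_p)))
}

#' Fit Furth's formula to an MSD profile
#'
#' Nonlinear least squares of the Furth persistent-random-walk model over the
#' supplied lags (typically the first 12), with `M, t_p >= 0`. By default the
#' residuals are weighted by `1/MSD` (relative error): the sampling standard
#' deviation of an empirical MSD grows roughly in proportion to its value, so
#' inverse-variance weighting stops the large-lag points from swamping the
#' short-lag curvature that identifies `t_p`. Initialization uses the slope of
#' the last two lags for `M` and two frame intervals for `t_p`, with a small
#' multi-start; non-convergence is flagged.
#'
#' @param lag_min lag times in minutes.
#' @param msd_um2 MSD values (um^2), same length.
#' @param weights `"relative"` (default, residuals scaled by `1/MSD`) or
#'   `"none"` (ordinary least squares).
#' @return Object of class `furth_fit`: list with `M`, `t_p`, `residual_norm`,
#'   `converged`, `lag_min`, `msd_um2`, `fitted`.
#' @export
fit_furth <- function(lag_min, msd_um2, weights = c("relative", "none")) {
  weights <- match.arg(weights)
  stopifnot(length(lag_min) == length(msd_um2))
  ok <- is.finite(lag_min) & is.finite(msd_um2) & lag_min > 0
  lag_min <- lag_min[ok]; msd_um2 <- msd_um2[ok]
  if (length(lag_min) < 4) stop("need >= 4 positive-lag MSD points")
  nl <- length(lag_min)
  M0 <- max((msd_um2[nl] - msd_um2[nl - 1]) /
              (lag_min[nl] - lag_min[nl - 1]) / 4, 1e-8)
  tp0 <- 2 * min(diff(lag_min))
  w <- if (weights == "relative" && all(msd_um2 > 0)) 1 / msd_um2
       else rep(1, nl)
  obj <- function(par) {
    sum((w * (furth_msd(lag_min, par[1], par[2]) - msd_um2))^2)
  }
  try_fit <- function(start) {
    tryCatch(stats::optim(start, obj, method = "L-BFGS-B",
                          lower = c(0, 0), upper = c(Inf, Inf),
                          control = list(factr = 10, pgtol = 1e-14,
                                         maxit = 1000)),
             error = function(e) NULL)
  }
  starts <- list(c(M0, tp0), c(M0, tp0 / 4), c(M0 * 4, tp0 * 4),
                 c(mean(msd_um2) / (4 * mean(lag_min)), tp0))
  best <- NULL
  for (s in starts) {
    f <- try_fit(pmax(s, c(1e-10, 0)))
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best))
    return(structure(list(M = NA_real_, t_p = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          lag_min = lag_min, msd_um2 = msd_um2,
                          fitted = rep(NA_real_, nl)),
                     class = "furth_fit"))
  structure(list(M = best$par[1], t_p = best$par[2],
                 residual_norm = sqrt(best$value),
                 converged = best$convergence == 0,
                 lag_min = lag_min, msd_um2 = msd_um2,
                 fitted = furth_msd(lag_min, best$par[1], best$par[2])),
            class = "furth_fit")
}

#' @export
print.furth_fit <- function(x, ...) {
  cat("Furth persistent-random-walk fit\n")
  cat(sprintf("  M   = %.4g um^2/min\n  t_p = %.4g min\n", x$M, x$t_p))
  cat(sprintf("  residual norm = %.3g over %d lags%s\n", x$residual_norm,
              length(x$lag_min), if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.furth_fit <- function(object, ...) c(M = object$M, t_p = object$t_p)

#' @export
predict.furth_fit <- function(object, t_min = object$lag_min, ...) {
  furth_msd(t_min, object$M, object$t_p)
}

#' @export
residuals.furth_fit <- function(object, ...) object$msd_um2 - object$fitted

#' @export
plot.furth_fit <- function(x, ...) {
  graphics::plot(x$lag_min, x$msd_um2, xlab = "lag (min)",
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  tt <- seq(0, max(x$lag_min), length.out = 100)
  graphics::lines(tt, furth_msd(tt, x$M, x$t_p))
  invisible(x)
}

#' Fit Furth's formula to every moving-window MSD profile
#'
#' @param msd data.frame from [msd_moving_window()].
#' @return data.frame with one row per window position: center_frame, M, t_p,
#'   residual_norm, converged.
#' @export
fit_furth_profiles <- function(msd) {
  do.call(rbind, lapply(split(msd, msd$center_frame), function(d) {
    f <- fit_furth(d$lag_min, d$msd_um2)
    data.frame(center_frame = d$center_frame[1], M = f$M, t_p = f$t_p,
               residual_norm = f$residual_norm, converged = f$converged)
  }))
}

#' Quantile binning with companion-variable summaries
#'
#' Assigns each value to one of `k` equal-probability bins (quintiles for
#' `k = 5`, tertiles for `k = 3`) with edges at the `i/k` empirical quantiles
#' (linear interpolation convention), and summarizes a companion variable per
#' bin by median and notch interval.
#'
#' @param values numeric vector to bin (length >= k).
#' @param k number of quantile bins.
#' @param companion optional companion variable (same length) to summarize
#'   per bin.
#' @return list with `bin` (integer assignment 1..k), `edges`, and `summary`
#'   (per-bin data.frame with n, median, notch_low, notch_high of the
#'   companion, or of `values` when no companion is given). Empty bins caused
#'   by heavy ties are flagged in `summary$empty`.
#' @export
bin_by_quantile <- function(values, k = 5, companion = NULL) {
  stopifnot(length(values) >= k)
  edges <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
                           names = FALSE)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  bin <- as.integer(pmin(pmax(bin, 1L), k))
  target <- if (is.null(companion)) values else companion
  summary <- do.call(rbind, lapply(seq_len(k), function(b) {
    v <- target[bin == b]
    if (!length(v))
      return(data.frame(bin = b, n = 0L, median = NA_real_,
                        notch_low = NA_real_, notch_high = NA_real_,
                        empty = TRUE))
    ns <- notch_summary(v)
    data.frame(bin = b, n = ns$n, median = ns$median,
               notch_low = ns$notch_low, notch_high = ns$notch_high,
               empty = FALSE)
  }))
  list(bin = bin, edges = edges, summary = summary)
}
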