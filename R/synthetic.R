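# Seed-deterministic synthetic data with known ground truth: persistent
# random walk trajectories, mode-specific membrane event series, two-mode
# feature tables, mode-label tables, and rendered label-mask movies.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate a persistent random walk trajectory
#'
#' 2-D Ornstein-Uhlenbeck velocity process with relaxation time `t_p` and
#' stationary per-component velocity variance `M / t_p`, discretized exactly
#' (the joint position/velocity increment over a frame is drawn from its exact
#' Gaussian transition), so the ensemble MSD equals Furth's formula
#' `4 M (t - t_p (1 - exp(-t/t_p)))` at every lag. `t_p -> 0` gives
#' uncorrelated steps with ensemble MSD `4 M t` (pure diffusion).
#'
#' @param M migration coefficient (um^2/min).
#' @param t_p persistence time (min).
#' @param frames number of frames.
#' @param dt frame interval (min).
#' @param seed integer seed.
#' @return data.frame with columns frame (0-based), x_um, y_um.
#' @export
simulate_trajectory <- function(M, t_p, frames, dt = 5, seed = 1) {
  stopifnot(M >= 0, t_p >= 0, frames >= 1)
  .with_seed(seed, {
    n <- frames
    if (t_p <= 1e-9 || M == 0) {
      sd_step <- sqrt(2 * M * dt)
      x <- cumsum(c(0, stats::rnorm(n - 1, sd = sd_step)))
      y <- cumsum(c(0, stats::rnorm(n - 1, sd = sd_step)))
      return(data.frame(frame = 0:(n - 1), x_um = x, y_um = y))
    }
    tau <- t_p
    s2 <- M / tau                 # stationary velocity variance per component
    a <- exp(-dt / tau)
    var_v <- s2 * (1 - a^2)
    cov_xv <- s2 * tau * (1 - a)^2
    var_x <- 2 * s2 * tau * dt - 4 * s2 * tau^2 * (1 - a) +
      s2 * tau^2 * (1 - a^2)
    # conditional decomposition xi_x | xi_v
    slope <- cov_xv / var_v
    sd_resid <- sqrt(max(var_x - cov_xv^2 / var_v, 0))
    step1 <- function() {
      v <- stats::rnorm(1, sd = sqrt(s2))
      pos <- numeric(n)
      for (i in seq_len(n - 1)) {
        xi_v <- stats::rnorm(1, sd = sqrt(var_v))
        xi_x <- slope * xi_v + stats::rnorm(1, sd = sd_resid)
        pos[i + 1] <- pos[i] + v * tau * (1 - a) + xi_x
        v <- a * v + xi_v
      }
      pos
    }
    data.frame(frame = 0:(n - 1), x_um = step1(), y_um = step1())
  })
}

#' Simulate mode-specific membrane event series
#'
#' Continuous mode: protrusion is a positively autocorrelated event series
#' and retraction follows it by one frame (`r(t) = p(t-1) + noise`), the
#' tightly coupled, protrusion-led regime. Discontinuous mode: baseline small
#' retractions with sparse large retraction events (bimodal retraction sizes),
#' each followed after `delay_frames` by an elevated protrusion, the
#' retraction-led, temporally decoupled regime (cross-correlation peak at a
#' positive lag, lower overall coordination).
#'
#' @param mode `"Continuous"` or `"Discontinuous"`.
#' @param frames series length.
#' @param seed integer seed.
#' @param noise_sd additive noise on the coupled series (um^2).
#' @param delay_frames Discontinuous retraction-to-protrusion delay (frames).
#' @param large_retraction_prob per-frame probability of a large retraction
#'   (Discontinuous).
#' @param large_retraction_um2 mean size of large retractions (um^2).
#' @return list with `protrusion_um2`, `retraction_um2` (length `frames`) and
#'   the generating parameters.
#' @export
simulate_membrane_events <- function(mode = c("Continuous", "Discontinuous"),
                                     frames = 96, seed = 1, noise_sd = 0.5,
                                     delay_frames = 3,
                                     large_retraction_prob = 0.08,
                                     large_retraction_um2 = 25) {
  mode <- match.arg(mode)
  .with_seed(seed, {
    n <- frames
    if (mode == "Continuous") {
      # AR(1) base keeps correlation spread over neighbouring lags
      innov <- stats::rgamma(n, shape = 4, scale = 1.5)
      p <- stats::filter(innov, 0.5, method = "recursive")
      p <- as.numeric(p)
      r <- c(mean(p), p[-n]) + stats::rnorm(n, sd = noise_sd)
      r <- pmax(r, 0)
    } else {
      p <- stats::rgamma(n, shape = 2, scale = 0.5)
      r <- stats::rgamma(n, shape = 2, scale = 0.5)
      big <- which(stats::runif(n) < large_retraction_prob)
      r[big] <- r[big] + stats::rnorm(length(big),
                                      mean = large_retraction_um2,
                                      sd = large_retraction_um2 / 8)
      fol <- big + delay_frames
      fol <- fol[fol <= n]
      p[fol] <- p[fol] + 0.8 * r[big[seq_along(fol)]] +
        stats::rnorm(length(fol), sd = noise_sd)
      p <- pmax(p, 0)
    }
    list(mode = mode, protrusion_um2 = p, retraction_um2 = r,
         delay_frames = delay_frames, noise_sd = noise_sd)
  })
}

#' Simulate a two-mode feature table with known structure
#'
#' Two multivariate Gaussian feature populations with a prescribed
#' per-feature mean shift (in within-mode SD units) between the modes, and a
#' per-cell latent speed with which selected features co-vary with
#' mode-specific correlation signs (so a feature can couple positively to
#' speed in one mode and negatively in the other, the "inverted" pattern).
#'
#' @param n_cells_per_mode cells per mode.
#' @param frames_per_cell observations per cell.
#' @param n_features number of feature columns (`feature_01`...).
#' @param effect numeric vector (recycled/padded to `n_features`) of mean
#'   shifts added to the Discontinuous mode, in SD units.
#' @param coupling named list per mode of numeric vectors (length
#'   `n_features`) of target feature-speed correlations in `[-1, 1]`.
#' @param seed integer seed.
#' @return data.frame with keys (cell_track_id, frame, condition, repeat_id,
#'   mode), `cell_speed_um_per_min`, and feature columns; the generating
#'   parameters are attached as attribute `ground_truth`.
#' @export
simulate_feature_table <- function(n_cells_per_mode = 25,
                                   frames_per_cell = 20,
                                   n_features = 20,
                                   effect = c(4, 4, 4, rep(0, 17)),
                                   coupling = NULL,
                                   seed = 1) {
  effect <- rep_len(effect, n_features)
  modes <- c("Discontinuous", "Continuous")
  if (is.null(coupling))
    coupling <- list(Discontinuous = rep(0, n_features),
                     Continuous = rep(0, n_features))
  .with_seed(seed, {
    rows <- lapply(modes, function(m) {
      rho <- rep_len(coupling[[m]], n_features)
      shift <- if (m == "Discontinuous") effect else rep(0, n_features)
      do.call(rbind, lapply(seq_len(n_cells_per_mode), function(cell) {
        z <- stats::rnorm(frames_per_cell)          # latent speed, z-scored
        speed <- 0.3 + 0.1 * z                      # um/min scale
        X <- vapply(seq_len(n_features), function(j) {
          # corr(f, z) = rho when f = rho*z + sqrt(1-rho^2)*eps
          shift[j] + rho[j] * z +
            sqrt(max(1 - rho[j]^2, 0)) * stats::rnorm(frames_per_cell)
        }, numeric(frames_per_cell))
        cbind(data.frame(
          cell_track_id = paste0(substr(m, 1, 1), cell),
          frame = seq_len(frames_per_cell) - 1L,
          condition = "synthetic", repeat_id = 1L, mode = m,
          cell_speed_um_per_min = speed),
          stats::setNames(as.data.frame(X),
                          sprintf("feature_%02d", seq_len(n_features))))
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ground_truth") <- list(effect = effect, coupling = coupling)
    out
  })
}

#' Simulate a mode-label table
#'
#' Per-cell mode assignment with the observed baseline balance (about 80% of
#' observations Discontinuous under standard fibronectin conditions) and a
#' small fraction of null observations (dead cells / sustained contact).
#'
#' @param n_cells number of cells.
#' @param frames_per_cell observations per cell.
#' @param prob_discontinuous probability a cell is Discontinuous.
#' @param prob_null per-observation probability of a null label.
#' @param condition,repeat_id metadata values.
#' @param seed integer seed.
#' @return mode-label data.frame (cell_track_id, frame, mode, condition,
#'   repeat_id).
#' @export
simulate_mode_labels <- function(n_cells = 40, frames_per_cell = 60,
                                 prob_discontinuous = 0.8, prob_null = 0.05,
                                 condition = "FN_2.5", repeat_id = 1L,
                                 seed = 1) {
  .with_seed(seed, {
    cell_mode <- ifelse(stats::runif(n_cells) < prob_discontinuous,
                        "Discontinuous", "Continuous")
    out <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      mode <- rep(cell_mode[i], frames_per_cell)
      mode[stats::runif(frames_per_cell) < prob_null] <- "null"
      data.frame(cell_track_id = i, frame = seq_len(frames_per_cell) - 1L,
                 mode = mode, condition = condition, repeat_id = repeat_id)
    }))
    rownames(out) <- NULL
    out
  })
}

# ---- mask rendering ---------------------------------------------------------

.disk_mask <- function(dim, center_rc, radius_px) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (rows - center_rc[1])^2 + (cols - center_rc[2])^2 <= radius_px^2
}

.shift_mask <- function(mask, dr, dc) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  rc <- which(mask, arr.ind = TRUE)
  rc[, 1] <- rc[, 1] + dr
  rc[, 2] <- rc[, 2] + dc
  ok <- rc[, 1] >= 1 & rc[, 1] <= nrow(mask) & rc[, 2] >= 1 & rc[, 2] <= ncol(mask)
  out[rc[ok, , drop = FALSE]] <- TRUE
  out
}

.outside_neighbors <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  nb <- pad[1:h, 2:(w + 1L)] | pad[3:(h + 2L), 2:(w + 1L)] |
        pad[2:(h + 1L), 1:w] | pad[2:(h + 1L), 3:(w + 2L)]
  nb & !mask
}

#' Render a synthetic label-mask movie from a trajectory and event series
#'
#' A deformable-disk cell is rendered per frame: the mask follows the
#' (rounded) trajectory, then the prescribed retraction pixels are removed
#' from the boundary and the prescribed protrusion pixels grown onto the
#' outside boundary, so the pipeline-measured event areas match the
#' prescription up to translation effects (exactly, for a stationary track).
#' Optionally renders a CMAC label layer (small disks riding inside the cell)
#' and a matching intensity stack with known foreground/background values.
#'
#' @param track data.frame with `x_um`, `y_um` (one row per frame), e.g. from
#'   [simulate_trajectory()]; `NULL` for a stationary cell.
#' @param protrusion_px,retraction_px integer event sizes (pixels) per frame
#'   transition (length `frames - 1`), e.g. scaled from
#'   [simulate_membrane_events()].
#' @param frames number of frames (required when `track` is `NULL`).
#' @param dim canvas size `c(rows, cols)` in pixels.
#' @param radius_px initial cell radius (pixels).
#' @param pixel_size_um pixel size (um).
#' @param label cell label id.
#' @param cmacs optional data.frame of CMAC blobs: columns `dr`, `dc` (offset
#'   from cell center, px), `radius_px`, `value` (intensity).
#' @param background intensity background value.
#' @param seed integer seed (boundary pixels are chosen at random).
#' @return list with `cell` ([label_movie()]), and when `cmacs` given,
#'   `cmac` (label_movie) and `paxillin` ([intensity_movie()]).
#' @export
render_mask_movie <- function(track = NULL, protrusion_px = NULL,
                              retraction_px = NULL, frames = NULL,
                              dim = c(120, 120), radius_px = 12,
                              pixel_size_um = 0.21, label = 1L,
                              cmacs = NULL, background = 2, seed = 1) {
  if (is.null(track)) {
    stopifnot(!is.null(frames))
    pos_px <- matrix(rep(round(dim / 2), each = frames), frames, 2)
  } else {
    frames <- nrow(track)
    # place trajectory origin at canvas center; y -> rows, x -> cols
    pos_px <- cbind(round(dim[1] / 2 + track$y_um / pixel_size_um),
                    round(dim[2] / 2 + track$x_um / pixel_size_um))
  }
  if (is.null(protrusion_px)) protrusion_px <- rep(0L, frames - 1)
  if (is.null(retraction_px)) retraction_px <- rep(0L, frames - 1)
  stopifnot(length(protrusion_px) == frames - 1,
            length(retraction_px) == frames - 1)
  .with_seed(seed, {
    masks <- vector("list", frames)
    masks[[1]] <- .disk_mask(dim, pos_px[1, ], radius_px)
    for (t in seq_len(frames - 1)) {
      base <- .shift_mask(masks[[t]],
                          pos_px[t + 1, 1] - pos_px[t, 1],
                          pos_px[t + 1, 2] - pos_px[t, 2])
      if (sum(base) < sum(masks[[t]]))
        stop("cell left the canvas at frame ", t, "; enlarge `dim`")
      if (retraction_px[t] >= sum(base))
        stop("retraction event exceeds cell area at frame ", t)
      m <- base
      # retract: strip random boundary pixels
      left <- retraction_px[t]
      while (left > 0) {
        bd <- which(.boundary_pixels(m))
        take <- bd[sample.int(length(bd), min(left, length(bd)))]
        m[take] <- FALSE
        left <- left - length(take)
      }
      # protrude: grow random outside-neighbour pixels, never re-adding
      # pixels present at t (so measured events equal the prescription for a
      # stationary cell)
      left <- protrusion_px[t]
      while (left > 0) {
        cand <- which(.outside_neighbors(m) & !masks[[t]] & !base)
        if (!length(cand)) stop("no room to protrude at frame ", t)
        take <- cand[sample.int(length(cand), min(left, length(cand)))]
        m[take] <- TRUE
        left <- left - length(take)
      }
      masks[[t + 1]] <- m
    }
    cell_frames <- lapply(masks, function(m) {
      f <- matrix(0L, dim[1], dim[2]); f[m] <- as.integer(label); f
    })
    out <- list(cell = label_movie(cell_frames, pixel_size_um,
                                   layer = "cell"))
    if (!is.null(cmacs)) {
      cmac_frames <- vector("list", frames)
      pax_frames <- vector("list", frames)
      for (t in seq_len(frames)) {
        cf <- matrix(0L, dim[1], dim[2])
        pf <- matrix(background, dim[1], dim[2])
        for (k in seq_len(nrow(cmacs))) {
          blob <- .disk_mask(dim, pos_px[t, ] + c(cmacs$dr[k], cmacs$dc[k]),
                             cmacs$radius_px[k])
          cf[blob] <- k
          pf[blob] <- cmacs$value[k]
        }
        cmac_frames[[t]] <- cf
        pax_frames[[t]] <- pf
      }
      out$cmac <- label_movie(cmac_frames, pixel_size_um, layer = "cmac")
      out$paxillin <- intensity_movie(pax_frames, channel = "paxillin")
    }
    out
  })
}
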