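# Multivariate layer: Spearman correlation networks with permutation nulls,
# canonical variates analysis, PCA, kernel-density state-space surfaces, and
# the univariate statistics used alongside them.

#' Spearman correlation matrix over a feature set
#'
#' Spearman's rank correlation (average-rank tie handling) between all pairs
#' of the selected features, computed per cell observation with a
#' pairwise-complete missing-value policy. Constant features give undefined
#' (NA) entries and are flagged.
#'
#' @param table data.frame of observations.
#' @param features character vector of feature column names.
#' @param min_n minimum complete observations required per pair.
#' @return list of class `correlation_matrix` with `rs` (features x features),
#'   `n` (pairwise complete counts), `constant` (flagged feature names).
#' @export
spearman_matrix <- function(table, features, min_n = 3) {
  X <- as.matrix(table[features])
  n_pair <- crossprod(!is.na(X))
  if (any(n_pair[upper.tri(n_pair)] < min_n))
    warning("some feature pairs have fewer than ", min_n,
            " complete observations")
  rs <- suppressWarnings(
    stats::cor(X, method = "spearman", use = "pairwise.complete.obs"))
  constant <- features[apply(X, 2, function(v) {
    v <- v[is.finite(v)]
    length(v) > 0 && stats::sd(v) == 0
  })]
  diag(rs) <- 1
  structure(list(rs = rs, n = n_pair, constant = constant),
            class = "correlation_matrix")
}

#' Difference between correlation networks with a permutation null
#'
#' Observed statistic: absolute differences `|A - B|` over the off-diagonal
#' (upper-triangle) correlation values. Null: the identity of the correlation
#' values in `A` is permuted (which pair each value belongs to is shuffled)
#' while `B` is held constant, the absolute differences recomputed, and the
#' results pooled over `n_perm` permutations (default 100). The empirical CDFs
#' of observed and pooled permuted differences are returned.
#'
#' @param A,B `correlation_matrix` objects (or plain matrices) on the same
#'   feature set and order.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed (permutations are seed-reproducible).
#' @return list with `observed` (vector of |diff|), `permuted` (pooled vector,
#'   length `n_perm * length(observed)`), `observed_cdf`, `permuted_cdf`
#'   (functions), `diff_matrix`.
#' @export
correlation_difference_with_permutation <- function(A, B, n_perm = 100,
                                                    seed = 1) {
  a <- if (inherits(A, "correlation_matrix")) A$rs else as.matrix(A)
  b <- if (inherits(B, "correlation_matrix")) B$rs else as.matrix(B)
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)))
    stop("correlation matrices have mismatched features")
  ut <- upper.tri(a)
  av <- a[ut]; bv <- b[ut]
  observed <- abs(av - bv)
  diff_matrix <- abs(a - b); diag(diff_matrix) <- 0
  permuted <- local({
    set.seed(as.integer(seed))
    unlist(lapply(seq_len(n_perm), function(i) abs(sample(av) - bv)))
  })
  list(observed = observed, permuted = permuted,
       observed_cdf = stats::ecdf(observed),
       permuted_cdf = stats::ecdf(permuted),
       diff_matrix = diff_matrix)
}

# ---- canonical variates analysis -------------------------------------------

# Complete-case + high-missingness feature policy shared by cva_fit/pca_fit.
.clean_matrix <- function(X, max_missing = 0.2) {
  X <- as.matrix(X)
  frac_na <- colMeans(is.na(X))
  drop <- colnames(X)[frac_na > max_missing]
  if (length(drop)) {
    warning("excluding features with >", max_missing * 100, "% missing: ",
            paste(drop, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  keep_rows <- stats::complete.cases(X)
  list(X = X[keep_rows, , drop = FALSE], rows = which(keep_rows))
}

#' Canonical variates analysis
#'
#' Supervised projection maximizing between-group relative to within-group
#' covariance: eigenvectors of `W^-1 B` where `W` is the pooled within-group
#' and `B` the between-group covariance matrix, sorted by eigenvalue. At most
#' `min(groups - 1, features)` non-null canonical variates exist; per-CV
#' variance fractions are the eigenvalues normalized to sum 1 over the
#' retained CVs. Features are z-scored by default (`scale. = TRUE`) so CV1
#' coefficients are comparable across features; rows with missing values are
#' dropped (complete-case) and features with more than 20% missing are
#' excluded with a warning. A small ridge (`1e-6 * trace(W)/p`) keeps `W`
#' invertible; a singular `W` without ridge is an error.
#'
#' @param X observations x features (matrix or data.frame).
#' @param groups group label per row (>= 2 groups).
#' @param scale. z-score features before the decomposition.
#' @param ridge ridge added to `diag(W)` as a fraction of `trace(W)/p`.
#' @return Object of class `cva_model`: `vectors` (features x CVs, CV1
#'   first), `eigenvalues`, `variance_fraction`, `coefficients` (CV1, named),
#'   `ranking` (features by decreasing |CV1 coefficient|), `scores`,
#'   `groups`, `centers` (group centers of mass in CV space), `center`,
#'   `scale`.
#' @export
cva_fit <- function(X, groups, scale. = TRUE, ridge = 1e-6) {
  cl <- .clean_matrix(X)
  X <- cl$X
  groups <- factor(groups[cl$rows])
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  ctr <- colMeans(X)
  scl <- if (scale.) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0)) stop("zero-variance feature: ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  p <- ncol(Xs); g <- nlevels(groups); N <- nrow(Xs)
  gm <- rowsum(Xs, groups) / as.vector(table(groups))
  overall <- colMeans(Xs)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lv in levels(groups)) {
    sel <- groups == lv
    d <- sweep(Xs[sel, , drop = FALSE], 2, gm[lv, ])
    W <- W + crossprod(d)
    db <- gm[lv, ] - overall
    B <- B + sum(sel) * tcrossprod(db)
  }
  W <- W / (N - g); B <- B / (g - 1)
  if (ridge > 0) W <- W + diag(ridge * sum(diag(W)) / p, p)
  Winv_B <- tryCatch(solve(W, B), error = function(e)
    stop("within-group covariance is singular; increase `ridge`"))
  eig <- eigen(Winv_B)
  ev <- Re(eig$values); V <- Re(eig$vectors)
  ord <- order(ev, decreasing = TRUE)
  k <- min(g - 1, p)
  ev <- pmax(ev[ord][seq_len(k)], 0)
  V <- V[, ord[seq_len(k)], drop = FALSE]
  # unit-norm vectors with a deterministic sign (largest coefficient positive)
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  V <- matrix(V, nrow = p,
              dimnames = list(colnames(Xs), paste0("CV", seq_len(k))))
  scores <- Xs %*% V
  centers <- rowsum(scores, groups) / as.vector(table(groups))
  coefs <- stats::setNames(V[, 1], colnames(Xs))
  structure(list(vectors = V, eigenvalues = ev,
                 variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
                 coefficients = coefs,
                 ranking = names(sort(abs(coefs), decreasing = TRUE)),
                 scores = scores, groups = groups, centers = centers,
                 center = ctr, scale = scl),
            class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat(sprintf("Canonical variates analysis: %d features, %d groups, %d CVs\n",
              nrow(x$vectors), nlevels(x$groups), ncol(x$vectors)))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  cat("top |CV1| features:",
      paste(utils::head(x$ranking, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cva_model <- function(object, ...) object$coefficients

#' Project new observations into CV space
#' @param object a `cva_model`.
#' @param newdata observations x features with the model's feature columns.
#' @param ... unused.
#' @return scores matrix.
#' @export
predict.cva_model <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata[, rownames(object$vectors), drop = FALSE]),
                    2, object$center), 2, object$scale, "/")
  Xs %*% object$vectors
}

#' @export
plot.cva_model <- function(x, ...) {
  k <- ncol(x$scores)
  s2 <- if (k >= 2) x$scores[, 2] else stats::rnorm(nrow(x$scores), sd = 0.02)
  graphics::plot(x$scores[, 1], s2, col = as.integer(x$groups),
                 xlab = "CV1", ylab = if (k >= 2) "CV2" else "jitter", ...)
  invisible(x)
}

#' Nearest-center separation of a CVA model
#'
#' Fraction of observations lying nearer (Euclidean, in CV space) to their
#' own group's center of mass than to any other group's.
#'
#' @param model a `cva_model`.
#' @return scalar in `[0, 1]`.
#' @export
cva_separation <- function(model) {
  d2 <- sapply(seq_len(nrow(model$centers)), function(gi)
    rowSums(sweep(model$scores, 2, model$centers[gi, ])^2))
  own <- match(as.character(model$groups), rownames(model$centers))
  mean(max.col(-d2, ties.method = "first") == own)
}

#' Principal component analysis via SVD of the normalized data matrix
#'
#' Features are z-scored ("normalized") and the scores/loadings obtained by
#' singular value decomposition. Complete-case rows; a zero-variance feature
#' is an error naming the feature.
#'
#' @param X observations x features.
#' @return Object of class `pca_model`: `loadings` (orthonormal columns),
#'   `scores`, `variance_fraction`, `sdev`, `center`, `scale`.
#' @export
pca_fit <- function(X) {
  cl <- .clean_matrix(X)
  X <- cl$X
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance feature: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(Xs)
  k <- min(dim(Xs))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(Xs), paste0("PC", seq_len(k)))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- colnames(loadings)
  varfrac <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = varfrac,
                 sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(Xs) - 1)),
                 center = ctr, scale = scl),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA (SVD of z-scored matrix): %d features\n", nrow(x$loadings)))
  cat("variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)),
            collapse = " "),
      if (length(x$variance_fraction) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata[, rownames(object$loadings), drop = FALSE]),
                    2, object$center), 2, object$scale, "/")
  Xs %*% object$loadings
}

#' Kernel-density probability surface on a 2-D score space
#'
#' Gaussian kernel density on a regular grid over the first two component
#' axes, normalized so the per-cell probability mass sums to 1. The bandwidth
#' per axis is Silverman's rule times `bandwidth_factor`; the default factor
#' 0.5 keeps the kernel scale well below the overall mode distributions so the
#' surface topology reflects the data rather than the smoothing.
#'
#' @param points n x 2 matrix of scores (n >= 10).
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @param gridsize number of grid nodes per axis.
#' @param expand grid margin in bandwidths beyond the data range.
#' @return Object of class `density_surface`: `x`, `y` (grid node centers),
#'   `mass` (matrix, sums to 1), `bandwidth`, `degenerate` flag.
#' @export
kde2d_surface <- function(points, bandwidth_factor = 0.5, gridsize = 101,
                          expand = 3) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 10) stop("need >= 10 points")
  sds <- c(stats::sd(points[, 1]), stats::sd(points[, 2]))
  rho <- if (all(sds > 0)) stats::cor(points[, 1], points[, 2]) else 1
  bw <- c(stats::bw.nrd0(points[, 1]), stats::bw.nrd0(points[, 2])) *
    bandwidth_factor
  if (any(sds == 0) || abs(rho) > 1 - 1e-12 ||
      any(bw <= 0) || any(!is.finite(bw)))
    return(structure(list(x = NULL, y = NULL, mass = NULL, bandwidth = bw,
                          degenerate = TRUE), class = "density_surface"))
  lims <- c(range(points[, 1]) + c(-1, 1) * expand * bw[1],
            range(points[, 2]) + c(-1, 1) * expand * bw[2])
  kd <- MASS::kde2d(points[, 1], points[, 2], h = 4 * bw, n = gridsize,
                    lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  mass <- kd$z * cell
  mass <- mass / sum(mass)
  structure(list(x = kd$x, y = kd$y, mass = mass, bandwidth = bw,
                 degenerate = FALSE), class = "density_surface")
}

#' @export
plot.density_surface <- function(x, ...) {
  if (x$degenerate) stop("degenerate density surface")
  graphics::image(x$x, x$y, x$mass, xlab = "component 1",
                  ylab = "component 2", useRaster = TRUE, ...)
  invisible(x)
}

#' Median with notch interval
#'
#' Median, IQR (linear-interpolation quantiles) and the notch interval
#' `median +/- 1.57 * IQR / sqrt(n)`, an approximate 95% confidence interval
#' for the median.
#'
#' @param values non-empty numeric vector.
#' @return list with `median`, `iqr`, `n`, `notch_low`, `notch_high`.
#' @export
notch_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("empty sample")
  med <- stats::median(values)
  iqr <- stats::IQR(values)   # type-7 linear interpolation quantiles
  half <- 1.57 * iqr / sqrt(n)
  list(median = med, iqr = iqr, n = n,
       notch_low = med - half, notch_high = med + half)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties, normal approximation
#' with tie correction otherwise; two samples of identical tied values give
#' `p = 1`.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `statistic` (rank-sum W of `a`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1)
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-mode catalogue of feature-to-speed correlations
#'
#' Within each cell trajectory (with at least `min_frames` observations),
#' Spearman's rs between each feature and cell speed is computed; per mode the
#' median of the per-cell rs values summarizes the coupling. A coupling is
#' non-significant (ns) if 0 lies inside the notch interval of the per-cell rs
#' values. Couplings are classified across the two modes as `both_positive`,
#' `both_negative`, `one_mode_only`, `inverted`, or `ns`.
#'
#' @param table feature table with `mode`, `cell_track_id`, speed and feature
#'   columns.
#' @param features character vector of feature names.
#' @param speed_col speed column name.
#' @param min_frames minimum observations per cell trajectory.
#' @return list with `catalogue` (data.frame: feature, median_rs and
#'   significance per mode, class) and `n_cells_skipped`.
#' @export
speed_correlation_catalogue <- function(table, features,
                                        speed_col = "cell_speed_um_per_min",
                                        min_frames = 8) {
  modes <- setdiff(unique(table$mode), "null")
  if (length(modes) != 2) stop("need exactly 2 non-null modes")
  skipped <- 0L
  per_cell <- list()
  for (m in modes) {
    sub <- table[table$mode == m, , drop = FALSE]
    for (cell in unique(sub$cell_track_id)) {
      d <- sub[sub$cell_track_id == cell, , drop = FALSE]
      if (nrow(d) < min_frames) { skipped <- skipped + 1L; next }
      rs <- vapply(features, function(f)
        suppressWarnings(stats::cor(d[[f]], d[[speed_col]],
                                    method = "spearman",
                                    use = "pairwise.complete.obs")),
        numeric(1))
      per_cell[[length(per_cell) + 1L]] <-
        c(list(mode = m, cell = cell), as.list(rs))
    }
  }
  if (!length(per_cell))
    stop("no cell trajectories with >= ", min_frames, " observations")
  pc <- do.call(rbind, lapply(per_cell, function(r)
    data.frame(r, check.names = FALSE)))
  rows <- lapply(features, function(f) {
    stats_mode <- lapply(modes, function(m) {
      v <- pc[[f]][pc$mode == m]
      v <- v[is.finite(v)]
      ns <- notch_summary(v)
      sig <- !(ns$notch_low <= 0 && ns$notch_high >= 0)
      list(median = ns$median, sig = sig)
    })
    s1 <- stats_mode[[1]]; s2 <- stats_mode[[2]]
    class <- if (s1$sig && s2$sig) {
      if (sign(s1$median) != sign(s2$median)) "inverted"
      else if (s1$median > 0) "both_positive" else "both_negative"
    } else if (s1$sig || s2$sig) "one_mode_only" else "ns"
    out <- data.frame(feature = f, class = class)
    out[[paste0("median_rs_", modes[1])]] <- s1$median
    out[[paste0("median_rs_", modes[2])]] <- s2$median
    out[[paste0("sig_", modes[1])]] <- s1$sig
    out[[paste0("sig_", modes[2])]] <- s2$sig
    out
  })
  list(catalogue = do.call(rbind, rows), n_cells_skipped = skipped)
}
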