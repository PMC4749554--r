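test_that("Spearman matrices equal the rank-then-Pearson oracle", {
  withr::local_seed(1)
  tab <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  cm <- spearman_matrix(tab, c("a", "b", "c"))
  # brute-force oracle: rank then Pearson
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm$rs[i, j],
                 cor(rank(tab[[i]]), rank(tab[[j]])), tolerance = 1e-12)
  expect_equal(diag(cm$rs), rep(1, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(cm$rs))
  # rank invariance under strictly monotone transforms
  tab2 <- transform(tab, a = exp(3 * a), b = b^3)
  cm2 <- spearman_matrix(tab2, c("a", "b", "c"))
  expect_equal(cm2$rs, cm$rs, tolerance = 1e-12)
  # constant feature flagged
  tab$d <- 1
  cmc <- suppressWarnings(spearman_matrix(tab, c("a", "d")))
  expect_identical(cmc$constant, "d")
  expect_true(is.na(cmc$rs["a", "d"]))
  # pairwise-complete counts
  tab$a[1] <- NA
  cmn <- spearman_matrix(tab, c("a", "b"))
  expect_identical(as.integer(cmn$n["a", "b"]), 4L)
})

test_that("correlation-difference permutation nulls are reproducible and dominated when A = B", {
  withr::local_seed(2)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  A <- spearman_matrix(as.data.frame(X), paste0("f", 1:4))
  res <- correlation_difference_with_permutation(A, A, n_perm = 100, seed = 7)
  expect_true(all(res$observed == 0))
  # same seed: identical pooled null
  res2 <- correlation_difference_with_permutation(A, A, n_perm = 100, seed = 7)
  expect_identical(res$permuted, res2$permuted)
  expect_length(res$permuted, 100 * length(res$observed))
  # observed CDF (step at 0) dominates the permuted CDF everywhere
  grid <- seq(0, 2, by = 0.01)
  expect_true(all(res$observed_cdf(grid) >= res$permuted_cdf(grid)))

  # enumeration oracle on a 3-feature matrix (3 off-diagonal values,
  # permutations drawn with the same RNG stream)
  a <- A$rs[1:3, 1:3]; bmat <- a * 0.5
  set.seed(11)
  av <- a[upper.tri(a)]; bv <- bmat[upper.tri(bmat)]
  manual <- c(abs(sample(av) - bv), abs(sample(av) - bv))
  res3 <- correlation_difference_with_permutation(a, bmat, n_perm = 2, seed = 11)
  expect_equal(res3$permuted, manual)
  expect_equal(res3$observed, abs(av - bv))
  expect_error(correlation_difference_with_permutation(a, A$rs, seed = 1),
               "mismatched")
})

test_that("CVA reproduces the Fisher LDA direction and the rank bound", {
  withr::local_seed(3)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[51:100, 2] <- X[51:100, 2] + 2.5
  g <- rep(c("a", "b"), each = 50)
  m <- cva_fit(X, g, scale. = FALSE, ridge = 0)
  # oracle: pooled within-covariance, LDA direction W^-1 (m1 - m2)
  W <- (crossprod(scale(X[1:50, ], scale = FALSE)) +
          crossprod(scale(X[51:100, ], scale = FALSE))) / (100 - 2)
  d <- colMeans(X[1:50, ]) - colMeans(X[51:100, ])
  lda <- solve(W, d); lda <- lda / sqrt(sum(lda^2))
  v <- m$vectors[, 1]
  expect_lt(min(max(abs(v - lda)), max(abs(v + lda))), 1e-8)
  # two groups: exactly one non-null CV; variance fractions sum to 1
  expect_identical(ncol(m$vectors), 1L)
  expect_equal(sum(m$variance_fraction), 1)
  # 3 groups, many features: groups - 1 CVs
  g3 <- rep(c("a", "b", "c"), length.out = 100)
  m3 <- cva_fit(X, g3)
  expect_identical(ncol(m3$vectors), 2L)
  # identity-within toy: CV1 proportional to the group mean difference
  Xi <- rbind(matrix(rnorm(2000), 500, 4), matrix(rnorm(2000), 500, 4))
  colnames(Xi) <- paste0("f", 1:4)
  Xi[1:500, ] <- sweep(Xi[1:500, ], 2, c(3, 0, 0, 0), "+")
  mi <- cva_fit(Xi, rep(c("a", "b"), each = 500), scale. = FALSE)
  expect_identical(mi$ranking[1], "f1")
  expect_error(cva_fit(X, rep("a", 100)), ">= 2 groups")
})

test_that("CVA separates synthetic modes and ranks shifted features first", {
  tab <- simulate_feature_table(n_cells_per_mode = 25, frames_per_cell = 20,
                                n_features = 20,
                                effect = c(4, 4, 4, rep(0, 17)), seed = 5)
  feats <- grep("^feature_", names(tab), value = TRUE)
  m <- cva_fit(tab[feats], tab$mode)
  expect_gte(cva_separation(m), 0.95)
  expect_setequal(m$ranking[1:3], c("feature_01", "feature_02", "feature_03"))
  expect_gt(m$variance_fraction[1], 0.99)
  # null case: no effect, separation near chance
  tab0 <- simulate_feature_table(n_cells_per_mode = 25, frames_per_cell = 20,
                                 effect = rep(0, 20), seed = 6)
  m0 <- cva_fit(tab0[feats], tab0$mode)
  expect_lt(cva_separation(m0), 0.7)
  # affine rescaling of features leaves scores invariant (up to sign)
  sc <- sweep(as.matrix(tab[feats]), 2, seq(0.1, 2, length.out = 20), "*")
  msc <- cva_fit(sc, tab$mode, scale. = FALSE)
  r <- abs(cor(msc$scores[, 1], m$scores[, 1]))
  expect_gt(r, 0.999)
})

test_that("PCA via SVD satisfies its invariants and the 2-feature closed form", {
  withr::local_seed(7)
  n <- 20000; rho <- 0.8
  z <- rnorm(n)
  X <- cbind(a = z, b = rho * z + sqrt(1 - rho^2) * rnorm(n)) +
    matrix(rnorm(2 * n, sd = 1e-12), n, 2)   # avoid exact degeneracy
  m <- pca_fit(X)
  expect_equal(sum(m$variance_fraction), 1)
  expect_equal(crossprod(m$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # closed form: eigenvalues of the 2x2 correlation matrix are 1 +/- rho
  expect_equal(m$variance_fraction[1], (1 + rho) / 2, tolerance = 0.01)
  expect_error(pca_fit(cbind(a = rep(1, 10), b = rnorm(10))), "zero-variance")
  # scores reproduce through predict
  expect_equal(predict(m, as.data.frame(X))[1:5, ], m$scores[1:5, ],
               tolerance = 1e-8)
})

test_that("KDE surfaces integrate to 1 and match an analytic mixture", {
  withr::local_seed(8)
  pts <- rbind(matrix(rnorm(4000, -2, 0.7), ncol = 2),
               matrix(rnorm(4000, 2, 0.7), ncol = 2))
  s <- kde2d_surface(pts, bandwidth_factor = 0.5, gridsize = 121)
  expect_equal(sum(s$mass), 1, tolerance = 1e-3)
  # mirror-symmetric points give a symmetric surface
  sym <- rbind(cbind(1:50 / 10, 1), cbind(-(1:50) / 10, 1),
               cbind(1:50 / 10, -1), cbind(-(1:50) / 10, -1))
  ss <- kde2d_surface(sym, gridsize = 41)
  expect_equal(ss$mass, ss$mass[rev(seq_len(41)), ], tolerance = 1e-10)
  # analytic oracle: equal-weight Gaussian mixture density on the grid
  dens_true <- function(x, y)
    0.5 * dnorm(x, -2, 0.7) * dnorm(y, -2, 0.7) +
    0.5 * dnorm(x, 2, 0.7) * dnorm(y, 2, 0.7)
  cell <- diff(s$x[1:2]) * diff(s$y[1:2])
  est <- s$mass / cell
  truth <- outer(s$x, s$y, dens_true)
  expect_lt(max(abs(est - truth)), 0.05)
  # degenerate input flagged
  dg <- kde2d_surface(cbind(rep(1, 20), 1:20))
  expect_true(dg$degenerate)
  expect_error(kde2d_surface(cbind(1:5, 1:5)), ">= 10")
})

test_that("notch summaries follow the stated formula and quantile convention", {
  ns <- notch_summary(1:9)
  expect_equal(ns$median, 5)
  expect_equal(ns$iqr, 4)   # type-7 linear interpolation
  expect_equal(ns$notch_low, 5 - 1.57 * 4 / 3)
  expect_equal(ns$notch_high, 5 + 1.57 * 4 / 3, tolerance = 1e-12)
  expect_equal(ns$notch_high - ns$median, 2.093, tolerance = 1e-3)
  # constant sample: zero-width notch
  nc <- notch_summary(rep(3, 8))
  expect_equal(nc$notch_low, 3); expect_equal(nc$notch_high, 3)
  # width shrinks as 1/sqrt(n) under concatenation
  n1 <- notch_summary(rep(1:9, 1)); n4 <- notch_summary(rep(1:9, 4))
  expect_equal((n4$notch_high - n4$notch_low) * 2,
               n1$notch_high - n1$notch_low, tolerance = 1e-12)
  expect_error(notch_summary(numeric(0)), "empty")
})

test_that("Wilcoxon rank-sum matches exhaustive enumeration and behaves monotonically", {
  # oracle: all C(6,3) = 20 splits, two-sided
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w_obs <- sum(rank(c(a, b))[1:3])
  splits <- combn(6, 3)
  ranks <- rank(c(a, b))
  w_all <- apply(splits, 2, function(i) sum(ranks[i]))
  p_exact <- 2 * mean(w_all <= w_obs)
  expect_equal(p_exact, 0.1)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, p_exact)
  # identical samples: p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # p decreases monotonically with a growing shift
  withr::local_seed(9)
  base <- rnorm(30)
  ps <- sapply(c(0.2, 0.8, 1.6), function(sh)
    wilcoxon_rank_sum(base, base + sh)$p_value)
  expect_true(all(diff(ps) < 0))
})

test_that("the speed-correlation catalogue recovers generated coupling classes", {
  coupling <- list(
    Discontinuous = c(0.6, -0.6, 0.6, 0, rep(0, 16)),
    Continuous    = c(-0.6, -0.6, 0.6, 0, rep(0, 16)))
  tab <- simulate_feature_table(n_cells_per_mode = 30, frames_per_cell = 25,
                                effect = rep(0, 20), coupling = coupling,
                                seed = 10)
  res <- speed_correlation_catalogue(tab, sprintf("feature_%02d", 1:4))
  cls <- setNames(res$catalogue$class, res$catalogue$feature)
  expect_identical(unname(cls["feature_01"]), "inverted")
  expect_identical(unname(cls["feature_02"]), "both_negative")
  expect_identical(unname(cls["feature_03"]), "both_positive")
  expect_identical(unname(cls["feature_04"]), "ns")
  # all per-cell rs positive -> significant positive median near the target
  expect_equal(res$catalogue[res$catalogue$feature == "feature_03",
                             "median_rs_Discontinuous"], 0.6, tolerance = 0.15)
  # short cells are skipped and counted
  tab_short <- tab[!(tab$cell_track_id %in% c("D1", "C1") & tab$frame >= 10), ]
  res2 <- speed_correlation_catalogue(tab_short, "feature_01", min_frames = 15)
  expect_identical(res2$n_cells_skipped, 2L)
  expect_error(speed_correlation_catalogue(tab, "feature_01", min_frames = 99),
               "no cell trajectories")
})
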