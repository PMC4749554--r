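test_that("protrusion/retraction equal brute-force pixel set differences", {
  px2 <- 0.21^2
  # identical masks
  m <- random_mask()
  e <- protrusion_retraction(m, m, 0.21)
  expect_equal(c(e$protrusion_um2, e$retraction_um2), c(0, 0))
  # shifted 3x3 square: 3 px gained, 3 px lost
  a <- matrix(FALSE, 10, 10); a[4:6, 4:6] <- TRUE
  b <- matrix(FALSE, 10, 10); b[4:6, 5:7] <- TRUE
  e <- protrusion_retraction(a, b, 0.21)
  expect_equal(e$protrusion_um2, 3 * px2)
  expect_equal(e$retraction_um2, 3 * px2)
  # disjoint masks: full areas
  d1 <- matrix(FALSE, 8, 8); d1[1:2, 1:2] <- TRUE
  d2 <- matrix(FALSE, 8, 8); d2[6:7, 6:7] <- TRUE
  e <- protrusion_retraction(d1, d2, 1)
  expect_equal(e$protrusion_um2, 4)
  expect_equal(e$retraction_um2, 4)
  expect_error(protrusion_retraction(d1, matrix(FALSE, 5, 5)), "mismatch")

  # property: protrusion(A,B) == retraction(B,A) on random pairs
  withr::local_seed(5)
  for (i in 1:20) {
    A <- random_mask(); B <- random_mask()
    ab <- protrusion_retraction(A, B, 0.21)
    ba <- protrusion_retraction(B, A, 0.21)
    expect_identical(ab$protrusion_um2, ba$retraction_um2)
    # brute force set-difference oracle
    expect_identical(ab$protrusion_um2, sum(B & !A) * px2)
    expect_identical(ab$retraction_um2, sum(A & !B) * px2)
  }
})

test_that("multi-window series respect nesting and consistency with window 1", {
  # static cell: zeros at all windows
  m <- matrix(FALSE, 12, 12); m[4:8, 4:8] <- TRUE
  ser <- multiwindow_series(rep(list(m), 10), windows = 1:5, pixel_size_um = 1)
  expect_true(all(vapply(ser, function(s)
    all(s$protrusion_um2 == 0) && all(s$retraction_um2 == 0), logical(1))))

  # monotonically growing cell: retraction 0 at every w, protrusion
  # non-decreasing in w (nested-set oracle)
  masks <- lapply(0:7, function(k) {
    f <- matrix(FALSE, 24, 24); f[(9 - k):(15 + k), 9:15] <- TRUE; f
  })
  ser <- multiwindow_series(masks, windows = 1:6, pixel_size_um = 1)
  expect_true(all(vapply(ser, function(s) all(s$retraction_um2 == 0),
                         logical(1))))
  first_pro <- vapply(ser, function(s) s$protrusion_um2[1], numeric(1))
  expect_true(all(diff(first_pro) >= 0))

  # w = 1 equals pairwise consecutive-frame results; series length = n - w
  w1 <- ser[[1]]
  direct <- vapply(1:7, function(t)
    protrusion_retraction(masks[[t]], masks[[t + 1]], 1)$protrusion_um2,
    numeric(1))
  expect_identical(w1$protrusion_um2, direct)
  expect_identical(lengths(lapply(ser, `[[`, "protrusion_um2")),
                   8L - 1:6)
  # short track: empty flagged series
  short <- multiwindow_series(masks[1:3], windows = 5)
  expect_true(short[[1]]$empty)
})

test_that("size distributions normalize, subtract and handle open bins", {
  # count oracle: events [1,1,3], edges [0,2,4]
  d <- size_probability_distribution(c(1, 1, 3), c(0, 2, 4))
  expect_equal(d$probability, c(2 / 3, 1 / 3))
  # out-of-range events fall into the end bins
  d2 <- size_probability_distribution(c(-5, 1, 99), c(0, 2, 4))
  expect_equal(d2$probability, c(2 / 3, 1 / 3))
  # normalization on random inputs
  withr::local_seed(6)
  ev <- rgamma(200, 2, 1)
  edges <- default_bin_edges(ev, width = 1)
  expect_equal(sum(size_probability_distribution(ev, edges)$probability), 1)
  expect_error(size_probability_distribution(numeric(0), c(0, 1)), "zero events")
  expect_error(size_probability_distribution(1, c(0, 0, 1)), "increasing")

  # differences: P - Q sums to 0, antisymmetric, toy oracle
  P <- structure(list(bin_edges = c(0, 1, 2), probability = c(.5, .5)),
                 class = "size_distribution")
  Q <- structure(list(bin_edges = c(0, 1, 2), probability = c(.25, .75)),
                 class = "size_distribution")
  expect_equal(distribution_difference(P, Q), c(.25, -.25))
  expect_equal(distribution_difference(P, Q), -distribution_difference(Q, P))
  expect_equal(sum(distribution_difference(P, Q)), 0)
  expect_equal(distribution_difference(P, P), c(0, 0))
  Qbad <- structure(list(bin_edges = c(0, 1, 3), probability = c(.25, .75)),
                    class = "size_distribution")
  expect_error(distribution_difference(P, Qbad), "mismatched")
})

test_that("cross-correlation profiles follow the sign convention and the direct-sum oracle", {
  withr::local_seed(7)
  p <- rgamma(40, 3, 1)
  # r = p: peak exactly 1 at lag 0
  x0 <- protrusion_retraction_xcov(p, p)
  expect_equal(x0$value[x0$lag == 0], 1)
  expect_equal(which.max(x0$value), which(x0$lag == 0))
  expect_true(all(abs(x0$value) <= 1 + 1e-12))
  # r(t) = p(t-1): protrusion leads, peak at lag -1
  r <- c(mean(p), p[-40])
  xm <- protrusion_retraction_xcov(p, r)
  expect_equal(xm$lag[which.max(xm$value)], -1)
  # length-10 random series against the brute-force direct-sum oracle
  p10 <- rnorm(10); r10 <- rnorm(10)
  prof <- protrusion_retraction_xcov(p10, r10, max_lag = 4)
  for (l in -4:4)
    expect_equal(prof$value[prof$lag == l], bf_xcov(p10, r10, l),
                 tolerance = 1e-12)
  # missing values are imputed by the trajectory mean
  p_na <- p; p_na[c(5, 20)] <- NA
  p_imp <- p; p_imp[c(5, 20)] <- mean(p[-c(5, 20)])
  expect_equal(protrusion_retraction_xcov(p_na, r)$value,
               protrusion_retraction_xcov(p_imp, r)$value)
  # constant series: undefined, flagged
  expect_true(protrusion_retraction_xcov(rep(2, 30), r[1:30])$undefined)
})

test_that("mean |xcov| summaries aggregate cells with equal weight", {
  prof <- function(vals) structure(list(lag = seq(-12, 12), value = vals,
                                        undefined = FALSE),
                                   class = "xcov_profile")
  v1 <- seq(-0.5, 0.5, length.out = 25)
  v2 <- rep(0.2, 25); v3 <- rep(-0.4, 25)
  profiles <- list(cellA = list(`1` = prof(v1)),
                   cellB = list(`1` = prof(v2)),
                   cellC = list(`1` = prof(v3)))
  s <- mean_abs_xcov_summary(profiles)
  # arithmetic oracle: mean of the three per-cell |.| lag-averages
  expect_equal(s$mean, mean(c(mean(abs(v1)), 0.2, 0.4)))
  expect_identical(s$n_cells, 3L)
  # single cell: mean passes through, CI undefined
  s1 <- mean_abs_xcov_summary(list(cellA = list(`1` = prof(v1))))
  expect_equal(s1$mean, mean(abs(v1)))
  expect_true(is.na(s1$ci_low))
  # identical cells: zero-width CI
  s2 <- mean_abs_xcov_summary(list(a = list(`1` = prof(v2)),
                                   b = list(`1` = prof(v2)),
                                   c = list(`1` = prof(v2))))
  expect_equal(s2$ci_low, s2$ci_high)
  expect_equal(s2$ci_low, 0.2)
})

test_that("the Friedman mode comparison matches the exact two-treatment statistic", {
  # identical values in every block: no evidence
  m_eq <- rbind(A = rep(1, 15), B = rep(1, 15))
  expect_gte(friedman_mode_comparison(m_eq)$p_value, 0.99)
  # A > B in all 15 blocks: exact rank statistic
  # ranks (2,1) per block -> chi2 = 12n/(k(k+1)) * sum((Rbar - (k+1)/2)^2) = n
  withr::local_seed(8)
  base <- runif(15)
  m <- rbind(A = base + 0.5, B = base)
  ft <- friedman_mode_comparison(m)
  expect_equal(ft$statistic, 15)
  expect_lt(ft$p_value, 0.01)
  # permuting block order leaves the statistic unchanged
  perm <- sample(15)
  expect_equal(friedman_mode_comparison(m[, perm])$statistic, ft$statistic)
  expect_error(friedman_mode_comparison(m[, 1:2]), "3 blocks")
})
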