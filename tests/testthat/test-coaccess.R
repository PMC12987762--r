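test_that("the distance penalty follows the floored power law", {
  p <- penalty_params(s = 0.75, alpha = 2)
  expect_equal(distance_penalty(1000, p), 0)          # one distance unit
  expect_equal(distance_penalty(0, p), 0)             # floored at zero
  expect_equal(distance_penalty(500, p), 0)           # below one unit
  expect_equal(distance_penalty(5e5, p), 2 * (1 - 500^(-0.75)),
               tolerance = 1e-10)
  expect_equal(distance_penalty(5e5, p), 1.9811, tolerance = 1e-4)
  expect_equal(distance_penalty(1e12, p), 2, tolerance = 1e-4)  # -> alpha
  expect_true(all(diff(distance_penalty(seq(0, 5e5, by = 1e4), p)) >= 0))
})

test_that("window penalty matrices match hand-computed values", {
  start <- c(0, 1e5, 4e5)
  r <- parse_region_ids(sprintf("chr1_%d_%d", start * 2, start * 2 + 1))
  r$start <- start; r$end <- start  # midpoints exactly 0, 100 kb, 400 kb
  w <- list(chrom = "chr1", start = 0, end = 5e5, members = 1:3)
  p <- penalty_params(s = 0.75, alpha = 1)
  pen <- build_penalty_matrix(w, r, p)
  expect_equal(pen[1, 2], 0.9684, tolerance = 1e-4)
  expect_equal(pen[1, 3], 0.9889, tolerance = 1e-4)
  expect_equal(pen[2, 3], 0.9861, tolerance = 1e-4)
  expect_equal(pen, t(pen))
  expect_equal(unname(diag(pen)), rep(0, 3))
  expect_error(build_penalty_matrix(list(members = 1L), r, p), "fewer than 2")
})

test_that("empirical matrices handle perfect, independent and constant columns", {
  x <- cbind(1:10, (1:10) * 3)
  expect_equal(empirical_matrix(x)[1, 2], 1, tolerance = 1e-6)

  set.seed(9)
  n <- 4000
  ind <- matrix(rnorm(3 * n), ncol = 3)
  S <- empirical_matrix(ind)
  expect_true(all(abs(S[upper.tri(S)]) < 3 / sqrt(n)))

  with_const <- cbind(rnorm(20), rep(5, 20), rnorm(20))
  Sc <- empirical_matrix(with_const)
  expect_equal(unname(Sc[2, c(1, 3)]), c(0, 0))
  expect_gte(Sc[2, 2], 1)
  expect_error(empirical_matrix(matrix(1, 1, 3)), "2 observations")
})

test_that("window scores are correlations of the regularized covariance", {
  wm <- list(W = diag(2), Theta = diag(2), converged = TRUE)
  expect_equal(window_scores(wm)[1, 2], 0)

  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- penalized_graphical_lasso(S, matrix(c(0, 0.2, 0.2, 0), 2),
                                   tol = 1e-8, max_iter = 500)
  expect_equal(window_scores(fit)[1, 2], 0.3, tolerance = 1e-6)
  pc <- window_scores(fit, basis = "partial_correlation")
  expect_equal(pc[1, 2], -fit$Theta[1, 2] / fit$Theta[1, 1], tolerance = 1e-10)
  expect_error(window_scores(list(W = -diag(2), Theta = diag(2))),
               "non-positive diagonal")
})

test_that("scores are invariant to rescaling an input region column", {
  set.seed(3)
  counts <- matrix(rpois(200, 3), 20, 10)
  m <- toy_matrix(counts, spacing = 5e4)
  m2 <- toy_matrix(sweep(counts, 2, c(7, rep(1, 9)), "*"), spacing = 5e4)
  w <- make_windows(m$regions, 5e5, 2.5e5)[[1]]
  p <- penalty_params(alpha = 0.1)
  s1 <- window_scores(fit_window(m, w, p))
  s2 <- window_scores(fit_window(m2, w, p))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("alpha bisection agrees with an exhaustive grid scan", {
  sim <- simulate_accessibility(synthetic_spec(150, 12, 2, chrom_length = 4e5,
                                               within_block_corr = 0.5,
                                               seed = 8))
  w <- make_windows(sim$matrix$regions, 5e5, 2.5e5)
  p <- organism_preset("human")
  eligible <- which(vapply(w, function(x) length(x$members), integer(1)) >= 2)
  for (k in eligible[1]) {
    a_grid <- grid_scan_alpha(sim$matrix, w[[k]], p, 0.20, 0.05)
    cal <- calibrate_alpha(sim$matrix, w[k], p, seed = 1)
    # within one grid step on the log scale
    expect_lt(abs(log(cal$alpha) - log(a_grid)),
              (log(1e4) - log(1e-4)) / 400 + 2e-3)
  }
})

test_that("vacuous constraints return the lower search bound and equal windows average to themselves", {
  sim <- simulate_accessibility(synthetic_spec(100, 10, 2, chrom_length = 3e5,
                                               seed = 2))
  w <- make_windows(sim$matrix$regions, 5e5, 2.5e5)
  p <- organism_preset("human")
  cal <- calibrate_alpha(sim$matrix, w, p, zero_frac_min = 0,
                         longrange_nonzero_max = 1, seed = 1)
  expect_equal(cal$alpha, 1e-4)

  dup <- c(w[1], w[1], w[1])
  one <- calibrate_alpha(sim$matrix, w[1], p, seed = 1)
  three <- calibrate_alpha(sim$matrix, dup, p, seed = 1)
  expect_equal(three$alpha, one$alpha)
  expect_length(three$window_alphas, 3)
})

test_that("network assembly reconciles window scores by mean and flags sign conflicts", {
  sim <- simulate_accessibility(synthetic_spec(200, 30, 3, chrom_length = 7.5e5,
                                               within_block_corr = 0.7,
                                               seed = 4))
  m <- sim$matrix
  w <- make_windows(m$regions, 5e5, 2.5e5)
  p <- organism_preset("human")
  p$alpha <- 0.1
  net <- suppressWarnings(estimate_network(m, p, windows = w))

  # oracle: accumulate per-window scores by hand
  n <- nrow(m$regions)
  acc <- matrix(0, n, n); cnt <- matrix(0, n, n)
  pos <- matrix(FALSE, n, n); neg <- matrix(FALSE, n, n)
  for (wi in w) {
    if (length(wi$members) < 2) next
    sc <- window_scores(fit_window(m, wi, p))
    idx <- wi$members
    acc[idx, idx] <- acc[idx, idx] + sc
    cnt[idx, idx] <- cnt[idx, idx] + 1
    pos[idx, idx] <- pos[idx, idx] | sc > 1e-10
    neg[idx, idx] <- neg[idx, idx] | sc < -1e-10
  }
  expected <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  expected[pos & neg] <- 0
  diag(expected) <- 0
  expected[abs(expected) < 1e-10] <- 0
  got <- as.matrix(net$scores)
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  expect_equal(net$n_sign_conflicts, sum((pos & neg)[upper.tri(pos)]))
  # support counts how many windows cover each scored pair
  expect_equal(unname(as.matrix(net$support)),
               unname(cnt * upper.tri(cnt) + t(cnt * upper.tri(cnt))))
})

test_that("a single window network equals that window's scores and bounds hold", {
  sim <- simulate_accessibility(synthetic_spec(150, 10, 2, chrom_length = 2.5e5,
                                               within_block_corr = 0.6,
                                               seed = 6))
  w <- make_windows(sim$matrix$regions, 5e5, 5e5)
  expect_length(w, 1)
  p <- organism_preset("human"); p$alpha <- 0.15
  net <- estimate_network(sim$matrix, p, windows = w)
  sc <- window_scores(fit_window(sim$matrix, w[[1]], p))
  diag(sc) <- 0
  expect_equal(unname(as.matrix(net$scores)), unname(sc), tolerance = 1e-12)
  expect_true(all(abs(net$scores@x) <= 1))
  expect_true(Matrix::isSymmetric(net$scores))
})

test_that("network estimation is invariant to the worker count", {
  sim <- simulate_accessibility(synthetic_spec(120, 24, 3, chrom_length = 6e5,
                                               within_block_corr = 0.6,
                                               seed = 12))
  p <- organism_preset("human"); p$alpha <- 0.12
  n1 <- suppressWarnings(estimate_network(sim$matrix, p, n_jobs = 1))
  n2 <- suppressWarnings(estimate_network(sim$matrix, p, n_jobs = 3))
  expect_identical(link_table(n1), link_table(n2))
})

test_that("oversized windows are skipped with a warning and alpha must be set", {
  set.seed(3)
  # 12 regions every 60 kb: windows of 8, 8 and 4 members
  m <- toy_matrix(matrix(rpois(60 * 12, 2), 60, 12), spacing = 6e4)
  p <- organism_preset("human")
  expect_error(estimate_network(m, p), "alpha is not set")
  p$alpha <- 0.1
  expect_warning(net <- estimate_network(m, p, max_elements = 6),
                 "max_elements")
  expect_equal(net$n_windows_skipped, 2L)
  expect_equal(net$n_windows_fit, 1L)
})
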