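# Independent reference implementations used as oracles. These deliberately
# share no code path with the package internals they check.

# proximal-gradient (ISTA, backtracking line search) minimizer of
#   tr(S Theta) - log det Theta + sum_{i != j} P_ij |Theta_ij|
# operating directly on Theta, unlike the package's W-based block
# coordinate descent
ref_penalized_glasso <- function(S, P, max_iter = 50000, tol = 1e-10) {
  p <- nrow(S)
  Theta <- diag(1 / diag(S), p)
  soft <- function(M, Thr) {
    out <- sign(M) * pmax(abs(M) - Thr, 0)
    diag(out) <- diag(M)
    out
  }
  smooth_f <- function(Th) {
    ld <- determinant(Th, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    sum(S * Th) - as.numeric(ld$modulus)
  }
  f <- smooth_f(Theta)
  t0 <- 1
  for (it in seq_len(max_iter)) {
    W <- solve(Theta)
    G <- S - W
    t <- t0
    repeat {
      cand <- soft(Theta - t * G, t * P)
      cand <- (cand + t(cand)) / 2
      fc <- smooth_f(cand)
      d <- cand - Theta
      if (is.finite(fc) &&
          fc <= f + sum(G * d) + sum(d * d) / (2 * t) + 1e-15) break
      t <- t / 2
      if (t < 1e-14) { cand <- Theta; fc <- f; break }
    }
    delta <- max(abs(cand - Theta))
    Theta <- cand
    f <- fc
    t0 <- min(t * 2, 1)
    if (delta < tol) break
  }
  list(Theta = Theta, W = solve(Theta))
}

# random correlation-like positive definite matrix with unit diagonal
random_corr <- function(p) {
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p + diag(0.5, p)
  D <- diag(1 / sqrt(diag(S)))
  D %*% S %*% D
}

# random symmetric non-negative penalty matrix with zero diagonal
random_penalty <- function(p, max_pen = 0.5) {
  P <- matrix(runif(p * p, 0, max_pen), p)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

# closed-form 2x2 graphical lasso with unit-diagonal S: the regularized
# covariance off-diagonal is the soft-thresholded empirical one
glasso_2x2_closed_form <- function(s12, rho) {
  w12 <- sign(s12) * max(abs(s12) - rho, 0)
  W <- matrix(c(1, w12, w12, 1), 2)
  list(W = W, Theta = solve(W))
}

# exhaustive log-grid search for the lowest alpha meeting the calibration
# constraints in one window (oracle for the bisection)
grid_scan_alpha <- function(m, w, p, zero_frac_min, longrange_nonzero_max,
                            n_grid = 400) {
  mid <- region_midpoints(m$regions[w$members, , drop = FALSE])
  grid <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  for (alpha in grid) {
    pa <- p
    pa$alpha <- alpha
    wm <- fit_window(m, w, pa)
    sc <- window_scores(wm, basis = "partial_correlation")
    ut <- upper.tri(sc)
    d <- abs(outer(mid, mid, "-"))
    zf <- mean(abs(sc[ut]) < 1e-10)
    long <- ut & d > p$distance_constraint
    ln <- if (any(long)) mean(abs(sc[long]) >= 1e-10) else 0
    if (zf >= zero_frac_min && ln <= longrange_nonzero_max) return(alpha)
  }
  NA_real_
}

# brute-force candidate-vs-reference matcher: double loop with manual
# half-open interval intersection, both end assignments
brute_force_match <- function(cand_a, cand_b, ref) {
  ov1 <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 && min(e1, e2) - max(s1, s2) >= 1
  }
  n <- nrow(cand_a)
  out <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(ref))) {
      straight <- ov1(cand_a$chrom[i], cand_a$start[i], cand_a$end[i],
                      ref$chrom_a[j], ref$start_a[j], ref$end_a[j]) &&
        ov1(cand_b$chrom[i], cand_b$start[i], cand_b$end[i],
            ref$chrom_b[j], ref$start_b[j], ref$end_b[j])
      swapped <- ov1(cand_a$chrom[i], cand_a$start[i], cand_a$end[i],
                     ref$chrom_b[j], ref$start_b[j], ref$end_b[j]) &&
        ov1(cand_b$chrom[i], cand_b$start[i], cand_b$end[i],
            ref$chrom_a[j], ref$start_a[j], ref$end_a[j])
      if (straight || swapped) { out[i] <- 1L; break }
    }
  }
  out
}

# random interval table on a couple of chromosomes
random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e4) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(20:200, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# small accessibility matrix straight from a dense count matrix on one
# chromosome, regions spaced `spacing` bp apart
toy_matrix <- function(counts, spacing = 1000, width = 200) {
  p <- ncol(counts)
  start <- spacing * seq_len(p)
  regions <- data.frame(chrom = "chr1", start = start,
                        end = start + width,
                        id = sprintf("chr1_%d_%d", start, start + width),
                        stringsAsFactors = FALSE)
  accessibility_matrix(Matrix::Matrix(counts, sparse = TRUE),
                       regions = regions)
}

# KKT residuals of the penalized graphical lasso solution
kkt_violation <- function(S, P, W, Theta, zero_tol = 1e-8) {
  R <- W - S   # stationarity: W - S = P * sign(Theta) on the support
  viol <- 0
  p <- nrow(S)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      if (abs(Theta[i, j]) > zero_tol) {
        viol <- max(viol, abs(R[i, j] - P[i, j] * sign(Theta[i, j])))
      } else {
        viol <- max(viol, max(abs(R[i, j]) - P[i, j], 0))
      }
    }
  }
  viol
}
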