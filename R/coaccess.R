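#' Penalty parameters for distance-penalized co-accessibility
#'
#' Bundles the knobs of the distance penalty
#' \deqn{\rho_{ij} = \left(1 - d_{ij}^{-s}\right)\alpha}
#' where d is the pair's midpoint distance expressed in kilobases
#' (`distance_scale` bp per unit) and s the power-law decay exponent of
#' chromatin contact frequency: 0.75 for human/mouse (tension-globule
#' polymer model), 0.85 for Drosophila. Negative raw values (d at or below
#' one distance unit) are floored at zero, so immediately adjacent regions
#' are unpenalized and the penalty grows towards `alpha` with distance.
#'
#' @param s Power-law exponent (> 0).
#' @param alpha Penalty scale; `NA` until calibrated (see
#'   [calibrate_alpha()]).
#' @param window_size Maximum cis-interaction distance in bp, also the
#'   sliding-window width (default 500 kb).
#' @param distance_scale Base pairs per distance unit (default 1000: d in kb).
#' @param distance_constraint Distance in bp beyond which a pair counts as
#'   long-range for the calibration constraints (default `window_size / 2`).
#' @return A `penalty_params` list.
#' @export
penalty_params <- function(s = 0.75, alpha = NA_real_, window_size = 5e5,
                           distance_scale = 1000,
                           distance_constraint = window_size / 2) {
  stopifnot(s > 0, is.na(alpha) || alpha >= 0, window_size > 0,
            distance_scale > 0, distance_constraint <= window_size)
  structure(list(s = s, alpha = alpha, window_size = window_size,
                 distance_scale = distance_scale,
                 distance_constraint = distance_constraint),
            class = "penalty_params")
}

#' Distance penalty for a pair of regions
#'
#' @param d Midpoint distance(s) in bp (vectorized).
#' @param p A [penalty_params()] with `alpha` set.
#' @return `max(0, (1 - (d / distance_scale)^(-s)) * alpha)`.
#' @examples
#' distance_penalty(5e5, penalty_params(alpha = 2))
#' @export
distance_penalty <- function(d, p) {
  stopifnot(all(d >= 0), !is.na(p$alpha))
  pmax(0, (1 - (d / p$distance_scale)^(-p$s)) * p$alpha)
}

#' Penalty matrix for a genomic window
#'
#' @param w A window from [make_windows()].
#' @param regions Region table the window indexes into.
#' @param p A [penalty_params()] with `alpha` set.
#' @return Symmetric non-negative matrix over the window's members with zero
#'   diagonal.
#' @export
build_penalty_matrix <- function(w, regions, p) {
  members <- w$members
  if (length(members) < 2L) stop("window has fewer than 2 member regions")
  mid <- region_midpoints(regions[members, , drop = FALSE])
  d <- abs(outer(mid, mid, "-"))
  pen <- matrix(distance_penalty(as.vector(d), p), nrow = length(mid))
  diag(pen) <- 0
  dimnames(pen) <- list(regions$id[members], regions$id[members])
  pen
}

#' Empirical correlation matrix of a window's regions
#'
#' Pearson correlation of the region columns across observations (cells or
#' metacells). Zero-variance columns get self-correlation 1 and
#' cross-correlation 0. When the smallest eigenvalue falls below `ridge` the
#' diagonal is ridged so the graphical lasso input is positive definite.
#'
#' @param sub Observations x regions matrix (dense or sparse).
#' @param ridge Ridge constant (default 1e-4).
#' @return Symmetric correlation-like matrix.
#' @export
empirical_matrix <- function(sub, ridge = 1e-4) {
  sub <- as.matrix(sub)
  if (nrow(sub) < 2L) stop("need at least 2 observations")
  if (ncol(sub) < 2L) stop("need at least 2 regions")
  S <- suppressWarnings(stats::cor(sub))
  constant <- apply(sub, 2, function(col) stats::var(col) == 0)
  if (any(is.na(S))) S[is.na(S)] <- 0
  diag(S) <- 1
  S[constant, ] <- 0
  S[, constant] <- 0
  diag(S) <- 1
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < ridge) S <- S + diag(ridge, nrow(S))
  S
}

#' Co-accessibility scores of a fitted window model
#'
#' The default basis reports the regularized covariance W as a correlation,
#' `W_ij / sqrt(W_ii W_jj)`; the alternative reports partial correlations
#' from the precision matrix, `-Theta_ij / sqrt(Theta_ii Theta_jj)`.
#' Entries below `zero_tol` in magnitude are stored as exact zeros.
#'
#' @param wm Window model as returned by [fit_window()].
#' @param basis `"regularized_covariance"` (default) or
#'   `"partial_correlation"`.
#' @param zero_tol Magnitude below which a score is an exact zero.
#' @return Symmetric score matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
window_scores <- function(wm, basis = c("regularized_covariance",
                                        "partial_correlation"),
                          zero_tol = 1e-10) {
  basis <- match.arg(basis)
  M <- if (basis == "regularized_covariance") wm$W else wm$Theta
  if (any(diag(M) <= 0)) stop("non-positive diagonal in fitted matrix")
  sc <- M / sqrt(diag(M) %o% diag(M))
  if (basis == "partial_correlation") {
    sc <- -sc
    diag(sc) <- 1
  }
  sc[abs(sc) < zero_tol] <- 0
  sc
}

#' Fit the penalized model in one genomic window
#'
#' Correlation of the window's region columns, distance-penalty matrix, and
#' the element-wise penalized graphical lasso.
#'
#' @param m An `AccessibilityMatrix`.
#' @param w A window from [make_windows()].
#' @param p A [penalty_params()] with `alpha` set.
#' @param ridge,tol,max_iter Numerical controls (see [empirical_matrix()],
#'   [penalized_graphical_lasso()]).
#' @return A window model: list with `window`, `S`, `penalty`, `W`, `Theta`,
#'   `converged`.
#' @export
fit_window <- function(m, w, p, ridge = 1e-4, tol = 1e-4, max_iter = 100L) {
  sub <- m$counts[, w$members, drop = FALSE]
  S <- empirical_matrix(sub, ridge = ridge)
  pen <- build_penalty_matrix(w, m$regions, p)
  fit <- suppressWarnings(
    penalized_graphical_lasso(S, pen, tol = tol, max_iter = max_iter))
  list(window = w, S = S, penalty = pen, W = fit$W, Theta = fit$Theta,
       converged = fit$converged)
}

# constraint check used by the alpha calibration: zero fraction over all
# pairs, and non-zero fraction among long-range pairs
window_sparsity_stats <- function(scores, mid, distance_constraint,
                                  zero_tol = 1e-10) {
  p <- nrow(scores)
  ut <- upper.tri(scores)
  zero_frac <- mean(abs(scores[ut]) < zero_tol)
  d <- abs(outer(mid, mid, "-"))
  long <- ut & d > distance_constraint
  longrange_nonzero <- if (any(long)) mean(abs(scores[long]) >= zero_tol) else 0
  list(zero_frac = zero_frac, longrange_nonzero = longrange_nonzero,
       n_pairs = sum(ut), n_long = sum(long))
}

# lowest alpha in [lo, hi] whose fit satisfies both sparsity constraints,
# by bisection on log(alpha); NA when even `hi` fails
calibrate_window_alpha <- function(m, w, p, zero_frac_min, longrange_nonzero_max,
                                   sparsity_basis = "precision",
                                   lo = 1e-4, hi = 1e4, depth = 50L,
                                   ridge = 1e-4, tol = 1e-4, max_iter = 100L,
                                   zero_tol = 1e-10) {
  mid <- region_midpoints(m$regions[w$members, , drop = FALSE])
  basis <- if (sparsity_basis == "precision") "partial_correlation"
           else "regularized_covariance"
  ok <- function(alpha) {
    pa <- p
    pa$alpha <- alpha
    wm <- fit_window(m, w, pa, ridge = ridge, tol = tol, max_iter = max_iter)
    st <- window_sparsity_stats(window_scores(wm, basis = basis,
                                              zero_tol = zero_tol), mid,
                                p$distance_constraint, zero_tol)
    st$zero_frac >= zero_frac_min && st$longrange_nonzero <= longrange_nonzero_max
  }
  if (ok(lo)) return(lo)
  if (!ok(hi)) return(NA_real_)
  llo <- log(lo); lhi <- log(hi)
  for (i in seq_len(depth)) {
    mid_l <- (llo + lhi) / 2
    if (ok(exp(mid_l))) lhi <- mid_l else llo <- mid_l
    if (lhi - llo < 1e-3) break
  }
  exp(lhi)
}

#' Calibrate the penalty scale alpha
#'
#' Alpha is chosen as the lowest penalty scale such that, in a fitted
#' window, at least `zero_frac_min` (default 20%) of all region pairs have a
#' zero co-accessibility score — guaranteeing minimal sparsity — and at most
#' `longrange_nonzero_max` (default 5%) of the long-range pairs (midpoint
#' distance beyond `distance_constraint`) remain non-zero — keeping most
#' connections short-range. The per-window alpha is found by bisection on a
#' log grid over `[1e-4, 1e4]`; the returned alpha is the mean over a random
#' sample of eligible windows.
#'
#' @param m An `AccessibilityMatrix`.
#' @param windows Windows from [make_windows()].
#' @param p A [penalty_params()]; its `alpha` is ignored.
#' @param n_sample_windows Number of windows to sample (without replacement;
#'   all windows when fewer are eligible).
#' @param zero_frac_min Minimum fraction of zero-score pairs per window.
#' @param longrange_nonzero_max Maximum fraction of non-zero long-range
#'   pairs per window.
#' @param seed Seed for the window sampling.
#' @param max_elements Windows with more regions are not eligible.
#' @param ridge,tol,max_iter,zero_tol Numerical controls.
#' @return List with `alpha` (the mean), `window_alphas`, and
#'   `window_indices` of the sampled windows (indices into `windows`).
#' @export
calibrate_alpha <- function(m, windows, p, n_sample_windows = 100L,
                            zero_frac_min = 0.20, longrange_nonzero_max = 0.05,
                            sparsity_basis = c("precision", "score"),
                            seed = 1L, max_elements = 200L,
                            ridge = 1e-4, tol = 1e-4, max_iter = 100L,
                            zero_tol = 1e-10) {
  sparsity_basis <- match.arg(sparsity_basis)
  sizes <- vapply(windows, function(w) length(w$members), integer(1))
  eligible <- which(sizes >= 2L & sizes <= max_elements)
  if (length(eligible) == 0L) stop("no eligible window (2..max_elements members)")
  set.seed(seed)
  take <- if (length(eligible) > n_sample_windows) {
    sort(sample(eligible, n_sample_windows))
  } else eligible
  alphas <- rep(NA_real_, length(take))
  for (i in seq_along(take)) {
    alphas[i] <- calibrate_window_alpha(
      m, windows[[take[i]]], p, zero_frac_min, longrange_nonzero_max,
      sparsity_basis = sparsity_basis,
      ridge = ridge, tol = tol, max_iter = max_iter, zero_tol = zero_tol)
  }
  skipped <- is.na(alphas)
  if (any(skipped)) {
    warning(sprintf("no alpha satisfied the constraints in %d window(s); skipped",
                    sum(skipped)))
  }
  if (all(skipped)) stop("alpha calibration failed in every sampled window")
  list(alpha = mean(alphas[!skipped]),
       window_alphas = alphas[!skipped],
       window_indices = take[!skipped])
}

#' Estimate the genome-wide co-accessibility network
#'
#' Fits the distance-penalized graphical lasso in every window with
#' 2..`max_elements` member regions and reconciles window-level scores into
#' one network: a pair seen in several windows gets the arithmetic mean of
#' its window scores, and pairs whose window scores disagree in sign are set
#' to zero and flagged. The result is independent of `n_jobs`.
#'
#' @param m An `AccessibilityMatrix`.
#' @param p A [penalty_params()] with `alpha` set (calibrate first if not).
#' @param windows Windows from [make_windows()]; defaults to tiling the
#'   region set at `p$window_size` with 50% overlap.
#' @param max_elements Maximum window size in regions; larger windows are
#'   skipped with a warning.
#' @param n_jobs Worker processes for the window fits (forked; identical
#'   output for any value).
#' @param basis Score basis, see [window_scores()].
#' @param ridge,tol,max_iter,zero_tol Numerical controls.
#' @return A `CoaccessNetwork`: list with `regions`, `scores` (sparse
#'   symmetric, `[-1, 1]`), `support` (windows per pair), `n_sign_conflicts`,
#'   `params`.
#' @export
estimate_network <- function(m, p, windows = NULL, max_elements = 200L,
                             n_jobs = 1L,
                             basis = "regularized_covariance",
                             ridge = 1e-4, tol = 1e-4, max_iter = 100L,
                             zero_tol = 1e-10) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  if (is.na(p$alpha)) stop("alpha is not set; run calibrate_alpha() first")
  if (is.null(windows)) windows <- make_windows(m$regions, p$window_size)
  sizes <- vapply(windows, function(w) length(w$members), integer(1))
  fit_idx <- which(sizes >= 2L & sizes <= max_elements)
  too_big <- which(sizes > max_elements)
  if (length(too_big) > 0) {
    warning(sprintf(
      "skipping %d window(s) exceeding max_elements = %d regions: %s",
      length(too_big), max_elements,
      paste(utils::head(vapply(windows[too_big], function(w)
        sprintf("%s:%d-%d (%d)", w$chrom, w$start, w$end, length(w$members)),
        character(1)), 10), collapse = ", ")))
  }
  if (length(fit_idx) == 0L) stop("no fittable window")

  one <- function(k) {
    w <- windows[[k]]
    wm <- fit_window(m, w, p, ridge = ridge, tol = tol, max_iter = max_iter)
    sc <- window_scores(wm, basis = basis, zero_tol = zero_tol)
    q <- length(w$members)
    ut <- which(upper.tri(sc), arr.ind = TRUE)
    list(i = w$members[ut[, 1]], j = w$members[ut[, 2]],
         x = sc[ut], converged = wm$converged)
  }
  fits <- if (n_jobs > 1L) {
    parallel::mclapply(fit_idx, one, mc.cores = n_jobs, mc.preschedule = TRUE)
  } else {
    lapply(fit_idx, one)
  }
  errs <- vapply(fits, inherits, logical(1), "try-error")
  if (any(errs)) stop("window fit failed: ", fits[[which(errs)[1]]])

  n <- nrow(m$regions)
  ii <- unlist(lapply(fits, `[[`, "i"), use.names = FALSE)
  jj <- unlist(lapply(fits, `[[`, "j"), use.names = FALSE)
  xx <- unlist(lapply(fits, `[[`, "x"), use.names = FALSE)
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  key <- (ii - 1) * n + jj
  uk <- sort(unique(key))
  pos <- match(key, uk)
  nk <- length(uk)
  sums <- as.vector(rowsum(xx, pos, reorder = TRUE))
  cnts <- tabulate(pos, nbins = nk)
  haspos <- as.vector(rowsum(as.numeric(xx > zero_tol), pos)) > 0
  hasneg <- as.vector(rowsum(as.numeric(xx < -zero_tol), pos)) > 0
  mean_sc <- sums / cnts
  conflict <- haspos & hasneg
  mean_sc[conflict] <- 0
  ki <- (uk - 1) %/% n + 1
  kj <- (uk - 1) %% n + 1
  keep <- abs(mean_sc) >= zero_tol
  scores <- Matrix::sparseMatrix(i = ki[keep], j = kj[keep], x = mean_sc[keep],
                                 dims = c(n, n), symmetric = TRUE)
  support <- Matrix::sparseMatrix(i = ki, j = kj, x = cnts,
                                  dims = c(n, n), symmetric = TRUE)
  dimnames(scores) <- list(m$regions$id, m$regions$id)
  dimnames(support) <- list(m$regions$id, m$regions$id)
  if (any(conflict)) {
    warning(sprintf("%d pair(s) with sign-inconsistent window scores set to 0",
                    sum(conflict)))
  }
  structure(list(regions = m$regions, scores = scores, support = support,
                 n_sign_conflicts = sum(conflict),
                 n_windows_fit = length(fit_idx),
                 n_windows_skipped = length(too_big),
                 converged_all = all(vapply(fits, `[[`, logical(1), "converged")),
                 params = p, basis = basis),
            class = "CoaccessNetwork")
}

#' @export
print.CoaccessNetwork <- function(x, ...) {
  cat(sprintf(
    "CoaccessNetwork: %d regions, %d non-zero pairs (%d window(s) fitted, alpha = %.4g)\n",
    nrow(x$regions), length(x$scores@x), x$n_windows_fit, x$params$alpha))
  invisible(x)
}

#' Network link table
#'
#' @param net A `CoaccessNetwork`.
#' @param min_abs_score Keep pairs with `|score| >=` this threshold.
#' @return `data.frame` with columns `Peak1`, `Peak2`, `coaccess`, sorted by
#'   chromosome, then Peak1 start, then Peak2 start.
#' @export
link_table <- function(net, min_abs_score = 0) {
  su <- methods::as(methods::as(net$scores, "generalMatrix"), "TsparseMatrix")
  sel <- su@i < su@j & abs(su@x) >= max(min_abs_score, 0)
  i <- su@i[sel] + 1L
  j <- su@j[sel] + 1L
  x <- su@x[sel]
  r <- net$regions
  ord <- order(r$chrom[i], r$start[i], r$start[j], method = "radix")
  data.frame(Peak1 = r$id[i][ord], Peak2 = r$id[j][ord],
             coaccess = x[ord], stringsAsFactors = FALSE)
}
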