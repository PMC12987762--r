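#' Specification of a planted-block synthetic dataset
#'
#' Desk-scale stand-in for a one-chromosome scATAC-seq experiment with known
#' co-accessibility structure. Region midpoints are placed uniformly at
#' random along the chromosome and sorted; the planted blocks (ground-truth
#' co-accessible modules) are contiguous runs of regions, so the structure
#' is cis-local and within window reach. Within a cell, regions of one block
#' share a latent Gaussian factor with loading `sqrt(within_block_corr)`;
#' counts are obtained from the latent propensities through a Gaussian
#' copula: Poisson marginals via `qpois(pnorm(z), rate)`, or Bernoulli
#' detection via a probit threshold.
#'
#' @param n_cells Number of cells.
#' @param n_regions Number of regions.
#' @param n_blocks Number of equal-size planted blocks.
#' @param block_coverage Fraction of regions belonging to planted blocks
#'   (default 0.6). Blocks are contiguous runs of
#'   `floor(block_coverage * n_regions / n_blocks)` regions separated by
#'   background runs, so that planted modules stay compact relative to the
#'   long-range distance threshold -- the regime the co-accessibility model
#'   assumes -- while background regions (label 0) emulate independent
#'   peaks.
#' @param chrom_length Chromosome length in bp; the default keeps the
#'   spacing at one region per 25 kb.
#' @param within_block_corr Latent correlation within a block, in `[0, 1)`.
#' @param depth_mean Expected total counts per cell; the default of one
#'   expected count per region emulates moderately deep data.
#' @param noise_model `"poisson"` or `"bernoulli"`.
#' @param region_width Width of every region in bp.
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells, n_regions, n_blocks,
                           chrom_length = 25000 * n_regions,
                           within_block_corr = 0.6,
                           block_coverage = 0.6,
                           depth_mean = n_regions,
                           noise_model = c("poisson", "bernoulli"),
                           region_width = 500, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_cells >= 2, n_regions >= 2, n_blocks >= 0,
            within_block_corr >= 0, within_block_corr < 1,
            block_coverage > 0, block_coverage <= 1,
            depth_mean > 0, chrom_length > n_regions * region_width)
  if (n_blocks > 0 && floor(block_coverage * n_regions / n_blocks) < 2) {
    stop("block_coverage * n_regions / n_blocks must allow blocks of >= 2 regions")
  }
  structure(list(n_cells = n_cells, n_regions = n_regions,
                 n_blocks = n_blocks, chrom_length = chrom_length,
                 within_block_corr = within_block_corr,
                 block_coverage = block_coverage,
                 depth_mean = depth_mean, noise_model = noise_model,
                 region_width = region_width,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate an accessibility matrix with planted co-accessible blocks
#'
#' @param spec A [synthetic_spec()].
#' @param window_size Used only to warn when a planted block spans more than
#'   a window (its structure would be partly invisible to window-wise
#'   estimation); default 500 kb.
#' @return List with `matrix` (an `AccessibilityMatrix`) and `blocks`
#'   (integer ground-truth label per region; 0 = no block).
#' @examples
#' sim <- simulate_accessibility(synthetic_spec(50, 20, 2, seed = 7))
#' dim(sim$matrix)
#' @export
simulate_accessibility <- function(spec, window_size = 5e5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  p <- spec$n_regions
  half <- spec$region_width / 2
  mid <- sort(round(stats::runif(p, half, spec$chrom_length - half)))
  start <- as.integer(round(mid - half))
  end <- as.integer(start + spec$region_width)
  regions <- data.frame(chrom = "chr1", start = start, end = end,
                        id = sprintf("chr1_%d_%d", start, end),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(regions$id)) {
    # re-jitter collided midpoints deterministically
    dup <- which(duplicated(regions$id))
    start[dup] <- start[dup] + seq_along(dup)
    end[dup] <- end[dup] + seq_along(dup)
    regions$start <- start; regions$end <- end
    regions$id <- sprintf("chr1_%d_%d", start, end)
  }

  blocks <- integer(p)
  if (spec$n_blocks > 0) {
    # compact contiguous blocks interleaved with background runs: block b
    # occupies `per` regions starting at an evenly spaced offset
    per <- max(2L, as.integer(floor(spec$block_coverage * p / spec$n_blocks)))
    stride <- p / spec$n_blocks
    for (b in seq_len(spec$n_blocks)) {
      from <- as.integer(round((b - 1) * stride)) + 1L
      to <- min(from + per - 1L, p)
      blocks[from:to] <- b
    }
    spans <- vapply(seq_len(spec$n_blocks), function(b) {
      mb <- mid[blocks == b]
      max(mb) - min(mb)
    }, numeric(1))
    if (any(spans > window_size)) {
      warning(sprintf(
        "%d planted block(s) span more than the %d bp window; their structure is partly invisible to window-wise estimation",
        sum(spans > window_size), as.integer(window_size)))
    }
  }

  r <- spec$within_block_corr
  f <- matrix(stats::rnorm(n * max(spec$n_blocks, 1)), nrow = n)
  eps <- matrix(stats::rnorm(n * p), nrow = n)
  z <- eps
  if (spec$n_blocks > 0 && r > 0) {
    in_block <- blocks > 0
    z[, in_block] <- sqrt(r) * f[, blocks[in_block], drop = FALSE] +
      sqrt(1 - r) * eps[, in_block, drop = FALSE]
  }

  rate0 <- spec$depth_mean / p
  if (spec$noise_model == "poisson") {
    counts <- matrix(stats::qpois(stats::pnorm(z), rate0), nrow = n)
  } else {
    p0 <- min(rate0, 0.99)
    counts <- matrix(as.integer(z > stats::qnorm(1 - p0)), nrow = n)
  }
  mat <- accessibility_matrix(Matrix::Matrix(counts, sparse = TRUE),
                              regions = regions)
  list(matrix = mat, blocks = blocks)
}
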