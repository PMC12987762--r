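#' Binarize accessibility counts
#'
#' Sets every positive count to 1. Kept for comparison only: the default
#' pipeline works on raw counts, which give the best downstream
#' enhancer-promoter predictions; binarization neither helps nor (much)
#' hurts.
#'
#' @param m An `AccessibilityMatrix`.
#' @return The binarized `AccessibilityMatrix` (same sparsity pattern).
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  counts <- m$counts
  counts@x <- rep(1, length(counts@x))
  accessibility_matrix(counts, regions = m$regions, cell_ids = m$cell_ids)
}

#' Per-cell total-count normalization
#'
#' Scales each cell so its total equals the median per-cell total of the
#' input, keeping count magnitudes comparable to raw data. Provided only to
#' enable comparisons with normalization-first workflows; total-count
#' normalization of scATAC counts can degrade co-accessibility estimates and
#' is off by default.
#'
#' @param m An `AccessibilityMatrix`; every cell must have total count > 0.
#' @return The row-rescaled `AccessibilityMatrix`.
#' @export
normalize_total <- function(m) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0)) {
    bad <- m$cell_ids[totals == 0]
    stop("cells with zero total count: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  target <- stats::median(totals)
  counts <- Matrix::Diagonal(x = target / totals) %*% m$counts
  accessibility_matrix(counts, regions = m$regions, cell_ids = m$cell_ids)
}

#' Filter regions by detection
#'
#' Keeps regions detected (count > 0) in at least `min_cells` cells. The
#' default of 1 discards only never-seen peaks, the minimal filtering under
#' which co-accessibility estimation is well defined.
#'
#' @param m An `AccessibilityMatrix`.
#' @param min_cells Minimum number of cells a region must be detected in.
#' @return The filtered `AccessibilityMatrix`; column order preserved.
#' @export
filter_regions <- function(m, min_cells = 1L) {
  stopifnot(inherits(m, "AccessibilityMatrix"), min_cells >= 0)
  detected <- Matrix::colSums(m$counts > 0)
  keep <- which(detected >= min_cells)
  if (length(keep) == 0L) {
    stop(sprintf("no region detected in >= %d cells; nothing left", min_cells))
  }
  accessibility_matrix(m$counts[, keep, drop = FALSE],
                       regions = m$regions[keep, , drop = FALSE],
                       cell_ids = m$cell_ids)
}
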