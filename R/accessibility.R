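#' Construct an accessibility matrix
#'
#' Binds a cells x regions sparse count matrix to its ordered region set.
#' Counts are stored column-oriented (`dgCMatrix`), so extracting the regions
#' of a genomic window is a cheap column slice — the dominant operation of
#' the window-wise network fit.
#'
#' @param counts A cells x regions matrix (dense or any `Matrix` class);
#'   coerced to `dgCMatrix`. Must be non-negative.
#' @param regions Region table (`chrom`, `start`, `end`, `id`) matching the
#'   columns, or `NULL` to parse it from `colnames(counts)`.
#' @param cell_ids Cell identifiers; default `rownames(counts)` or generated.
#' @return An `AccessibilityMatrix`: list with `counts` (dgCMatrix),
#'   `regions` (data.frame) and `cell_ids`.
#' @export
accessibility_matrix <- function(counts, regions = NULL, cell_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (min(counts@x, 0) < 0) stop("counts must be non-negative")
  if (is.null(regions)) {
    if (is.null(colnames(counts))) {
      stop("regions not given and counts has no column names to parse")
    }
    regions <- parse_region_ids(colnames(counts))
  }
  if (nrow(regions) != ncol(counts)) {
    stop(sprintf("region table has %d rows but counts has %d columns",
                 nrow(regions), ncol(counts)))
  }
  if (anyDuplicated(regions$id)) stop("duplicate region ids")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  rownames(regions) <- NULL
  dimnames(counts) <- list(cell_ids, regions$id)
  structure(list(counts = counts, regions = regions, cell_ids = cell_ids),
            class = "AccessibilityMatrix")
}

#' @export
print.AccessibilityMatrix <- function(x, ...) {
  nnz <- length(x$counts@x)
  cat(sprintf(
    "AccessibilityMatrix: %d cells x %d regions (%d chromosome%s), %.2f%% non-zero\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$regions$chrom)),
    if (length(unique(x$regions$chrom)) == 1L) "" else "s",
    100 * nnz / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.AccessibilityMatrix <- function(x) dim(x$counts)

#' Read an accessibility matrix from MTX triplet + sidecar files
#'
#' Expects the 10x-style trio: a Matrix Market file of counts plus plain-text
#' sidecars listing peak ids and cell barcodes (one per line). The matrix may
#' be stored either cells x regions or regions x cells; orientation is
#' resolved against the sidecar lengths.
#'
#' @param mtx Path to the Matrix Market counts file.
#' @param peaks Path to the peak id sidecar (one id or BED3 row per line).
#' @param barcodes Path to the cell barcode sidecar (one per line).
#' @return An [accessibility_matrix()].
#' @export
read_accessibility <- function(mtx, peaks, barcodes) {
  m <- Matrix::readMM(mtx)
  if (prod(dim(m)) == 0L) stop("empty matrix file: ", mtx)
  regions <- read_peaks(peaks)
  cells <- readLines(barcodes, warn = FALSE)
  cells <- cells[nzchar(trimws(cells))]
  if (nrow(m) == length(cells) && ncol(m) == nrow(regions)) {
    # cells x regions already
  } else if (nrow(m) == nrow(regions) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "dimension mismatch: matrix %d x %d vs %d peaks / %d barcodes",
      nrow(m), ncol(m), nrow(regions), length(cells)))
  }
  message(sprintf("read %d cells x %d regions from %s",
                  nrow(m), ncol(m), mtx))
  accessibility_matrix(m, regions = regions, cell_ids = cells)
}

#' Write an accessibility matrix as MTX triplet + sidecar files
#'
#' @param m An `AccessibilityMatrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_accessibility <- function(m, dir, prefix = "matrix") {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_peaks.txt", "_barcodes.txt")))
  Matrix::writeMM(m$counts, paths[1])
  writeLines(m$regions$id, paths[2])
  writeLines(m$cell_ids, paths[3])
  invisible(paths)
}
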