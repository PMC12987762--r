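#' LSI embedding of cells
#'
#' Latent semantic indexing, the standard scATAC-seq reduction: TF-IDF
#' weighting of the count matrix followed by truncated SVD, projecting cells
#' into a low-dimensional space of region-topics. The variant used is
#' tf = count / cell total, idf = log(1 + n_cells / (1 + n_cells with peak)),
#' smoothed so never-detected regions do not divide by zero. Embedding rows
#' are L2-normalized so that Euclidean neighbourhoods reflect angular
#' similarity of chromatin profiles.
#'
#' All components, including the first (often depth-correlated on real
#' data), are retained by default; set `drop_first = TRUE` to discard it.
#'
#' @param m An `AccessibilityMatrix`.
#' @param n_components Rank of the truncated SVD; must be smaller than
#'   `min(n_cells, n_regions)`.
#' @param seed Seed for the randomized SVD initialization (result is
#'   deterministic for a fixed seed).
#' @param drop_first Drop the first component after the SVD.
#' @return List with `coords` (cells x components, L2-normalized rows),
#'   `n_components` and `component_variances` (singular values).
#' @export
lsi_embedding <- function(m, n_components = 50L, seed = 1L, drop_first = FALSE) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  counts <- m$counts
  n_cells <- nrow(counts)
  detected <- Matrix::colSums(counts > 0)
  if (any(detected == 0)) {
    warning(sprintf("excluding %d all-zero region column(s) from the LSI",
                    sum(detected == 0)))
    counts <- counts[, detected > 0, drop = FALSE]
    detected <- detected[detected > 0]
  }
  if (length(counts@x) == 0L) stop("count matrix is all zero")
  k <- as.integer(n_components) + as.integer(drop_first)
  if (k >= min(dim(counts))) {
    stop(sprintf("n_components = %d too large for a %d x %d matrix",
                 n_components, nrow(counts), ncol(counts)))
  }
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  tf <- Matrix::Diagonal(x = 1 / totals) %*% counts
  idf <- log(1 + n_cells / (1 + detected))
  x <- tf %*% Matrix::Diagonal(x = idf)
  set.seed(seed)
  if (k + 5L >= min(dim(x))) {
    sv <- svd(as.matrix(x), nu = k, nv = 0)
    d <- sv$d[seq_len(k)]
    u <- sv$u
  } else {
    sv <- irlba::irlba(x, nv = k)
    d <- sv$d
    u <- sv$u
  }
  coords <- u %*% diag(d, nrow = k)
  if (drop_first) {
    coords <- coords[, -1L, drop = FALSE]
    d <- d[-1L]
  }
  norms <- sqrt(rowSums(coords^2))
  norms[norms == 0] <- 1
  coords <- coords / norms
  rownames(coords) <- m$cell_ids
  if (any(!is.finite(coords))) stop("non-finite values in LSI embedding")
  list(coords = coords, n_components = ncol(coords), component_variances = d)
}

#' Group cells into metacell seeds by k-nearest neighbours
#'
#' Visits candidate seed cells in seeded-random order; each candidate's group
#' is itself plus its k nearest neighbours (Euclidean distance on embedding
#' rows). A group is accepted unless it shares more than `max_shared_fraction`
#' of its members with an already-accepted group, and acceptance stops at
#' `max_metacells` (default cap 5000, the conventional upper bound on the
#' number of metacells).
#'
#' @param e Embedding from [lsi_embedding()].
#' @param k Neighbours per group (group size is `k + 1`).
#' @param max_metacells Maximum number of groups.
#' @param max_shared_fraction Maximum tolerated overlap, as a fraction of
#'   group size, with any accepted group.
#' @param seed Seed driving the candidate visiting order.
#' @return List with `groups` (list of integer cell-index vectors), `k` and
#'   `max_metacells`.
#' @export
knn_groups <- function(e, k = 50L, max_metacells = 5000L,
                       max_shared_fraction = 0.9, seed = 1L) {
  coords <- e$coords
  n <- nrow(coords)
  stopifnot(k >= 1, max_metacells >= 1,
            max_shared_fraction > 0, max_shared_fraction <= 1)
  if (k >= n) stop(sprintf("k = %d but only %d cells", k, n))
  set.seed(seed)
  order_visit <- sample.int(n)
  groups <- list()
  membership <- vector("list", n)  # cell -> accepted group ids, for overlap test
  group_size <- k + 1L
  for (i in order_visit) {
    if (length(groups) >= max_metacells) break
    d2 <- colSums((t(coords) - coords[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    cand <- c(i, nb)
    hit <- unlist(membership[cand], use.names = FALSE)
    if (length(hit) > 0) {
      max_overlap <- max(tabulate(hit, nbins = length(groups)))
      if (max_overlap > max_shared_fraction * group_size) next
    }
    gid <- length(groups) + 1L
    groups[[gid]] <- sort(cand)
    for (cell in cand) membership[[cell]] <- c(membership[[cell]], gid)
  }
  list(groups = groups, k = k, max_metacells = max_metacells)
}

#' Aggregate counts into metacells
#'
#' Sums the count rows of each group's member cells into one metacell row.
#' With disjoint groups covering all cells this conserves column totals
#' exactly.
#'
#' @param m An `AccessibilityMatrix`.
#' @param a Assignment from [knn_groups()].
#' @return An `AccessibilityMatrix` with one row per group, same region set,
#'   cell ids `metacell_1 ...` in group order.
#' @export
aggregate_counts <- function(m, a) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  groups <- a$groups
  if (length(groups) == 0L) stop("no groups to aggregate")
  if (any(lengths(groups) == 0L)) stop("empty metacell group")
  idx <- unlist(groups, use.names = FALSE)
  if (any(idx < 1L) || any(idx > nrow(m$counts))) {
    stop("group indices out of range")
  }
  ind <- Matrix::sparseMatrix(
    i = rep.int(seq_along(groups), lengths(groups)),
    j = idx, x = 1,
    dims = c(length(groups), nrow(m$counts)))
  agg <- ind %*% m$counts
  accessibility_matrix(agg, regions = m$regions,
                       cell_ids = sprintf("metacell_%d", seq_along(groups)))
}

#' Export a metacell assignment as a long table
#'
#' @param a Assignment from [knn_groups()].
#' @param cell_ids Cell identifiers indexed by the assignment.
#' @return A `data.frame` with columns `cell_id`, `metacell_id`; cells in
#'   several groups appear once per group.
#' @export
metacell_table <- function(a, cell_ids) {
  data.frame(
    cell_id = cell_ids[unlist(a$groups, use.names = FALSE)],
    metacell_id = sprintf("metacell_%d",
                          rep.int(seq_along(a$groups), lengths(a$groups))),
    stringsAsFactors = FALSE
  )
}
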