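#' Build the thresholded co-accessibility graph
#'
#' Undirected graph over regions with an edge where `|score| >= cutoff`
#' (negative co-accessibility still binds modules), edge weight `|score|`.
#'
#' @param net A `CoaccessNetwork`.
#' @param cutoff Score magnitude threshold in `[0, 1]`.
#' @return An `igraph` graph whose vertices are region ids with at least one
#'   edge.
#' @keywords internal
coaccess_graph <- function(net, cutoff) {
  lt <- link_table(net, min_abs_score = max(cutoff, 1e-10))
  if (nrow(lt) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lt$Peak1, to = lt$Peak2, weight = abs(lt$coaccess)),
    directed = FALSE)
  g
}

louvain_communities <- function(g, seed, resolution = 1.0) {
  set.seed(seed)
  igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                          resolution = resolution)
}

#' Choose the CCAN score cutoff
#'
#' Scans cutoffs over a grid from 0 to 1 and, at each, counts Louvain
#' communities with at least `min_ccan_size` members in the thresholded
#' graph; returns the cutoff maximizing that count. Ties are broken by the
#' partition's modularity and then by the smallest cutoff: community count
#' alone is often flat in the cutoff (Louvain resolves strong modules even
#' before weak noise edges are removed), whereas modularity peaks once the
#' noise edges drop out, which is the boundary this scan is after.
#'
#' @param net A `CoaccessNetwork`.
#' @param grid_step Grid increment (default 0.01).
#' @param min_ccan_size Minimum community size (default 3).
#' @param seed Louvain seed.
#' @param resolution Louvain resolution parameter.
#' @return The selected cutoff.
#' @export
select_cutoff <- function(net, grid_step = 0.01, min_ccan_size = 3L,
                          seed = 1L, resolution = 1.0) {
  grid <- seq(0, 1, by = grid_step)
  counts <- integer(length(grid))
  mods <- rep(-Inf, length(grid))
  for (gi in seq_along(grid)) {
    g <- coaccess_graph(net, grid[gi])
    if (igraph::vcount(g) == 0L) { counts[gi] <- 0L; next }
    comm <- louvain_communities(g, seed, resolution)
    counts[gi] <- sum(igraph::sizes(comm) >= min_ccan_size)
    mods[gi] <- igraph::modularity(comm)
  }
  if (all(counts == 0L)) {
    warning("no cutoff yields a community of the minimum size; returning grid maximum")
    return(grid[length(grid)])
  }
  best <- which(counts == max(counts))
  best <- best[mods[best] >= max(mods[best]) - 1e-12]
  grid[best[1]]
}

#' Extract cis-co-accessibility networks (CCANs)
#'
#' CCANs are modules of regions with high mutual absolute co-accessibility:
#' Louvain communities of the graph keeping edges with `|score| >= cutoff`,
#' weighted by `|score|`. Communities smaller than `min_ccan_size` are
#' dropped; ids are assigned in decreasing size order (ties broken by the
#' smallest member region position, for determinism).
#'
#' @param net A `CoaccessNetwork`.
#' @param cutoff Score threshold in `[0, 1]`; `"auto"` runs
#'   [select_cutoff()].
#' @param min_ccan_size Minimum module size (default 3).
#' @param seed Louvain seed.
#' @param resolution Louvain resolution parameter.
#' @return List of CCANs: each a list with `ccan_id`, `member_regions`
#'   (region ids) and `cutoff_used`.
#' @export
find_ccans <- function(net, cutoff = "auto", min_ccan_size = 3L, seed = 1L,
                       resolution = 1.0) {
  if (identical(cutoff, "auto")) {
    cutoff <- select_cutoff(net, min_ccan_size = min_ccan_size, seed = seed,
                            resolution = resolution)
  }
  stopifnot(cutoff >= 0, cutoff <= 1)
  g <- coaccess_graph(net, cutoff)
  if (igraph::vcount(g) == 0L) return(list())
  comm <- louvain_communities(g, seed, resolution)
  mem <- igraph::membership(comm)
  groups <- split(names(mem), as.integer(mem))
  groups <- groups[lengths(groups) >= min_ccan_size]
  if (length(groups) == 0L) return(list())
  first_pos <- vapply(groups, function(g_) min(match(g_, net$regions$id)),
                      numeric(1))
  ord <- order(-lengths(groups), first_pos)
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    list(ccan_id = i,
         member_regions = sort(groups[[i]]),
         cutoff_used = cutoff)
  })
}

#' CCAN membership table
#'
#' @param ccans Result of [find_ccans()].
#' @return `data.frame` with columns `region_id`, `ccan_id`.
#' @export
ccan_table <- function(ccans) {
  if (length(ccans) == 0L) {
    return(data.frame(region_id = character(), ccan_id = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    region_id = unlist(lapply(ccans, `[[`, "member_regions"), use.names = FALSE),
    ccan_id = rep.int(vapply(ccans, `[[`, integer(1), "ccan_id"),
                      vapply(ccans, function(x) length(x$member_regions),
                             integer(1))),
    stringsAsFactors = FALSE)
}

#' Write CCANs as BED
#'
#' One line per member region, with the CCAN id in the name field.
#'
#' @param ccans Result of [find_ccans()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ccans_bed <- function(ccans, path) {
  tab <- ccan_table(ccans)
  reg <- parse_region_ids(tab$region_id)
  lines <- sprintf("%s\t%d\t%d\tCCAN_%d", reg$chrom, reg$start, reg$end,
                   tab$ccan_id)
  writeLines(lines, path)
  invisible(path)
}
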