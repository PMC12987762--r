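#' Read a reference interaction table
#'
#' Chromatin-contact reference interactions (promoter capture Hi-C style):
#' a TSV with both fragments' coordinates and an optional score. Recognized
#' column layouts: `baitChr/baitStart/baitEnd/oeChr/oeStart/oeEnd[/score]`
#' (the PCHiC peak-matrix layout) or
#' `chrom1/start1/end1/chrom2/start2/end2[/score]`; otherwise the first six
#' columns are taken positionally. Coordinates are expected in the same
#' genome build as the peaks (any liftover happens upstream).
#'
#' @param path TSV path with a header line.
#' @return `data.frame` with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `source_score` (NA when absent). Side
#'   "a" is the promoter/bait fragment.
#' @export
read_reference_interactions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  nm <- tolower(names(tab))
  pick <- function(cands) {
    for (cn in cands) {
      hit <- which(nm == cn)
      if (length(hit) == 1L) return(hit)
    }
    NA_integer_
  }
  if (ncol(tab) < 6L) stop("reference table needs at least 6 columns: ", path)
  layout_a <- c(pick("baitchr"), pick("baitstart"), pick("baitend"),
                pick("oechr"), pick("oestart"), pick("oeend"))
  layout_b <- c(pick("chrom1"), pick("start1"), pick("end1"),
                pick("chrom2"), pick("start2"), pick("end2"))
  cols <- if (!anyNA(layout_a)) layout_a else if (!anyNA(layout_b)) layout_b
          else seq_len(6L)
  score_col <- pick("score")
  out <- data.frame(
    chrom_a = as.character(tab[[cols[1]]]),
    start_a = as.integer(tab[[cols[2]]]),
    end_a = as.integer(tab[[cols[3]]]),
    chrom_b = as.character(tab[[cols[4]]]),
    start_b = as.integer(tab[[cols[5]]]),
    end_b = as.integer(tab[[cols[6]]]),
    source_score = if (is.na(score_col)) NA_real_
                   else as.numeric(tab[[score_col]]),
    stringsAsFactors = FALSE)
  if (any(out$end_a <= out$start_a) || any(out$end_b <= out$start_b)) {
    stop("reference intervals must satisfy end > start")
  }
  out
}

#' Candidate promoter-peak pairs
#'
#' For each distinct promoter fragment of the reference, pairs it with every
#' peak whose midpoint lies within `window` bp of the promoter midpoint on
#' the same chromosome. This is the candidate universe over which predicted
#' links are evaluated.
#'
#' @param reference Table from [read_reference_interactions()] (its "a" side
#'   provides the promoter fragments), or a region-table of promoters.
#' @param regions Peak region table.
#' @param window Maximum midpoint distance in bp (default 500 kb).
#' @return `data.frame` with columns `prom_chrom`, `prom_start`, `prom_end`,
#'   `peak_id`; deduplicated.
#' @export
build_candidates <- function(reference, regions, window = 5e5) {
  stopifnot(window > 0)
  if (all(c("chrom_a", "start_a", "end_a") %in% names(reference))) {
    prom <- unique(data.frame(chrom = reference$chrom_a,
                              start = reference$start_a,
                              end = reference$end_a,
                              stringsAsFactors = FALSE))
  } else {
    prom <- unique(reference[, c("chrom", "start", "end")])
  }
  if (nrow(prom) == 0L || nrow(regions) == 0L) {
    return(data.frame(prom_chrom = character(), prom_start = integer(),
                      prom_end = integer(), peak_id = character(),
                      stringsAsFactors = FALSE))
  }
  pm <- (prom$start + prom$end) / 2
  rm_ <- region_midpoints(regions)
  out <- vector("list", nrow(prom))
  for (i in seq_len(nrow(prom))) {
    hit <- which(regions$chrom == prom$chrom[i] & abs(rm_ - pm[i]) <= window)
    if (length(hit) == 0L) next
    out[[i]] <- data.frame(prom_chrom = prom$chrom[i],
                           prom_start = prom$start[i],
                           prom_end = prom$end[i],
                           peak_id = regions$id[hit],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(prom_chrom = character(), prom_start = integer(),
                      prom_end = integer(), peak_id = character(),
                      stringsAsFactors = FALSE))
  }
  unique(res)
}

# GRanges helpers for the 1-bp overlap rule (0-based half-open input,
# converted to the 1-based closed convention of IRanges)
as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

#' Match candidate pairs against reference interactions
#'
#' A candidate pair matches a reference interaction when each of its two
#' regions overlaps one of the interaction's two regions by at least one
#' base pair, in either order (peaks are unstranded, so the assignment of
#' candidate ends to reference ends is free). Overlap requires the same
#' chromosome; no minimum fractional overlap or window extension.
#'
#' @param candidates Two paired region tables: a list with elements `a` and
#'   `b`, each a `data.frame` with `chrom`, `start`, `end` and one row per
#'   candidate; or the output of [build_candidates()] (promoter side = a,
#'   peak side = b).
#' @param reference Table from [read_reference_interactions()].
#' @return Integer vector of 0/1 labels, one per candidate pair.
#' @export
match_links <- function(candidates, reference) {
  if (is.data.frame(candidates) && "peak_id" %in% names(candidates)) {
    peak <- parse_region_ids(unique(candidates$peak_id))
    pk <- peak[match(candidates$peak_id, peak$id), ]
    candidates <- list(
      a = data.frame(chrom = candidates$prom_chrom,
                     start = candidates$prom_start,
                     end = candidates$prom_end, stringsAsFactors = FALSE),
      b = data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                     stringsAsFactors = FALSE))
  }
  n <- nrow(candidates$a)
  if (n == 0L) return(integer(0))
  if (nrow(reference) == 0L) return(integer(n))
  ga <- as_granges(candidates$a$chrom, candidates$a$start, candidates$a$end)
  gb <- as_granges(candidates$b$chrom, candidates$b$start, candidates$b$end)
  ra <- as_granges(reference$chrom_a, reference$start_a, reference$end_a)
  rb <- as_granges(reference$chrom_b, reference$start_b, reference$end_b)
  ov <- function(g, r) {
    h <- suppressWarnings(GenomicRanges::findOverlaps(g, r, minoverlap = 1L))
    sp <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    out <- vector("list", length(g))
    out[as.integer(names(sp))] <- sp
    out
  }
  a_ra <- ov(ga, ra); a_rb <- ov(ga, rb)
  b_ra <- ov(gb, ra); b_rb <- ov(gb, rb)
  labels <- integer(n)
  for (i in seq_len(n)) {
    straight <- intersect(a_ra[[i]], b_rb[[i]])
    swapped <- intersect(a_rb[[i]], b_ra[[i]])
    labels[i] <- as.integer(length(straight) > 0L || length(swapped) > 0L)
  }
  labels
}

#' Score candidates with a co-accessibility network
#'
#' A (promoter fragment, peak) candidate inherits the strongest predicted
#' link compatible with it: the maximum network score between any peak
#' overlapping the promoter fragment (by at least 1 bp) and the candidate
#' peak; 0 when no such link exists.
#'
#' @param candidates Output of [build_candidates()].
#' @param net A `CoaccessNetwork`.
#' @return Numeric score vector, one per candidate.
#' @export
score_candidates <- function(candidates, net) {
  n <- nrow(candidates)
  if (n == 0L) return(numeric(0))
  reg <- net$regions
  gp <- as_granges(candidates$prom_chrom, candidates$prom_start,
                   candidates$prom_end)
  gr <- as_granges(reg$chrom, reg$start, reg$end)
  h <- suppressWarnings(GenomicRanges::findOverlaps(gp, gr, minoverlap = 1L))
  sp <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
  prom_peaks <- vector("list", n)
  prom_peaks[as.integer(names(sp))] <- sp
  peak_pos <- match(candidates$peak_id, reg$id)
  scores <- numeric(n)
  sc <- net$scores
  for (i in seq_len(n)) {
    pp <- prom_peaks[[i]]
    if (length(pp) == 0L || is.na(peak_pos[i])) next
    vals <- sc[pp, peak_pos[i]]
    vals <- vals[pp != peak_pos[i]]
    if (length(vals) > 0L) scores[i] <- max(vals)
  }
  scores
}

#' ROC curve and AUC for labeled candidates
#'
#' Standard ROC over score thresholds with trapezoidal handling of ties
#' (equivalently, the Mann-Whitney statistic with ties counted 1/2).
#'
#' @param labels 0/1 vector.
#' @param scores Numeric prediction scores (candidates without a predicted
#'   link should carry 0).
#' @return List with `roc` (`data.frame`: `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  if (all(labels == 1)) stop("degenerate labels: no negatives")
  if (all(labels == 0)) stop("degenerate labels: no positives")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities,
                      tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  list(roc = curve, auc = as.numeric(pROC::auc(r)))
}
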