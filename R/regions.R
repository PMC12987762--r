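#' Parse peak identifiers into genomic regions
#'
#' Peak names of scATAC-seq matrices usually encode their genomic interval as
#' `"chrom_start_end"` (or with `:`/`-` separators, as in `"chr1:100-500"`).
#' This parses a vector of such identifiers into a region table. Coordinates
#' are interpreted as 0-based half-open (BED convention).
#'
#' @param ids Character vector of peak identifiers.
#' @param separators Candidate separator characters tried in order on each id.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `id` (the
#'   input id, verbatim), one row per input id, in input order.
#' @examples
#' parse_region_ids(c("chr1_100_500", "chr2:1000-2000"))
#' @export
parse_region_ids <- function(ids, separators = c("_", "-", ":")) {
  if (length(ids) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(ids)) stop("region ids contain NA")
  # build a character class: "]" must come first, "-" last, "^" not first
  chars <- unique(separators)
  chars <- c(chars[chars == "]"], chars[!chars %in% c("]", "-", "^")],
             chars[chars == "^"], chars[chars == "-"])
  sep_class <- paste0("[", paste(chars, collapse = ""), "]")
  # split on the LAST two separator occurrences so chromosome names that
  # themselves contain separators (e.g. "chrUn_GL000218v1") survive
  parse_one <- function(id) {
    pos <- gregexpr(sep_class, id)[[1]]
    if (pos[1] == -1L || length(pos) < 2L) {
      stop(sprintf("malformed region id: '%s'", id))
    }
    p2 <- pos[length(pos)]
    p1 <- pos[length(pos) - 1L]
    chrom <- substr(id, 1L, p1 - 1L)
    s <- substr(id, p1 + 1L, p2 - 1L)
    e <- substr(id, p2 + 1L, nchar(id))
    start <- suppressWarnings(as.integer(s))
    end <- suppressWarnings(as.integer(e))
    if (chrom == "" || is.na(start) || is.na(end)) {
      stop(sprintf("non-numeric coordinates in region id: '%s'", id))
    }
    if (start < 0L) stop(sprintf("negative start in region id: '%s'", id))
    if (end <= start) {
      stop(sprintf("end <= start in region id: '%s'", id))
    }
    c(chrom = chrom, start = start, end = end)
  }
  parts <- lapply(ids, parse_one)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), "chrom"),
    start = as.integer(vapply(parts, `[[`, character(1), "start")),
    end = as.integer(vapply(parts, `[[`, character(1), "end")),
    id = as.character(ids),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Region midpoints
#'
#' @param regions Region table from [parse_region_ids()].
#' @return Numeric vector of interval midpoints `(start + end) / 2` in bp.
#' @export
region_midpoints <- function(regions) {
  (regions$start + regions$end) / 2
}

#' Genomic distance between two regions
#'
#' Distance is measured between interval midpoints; regions on different
#' chromosomes have no defined distance (trans pairs are never modelled)
#' and yield `NA`.
#'
#' @param a,b Single-row region data.frames (or lists with `chrom`, `start`,
#'   `end`).
#' @return Midpoint distance in bp, or `NA` for a trans pair.
#' @export
region_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_real_)
  abs((a$start + a$end) / 2 - (b$start + b$end) / 2)
}

#' Tile chromosomes into overlapping analysis windows
#'
#' Each chromosome is tiled with windows of fixed size anchored at coordinate
#' 0 and advancing by `step`, until the last region midpoint on that
#' chromosome is covered. A region belongs to a window when its midpoint lies
#' in `[start, end)`. With the default 50% overlap (`step = window_size / 2`)
#' every same-chromosome pair closer than half a window is jointly modelled
#' in at least one window. Windows containing no region are dropped.
#'
#' @param regions Region table (see [parse_region_ids()]).
#' @param window_size Window width in bp (default 500 kb, the maximum
#'   distance considered for cis-interactions).
#' @param step Advance between consecutive windows in bp; must satisfy
#'   `0 < step <= window_size`. Default `window_size / 2`.
#' @return List of windows; each a list with `chrom`, `start`, `end`, and
#'   `members` (integer row indices into `regions`).
#' @examples
#' r <- parse_region_ids(c("chr1_90000_110000", "chr1_290000_310000"))
#' length(make_windows(r, window_size = 5e5))
#' @export
make_windows <- function(regions, window_size = 5e5, step = window_size / 2) {
  stopifnot(window_size > 0, step > 0, step <= window_size)
  if (nrow(regions) == 0L) return(list())
  mid <- region_midpoints(regions)
  out <- list()
  for (chrom in unique(regions$chrom)) {
    on_chrom <- which(regions$chrom == chrom)
    max_mid <- max(mid[on_chrom])
    starts <- seq(0, max_mid, by = step)
    for (ws in starts) {
      members <- on_chrom[mid[on_chrom] >= ws & mid[on_chrom] < ws + window_size]
      if (length(members) == 0L) next
      out[[length(out) + 1L]] <- list(
        chrom = chrom, start = ws, end = ws + window_size,
        members = members
      )
    }
  }
  out
}

#' Read a peak list from a sidecar or BED3 file
#'
#' Accepts either one region id per line (the MTX sidecar convention) or a
#' 3+ column BED file, in which case ids are built as `chrom_start_end`.
#'
#' @param path File path.
#' @return Region table as from [parse_region_ids()].
#' @export
read_peaks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty peak file: ", path)
  if (grepl("\t", lines[[1]])) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L)) stop("BED file with fewer than 3 columns: ", path)
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- as.integer(vapply(fields, `[[`, character(1), 2L))
    end <- as.integer(vapply(fields, `[[`, character(1), 3L))
    ids <- paste(chrom, start, end, sep = "_")
    out <- parse_region_ids(ids)
  } else {
    out <- parse_region_ids(lines)
  }
  if (anyDuplicated(out$id)) {
    stop("duplicate region ids in ", path, ": ",
         paste(utils::head(out$id[duplicated(out$id)], 5), collapse = ", "))
  }
  out
}
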