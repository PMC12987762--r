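#' Organism presets
#'
#' Literature-based defaults for the distance penalty: power-law exponent
#' s = 0.75 and 500 kb window for human and mouse, s = 0.85 for Drosophila.
#'
#' @param name `"human"`, `"mouse"` or `"drosophila"`.
#' @return A [penalty_params()] (alpha unset).
#' @export
organism_preset <- function(name = c("human", "mouse", "drosophila")) {
  name <- match.arg(name)
  s <- switch(name, human = 0.75, mouse = 0.75, drosophila = 0.85)
  penalty_params(s = s, window_size = 5e5, distance_constraint = 2.5e5)
}

#' Write the network link table
#'
#' TSV with header `Peak1  Peak2  coaccess`, one row per unordered pair with
#' `|score| >= min_abs_score`, sorted by chromosome, Peak1 start, Peak2
#' start. Byte output is deterministic for identical networks.
#'
#' @param net A `CoaccessNetwork`.
#' @param path Output file.
#' @param min_abs_score Score magnitude threshold (default 0: all stored
#'   pairs).
#' @return Invisibly, `path`.
#' @export
write_links <- function(net, path, min_abs_score = 0) {
  lt <- link_table(net, min_abs_score = min_abs_score)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("Peak1\tPeak2\tcoaccess", con)
  if (nrow(lt) > 0) {
    writeLines(sprintf("%s\t%s\t%.10g", lt$Peak1, lt$Peak2, lt$coaccess), con)
  }
  invisible(path)
}

#' Read a link table written by [write_links()]
#'
#' @param path TSV path.
#' @return `data.frame` with `Peak1`, `Peak2`, `coaccess`.
#' @export
read_links <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write the network as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, score.
#'
#' @inheritParams write_links
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(net, path, min_abs_score = 0) {
  lt <- link_table(net, min_abs_score = min_abs_score)
  r1 <- parse_region_ids(unique(lt$Peak1))
  r2 <- parse_region_ids(unique(lt$Peak2))
  a <- r1[match(lt$Peak1, r1$id), ]
  b <- r2[match(lt$Peak2, r2$id), ]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(lt) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%.10g",
                       a$chrom, a$start, a$end, b$chrom, b$start, b$end,
                       lt$coaccess), con)
  }
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline; unspecified fields take the
#' package defaults (and `organism` presets fill s / window size /
#' long-range distance unless explicitly overridden).
#'
#' @param organism Preset name, see [organism_preset()].
#' @param alpha Penalty scale, or `"auto"` to calibrate.
#' @param cutoff CCAN cutoff, or `"auto"` to scan.
#' @param ... Overrides of any default listed in the return.
#' @return A named list (class `run_config`), serializable as YAML.
#' @export
run_config <- function(organism = "human", alpha = "auto", cutoff = "auto",
                       ...) {
  preset <- organism_preset(organism)
  cfg <- list(
    organism = organism,
    s = preset$s,
    window_size = preset$window_size,
    distance_constraint = preset$distance_constraint,
    distance_scale = preset$distance_scale,
    step = preset$window_size / 2,
    alpha = alpha,
    cutoff = cutoff,
    min_cells = 1L,
    do_binarize = FALSE,
    do_normalize = FALSE,
    do_metacells = FALSE,
    n_components = 50L,
    k = 50L,
    max_metacells = 5000L,
    max_shared_fraction = 0.9,
    n_sample_windows = 100L,
    zero_frac_min = 0.20,
    longrange_nonzero_max = 0.05,
    sparsity_basis = "precision",
    max_elements = 200L,
    ridge = 1e-4,
    tol = 1e-4,
    max_iter = 100L,
    zero_tol = 1e-10,
    basis = "regularized_covariance",
    min_ccan_size = 3L,
    resolution = 1.0,
    min_abs_score = 0,
    n_jobs = 1L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full co-accessibility pipeline
#'
#' filter regions -> optional binarize / normalize -> optional metacells ->
#' windows -> alpha calibration (if `"auto"`) -> network estimation -> CCAN
#' extraction (cutoff `"auto"` scans a grid) -> writes `links.tsv`,
#' `links.bedpe`, `ccans.tsv`, `ccans.bed`, the resolved `config.yaml` and a
#' `run.log` into `out_dir`.
#'
#' @param m An `AccessibilityMatrix`.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `network`, `ccans`, `alpha`, `cutoff` and
#'   the `paths` written.
#' @export
run_pipeline <- function(m, config = run_config(), out_dir) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- config
  note("input: %d cells x %d regions", nrow(m$counts), ncol(m$counts))

  m <- stage("filter", filter_regions(m, cfg$min_cells))
  note("after filtering (min_cells = %d): %d regions", cfg$min_cells,
       ncol(m$counts))
  if (cfg$do_binarize) m <- stage("binarize", binarize(m))
  if (cfg$do_normalize) m <- stage("normalize", normalize_total(m))
  if (cfg$do_metacells) {
    m <- stage("metacells", {
      emb <- lsi_embedding(m, n_components = cfg$n_components, seed = cfg$seed)
      asg <- knn_groups(emb, k = cfg$k, max_metacells = cfg$max_metacells,
                        max_shared_fraction = cfg$max_shared_fraction,
                        seed = cfg$seed)
      note("metacells: %d groups of up to %d cells", length(asg$groups),
           cfg$k + 1L)
      aggregate_counts(m, asg)
    })
  }

  p <- penalty_params(s = cfg$s, window_size = cfg$window_size,
                      distance_scale = cfg$distance_scale,
                      distance_constraint = cfg$distance_constraint)
  windows <- stage("windows",
                   make_windows(m$regions, cfg$window_size, cfg$step))
  note("windows: %d (size %g bp, step %g bp)", length(windows),
       cfg$window_size, cfg$step)

  if (identical(cfg$alpha, "auto")) {
    cal <- stage("calibrate_alpha", calibrate_alpha(
      m, windows, p, n_sample_windows = cfg$n_sample_windows,
      zero_frac_min = cfg$zero_frac_min,
      longrange_nonzero_max = cfg$longrange_nonzero_max,
      sparsity_basis = cfg$sparsity_basis,
      seed = cfg$seed, max_elements = cfg$max_elements,
      ridge = cfg$ridge, tol = cfg$tol, max_iter = cfg$max_iter,
      zero_tol = cfg$zero_tol))
    p$alpha <- cal$alpha
    note("calibrated alpha = %.6g over %d window(s)", cal$alpha,
         length(cal$window_alphas))
  } else {
    p$alpha <- as.numeric(cfg$alpha)
    note("alpha = %.6g (given)", p$alpha)
  }

  net <- stage("estimate_network", estimate_network(
    m, p, windows = windows, max_elements = cfg$max_elements,
    n_jobs = cfg$n_jobs, basis = cfg$basis, ridge = cfg$ridge,
    tol = cfg$tol, max_iter = cfg$max_iter, zero_tol = cfg$zero_tol))
  note("network: %d non-zero pairs, %d window(s) fitted, %d skipped, %d sign conflict(s)",
       length(net$scores@x), net$n_windows_fit, net$n_windows_skipped,
       net$n_sign_conflicts)

  cutoff <- cfg$cutoff
  if (identical(cutoff, "auto")) {
    cutoff <- stage("select_cutoff", select_cutoff(
      net, min_ccan_size = cfg$min_ccan_size, seed = cfg$seed,
      resolution = cfg$resolution))
    note("selected CCAN cutoff = %.2f", cutoff)
  }
  ccans <- stage("find_ccans", find_ccans(
    net, cutoff = cutoff, min_ccan_size = cfg$min_ccan_size,
    seed = cfg$seed, resolution = cfg$resolution))
  note("CCANs: %d module(s)", length(ccans))

  paths <- list(links = file.path(out_dir, "links.tsv"),
                bedpe = file.path(out_dir, "links.bedpe"),
                ccans = file.path(out_dir, "ccans.tsv"),
                ccans_bed = file.path(out_dir, "ccans.bed"),
                config = file.path(out_dir, "config.yaml"),
                log = log_path)
  write_links(net, paths$links, min_abs_score = cfg$min_abs_score)
  write_bedpe(net, paths$bedpe, min_abs_score = cfg$min_abs_score)
  ct <- ccan_table(ccans)
  utils::write.table(ct, paths$ccans, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_ccans_bed(ccans, paths$ccans_bed)
  resolved <- unclass(cfg)
  resolved$alpha <- p$alpha
  resolved$cutoff <- cutoff
  yaml::write_yaml(resolved, paths$config)
  writeLines(log_lines, log_path)
  invisible(list(network = net, ccans = ccans, alpha = p$alpha,
                 cutoff = cutoff, paths = paths, config = resolved))
}

#' Rebuild a network object from a link table
#'
#' Inverse of [link_table()] / [write_links()]: useful to evaluate or
#' re-threshold a persisted network without refitting.
#'
#' @param links `data.frame` with `Peak1`, `Peak2`, `coaccess`.
#' @param regions Region table; defaults to the regions appearing in the
#'   links.
#' @return A `CoaccessNetwork` (support counts unknown, set to 1 per pair).
#' @export
network_from_links <- function(links, regions = NULL) {
  if (is.null(regions)) {
    regions <- parse_region_ids(unique(c(links$Peak1, links$Peak2)))
  }
  i <- match(links$Peak1, regions$id)
  j <- match(links$Peak2, regions$id)
  if (anyNA(i) || anyNA(j)) stop("links reference peaks absent from regions")
  n <- nrow(regions)
  lo <- pmin(i, j); hi <- pmax(i, j)
  scores <- Matrix::sparseMatrix(i = lo, j = hi, x = links$coaccess,
                                 dims = c(n, n), symmetric = TRUE)
  support <- Matrix::sparseMatrix(i = lo, j = hi, x = 1,
                                  dims = c(n, n), symmetric = TRUE)
  dimnames(scores) <- list(regions$id, regions$id)
  structure(list(regions = regions, scores = scores, support = support,
                 n_sign_conflicts = NA_integer_, n_windows_fit = NA_integer_,
                 n_windows_skipped = NA_integer_, converged_all = NA,
                 params = penalty_params(alpha = NA_real_),
                 basis = "regularized_covariance"),
            class = "CoaccessNetwork")
}
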