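# hand-built network: region ids on one chromosome, score matrix given
build_net <- function(score_mat, spacing = 1e4) {
  n <- nrow(score_mat)
  start <- spacing * seq_len(n)
  regions <- data.frame(chrom = "chr1", start = start, end = start + 500,
                        id = sprintf("chr1_%d_%d", start, start + 500),
                        stringsAsFactors = FALSE)
  sc <- Matrix::forceSymmetric(Matrix::Matrix(score_mat, sparse = TRUE))
  dimnames(sc) <- list(regions$id, regions$id)
  structure(list(regions = regions, scores = sc,
                 support = sc != 0, n_sign_conflicts = 0L,
                 n_windows_fit = 1L, n_windows_skipped = 0L,
                 converged_all = TRUE,
                 params = penalty_params(alpha = 1), basis = "regularized_covariance"),
            class = "CoaccessNetwork")
}

two_block_scores <- function(intra = 0.8, inter = 0.1) {
  sc <- matrix(0, 8, 8)
  sc[1:4, 1:4] <- intra
  sc[5:8, 5:8] <- intra
  sc[4, 5] <- sc[5, 4] <- inter   # weak bridge
  diag(sc) <- 0
  sc
}

test_that("two disconnected cliques give exactly their memberships", {
  sc <- two_block_scores(inter = 0)
  net <- build_net(sc)
  cc <- find_ccans(net, cutoff = 0.5, seed = 1)
  expect_length(cc, 2)
  expect_equal(cc[[1]]$member_regions, sort(net$regions$id[1:4]))
  expect_equal(cc[[2]]$member_regions, sort(net$regions$id[5:8]))
  expect_equal(vapply(cc, `[[`, integer(1), "ccan_id"), 1:2)
  # every region in at most one module
  expect_false(anyDuplicated(ccan_table(cc)$region_id) > 0)
})

test_that("cutoffs above all scores yield no modules", {
  net <- build_net(two_block_scores())
  expect_length(find_ccans(net, cutoff = 0.9, seed = 1), 0)
})

test_that("the cutoff scan lands just above the weak inter-block links", {
  net <- build_net(two_block_scores(intra = 0.8, inter = 0.1))
  cut <- select_cutoff(net, seed = 1)
  expect_equal(cut, 0.11, tolerance = 1e-9)
  cc <- find_ccans(net, cutoff = cut, seed = 1)
  expect_length(cc, 2)
})

test_that("raising the cutoff only removes edges", {
  set.seed(44)
  sc <- matrix(0, 12, 12)
  sc[upper.tri(sc)] <- runif(66) * (runif(66) < 0.4)
  sc <- sc + t(sc)
  net <- build_net(sc)
  sizes <- vapply(seq(0, 1, by = 0.05), function(co)
    igraph::ecount(coaccess:::coaccess_graph(net, co)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("seeded Louvain partitions are reproducible", {
  sim <- simulate_accessibility(synthetic_spec(200, 30, 3, chrom_length = 7.5e5,
                                               within_block_corr = 0.7, seed = 5))
  p <- organism_preset("human"); p$alpha <- 0.1
  net <- suppressWarnings(estimate_network(sim$matrix, p))
  c1 <- find_ccans(net, cutoff = 0.1, seed = 99)
  c2 <- find_ccans(net, cutoff = 0.1, seed = 99)
  expect_identical(c1, c2)
})

test_that("planted blocks are recovered as CCANs", {
  sim <- simulate_accessibility(synthetic_spec(400, 40, 4, chrom_length = 1e6,
                                               within_block_corr = 0.8, seed = 2))
  w <- make_windows(sim$matrix$regions, 5e5, 2.5e5)
  p <- organism_preset("human")
  cal <- calibrate_alpha(sim$matrix, w, p, seed = 1)
  p$alpha <- cal$alpha
  net <- suppressWarnings(estimate_network(sim$matrix, p, windows = w))
  # at a cutoff separating planted signal (within-block scores ~0.6-0.7)
  # from reconciliation noise, Louvain returns the planted modules
  cc <- find_ccans(net, cutoff = 0.2, seed = 1)
  tab <- ccan_table(cc)
  pred <- integer(40)
  names(pred) <- sim$matrix$regions$id
  pred[tab$region_id] <- tab$ccan_id
  expect_gte(mclust::adjustedRandIndex(pred, sim$blocks), 0.8)
})

test_that("CCAN tables and BED export carry the module labels", {
  net <- build_net(two_block_scores(inter = 0))
  cc <- find_ccans(net, cutoff = 0.5, seed = 1)
  tab <- ccan_table(cc)
  expect_named(tab, c("region_id", "ccan_id"))
  expect_equal(nrow(tab), 8)
  f <- withr::local_tempfile(fileext = ".bed")
  write_ccans_bed(cc, f)
  lines <- readLines(f)
  expect_length(lines, 8)
  expect_true(all(grepl("\tCCAN_[12]$", lines)))
})
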