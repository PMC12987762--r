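ref_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom_a = r[[1]], start_a = as.integer(r[[2]]),
               end_a = as.integer(r[[3]]), chrom_b = r[[4]],
               start_b = as.integer(r[[5]]), end_b = as.integer(r[[6]]),
               source_score = NA_real_, stringsAsFactors = FALSE)))
}

test_that("candidate pairs respect the distance window and chromosome", {
  regions <- parse_region_ids(c("chr1_9900_10100", "chr1_899900_900100"))
  ref <- ref_table(list("chr1", 1000, 2000, "chr1", 5e6, 5.1e6))
  cand <- build_candidates(ref, regions, window = 5e5)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$peak_id, "chr1_9900_10100")

  ref2 <- ref_table(list("chr2", 1000, 2000, "chr2", 5e6, 5.1e6))
  expect_equal(nrow(build_candidates(ref2, regions, window = 5e5)), 0)

  # two promoters sharing a nearby peak yield two distinct candidates
  ref3 <- ref_table(list("chr1", 1000, 2000, "chr1", 5e6, 5.1e6),
                    list("chr1", 20000, 21000, "chr1", 6e6, 6.1e6))
  expect_equal(nrow(build_candidates(ref3, regions, window = 5e5)), 2)
})

test_that("link matching needs both ends to overlap, in either order", {
  cand <- list(
    a = data.frame(chrom = "chr1", start = 100, end = 200),
    b = data.frame(chrom = "chr1", start = 5000, end = 5100))
  ref <- ref_table(list("chr1", 150, 300, "chr1", 5050, 5200))
  expect_equal(match_links(cand, ref), 1L)
  # same interaction listed with its ends swapped still matches
  ref_sw <- ref_table(list("chr1", 5050, 5200, "chr1", 150, 300))
  expect_equal(match_links(cand, ref_sw), 1L)
  # one shared end is not enough
  ref_half <- ref_table(list("chr1", 150, 300, "chr1", 9000, 9100))
  expect_equal(match_links(cand, ref_half), 0L)
  # adjacency without a shared base does not count (half-open intervals)
  ref_adj <- ref_table(list("chr1", 200, 300, "chr1", 5050, 5200))
  expect_equal(match_links(cand, ref_adj), 0L)
})

test_that("matching agrees with a brute-force double loop on random instances", {
  set.seed(15)
  for (rep in 1:25) {
    nc <- sample(3:12, 1)
    nr <- sample(1:8, 1)
    ca <- random_intervals(nc)
    cb <- random_intervals(nc)
    ra <- random_intervals(nr)
    rb <- random_intervals(nr)
    ref <- data.frame(chrom_a = ra$chrom, start_a = ra$start, end_a = ra$end,
                      chrom_b = rb$chrom, start_b = rb$start, end_b = rb$end,
                      source_score = NA_real_, stringsAsFactors = FALSE)
    got <- match_links(list(a = ca, b = cb), ref)
    expect_identical(got, brute_force_match(ca, cb, ref))
  }
})

test_that("ROC analysis covers perfect, random, and degenerate scores", {
  labels <- rep(c(1, 0), each = 50)
  perfect <- roc_auc(labels, as.numeric(labels))
  expect_equal(perfect$auc, 1.0)

  set.seed(23)
  n <- 4000
  lab <- rbinom(n, 1, 0.4)
  rnd <- roc_auc(lab, runif(n))
  expect_lt(abs(rnd$auc - 0.5), 3 / sqrt(n))

  ties <- roc_auc(labels, rep(0.7, 100))
  expect_equal(ties$auc, 0.5)

  expect_error(roc_auc(rep(1, 5), rnorm(5)), "no negatives")
  expect_error(roc_auc(rep(0, 5), rnorm(5)), "no positives")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  lab <- rbinom(200, 1, 0.5)
  sc <- rnorm(200) + lab
  a1 <- roc_auc(lab, sc)$auc
  expect_equal(roc_auc(lab, exp(sc))$auc, a1)
  expect_equal(roc_auc(lab, 3 * sc - 10)$auc, a1)
})

test_that("the ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(6)
  lab <- rbinom(300, 1, 0.3)
  sc <- rnorm(300) + 0.8 * lab
  r <- roc_auc(lab, sc)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("reference tables load from both PCHiC-style and generic headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("baitChr\tbaitStart\tbaitEnd\toeChr\toeStart\toeEnd\tscore",
               "chr1\t100\t200\tchr1\t700\t900\t7.5"), f)
  ref <- read_reference_interactions(f)
  expect_equal(ref$start_a, 100L)
  expect_equal(ref$end_b, 900L)
  expect_equal(ref$source_score, 7.5)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom1\tstart1\tend1\tchrom2\tstart2\tend2",
               "chr2\t10\t20\tchr2\t50\t80"), f2)
  ref2 <- read_reference_interactions(f2)
  expect_equal(ref2$chrom_a, "chr2")
  expect_true(is.na(ref2$source_score))
})

test_that("candidates inherit the strongest compatible network link", {
  sim <- simulate_accessibility(synthetic_spec(200, 20, 2, chrom_length = 5e5,
                                               within_block_corr = 0.8, seed = 9))
  p <- organism_preset("human"); p$alpha <- 0.1
  net <- suppressWarnings(estimate_network(sim$matrix, p))
  reg <- net$regions
  # a promoter sitting exactly on region 1 paired with region 2
  cand <- data.frame(prom_chrom = reg$chrom[1], prom_start = reg$start[1],
                     prom_end = reg$end[1], peak_id = reg$id[2],
                     stringsAsFactors = FALSE)
  sc <- score_candidates(cand, net)
  expect_equal(sc, as.numeric(net$scores[1, 2]))
  # a promoter overlapping nothing scores zero
  cand0 <- data.frame(prom_chrom = "chr1", prom_start = 1, prom_end = 5,
                      peak_id = reg$id[2], stringsAsFactors = FALSE)
  expect_equal(score_candidates(cand0, net), 0)
})
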