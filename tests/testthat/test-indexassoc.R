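rec_tbl <- function(pos, i1, i2, class = "SNP", chrom = "A10",
                    d1 = 20, d2 = 20) {
  tibble::tibble(chrom = chrom, pos = pos, variant_class = class,
                 index_pool1 = i1, index_pool2 = i2, delta = i2 - i1,
                 depth_pool1 = d1, depth_pool2 = d2)
}

test_that("index arithmetic follows the depth-ratio definition", {
  s <- tibble::tibble(chrom = "A10", pos = c(100, 200), variant_class = "SNP",
                      dp_pool1_m = c(4L, 6L), dp_pool1_p = c(8L, 6L),
                      dp_pool2_m = c(10L, 6L), dp_pool2_p = c(5L, 6L))
  r <- compute_indices(s)
  expect_equal(r$index_pool2[1], 10 / 15, tolerance = 1e-12)
  expect_equal(round(r$index_pool2[1], 4), 0.6667)
  expect_equal(r$delta[1], 10 / 15 - 4 / 12)
  # equal depths in both pools -> delta 0
  expect_equal(r$delta[2], 0)
  # zero depth is an error, not NA
  s$dp_pool1_m[1] <- 0L; s$dp_pool1_p[1] <- 0L
  expect_error(compute_indices(s), "zero total depth")
})

test_that("low-index filter removes only sites low in both pools", {
  r <- rec_tbl(1:4 * 100, i1 = c(0.25, 0.25, 0.30, 0.50),
               i2 = c(0.20, 0.80, 0.10, 0.50))
  out <- filter_low_index(r)
  expect_equal(out$pos, c(200, 300, 400))   # (0.25,0.20) removed; boundary kept
  expect_identical(filter_low_index(out), out)
  expect_error(filter_low_index(r, 0), "threshold")
  expect_error(filter_low_index(r, 1), "threshold")
})

test_that("sliding windows average member sites and tile the chromosome", {
  # constant delta: every non-empty window mean equals the constant
  set.seed(31)
  pos <- sort(sample(1:5e6, 300))
  r <- rec_tbl(pos, i1 = 0.2, i2 = 0.7)
  w <- sliding_windows(r, c(A10 = 5e6), window_size = 1e6, step = 1e4)
  expect_true(all(abs(w$delta[w$n_sites > 0] - 0.5) < 1e-12))
  expect_true(all(is.na(w$delta[w$n_sites == 0])))
  expect_equal(w$start, seq(1, 5e6, by = 1e4))

  # single interior site: brute-force count of covering windows
  r1 <- rec_tbl(2.5e6, 0.2, 0.7)
  w1 <- sliding_windows(r1, c(A10 = 5e6), 1e6, 1e4)
  brute <- sum(vapply(seq(1, 5e6, 1e4), function(s) {
    s <= 2.5e6 && 2.5e6 <= s + 1e6 - 1
  }, logical(1)))
  expect_equal(sum(w1$n_sites), brute)
  expect_equal(brute, ceiling(1e6 / 1e4))

  expect_error(sliding_windows(r1, numeric(0)), "non-empty")
  expect_error(sliding_windows(r1, c(A10 = 5e6), 1e4, 1e6), "step")
})

test_that("window means equal a brute-force per-window recomputation", {
  set.seed(32)
  pos <- sort(sample(1:3e6, 800))
  r <- rec_tbl(pos, i1 = runif(800), i2 = runif(800),
               d1 = rpois(800, 25) + 1, d2 = rpois(800, 25) + 1)
  w <- sliding_windows(r, c(A10 = 3e6), window_size = 5e5, step = 5e4)
  for (i in sample(nrow(w), 40)) {
    inside <- r$pos >= w$start[i] & r$pos <= w$start[i] + 5e5 - 1
    if (!any(inside)) {
      expect_true(is.na(w$delta[i]))
    } else {
      expect_equal(w$delta[i], mean(r$delta[inside]))
      expect_equal(w$index_pool1[i], mean(r$index_pool1[inside]))
      expect_equal(w$n_sites[i], sum(inside))
      expect_equal(w$depth_pool1[i], median(r$depth_pool1[inside]))
      # window mean stays within the member range
      expect_gte(w$delta[i], min(r$delta[inside]) - 1e-12)
      expect_lte(w$delta[i], max(r$delta[inside]) + 1e-12)
    }
  }
})

test_that("null threshold shrinks with depth, is centred, deterministic, and guarded", {
  set.seed(33)
  t10 <- simulate_null_threshold(depth = 10, n_sim = 20000)
  t30 <- simulate_null_threshold(depth = 30, n_sim = 20000)
  expect_gt(t10, t30)

  # symmetric null: mean delta ~ 0
  set.seed(33)
  n1 <- 20L; n2 <- 19L
  f1 <- rbinom(20000, 2 * n1, 0.5) / (2 * n1)
  f2 <- rbinom(20000, 2 * n2, 0.5) / (2 * n2)
  d <- rbinom(20000, 30, f2) / 30 - rbinom(20000, 30, f1) / 30
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(20000))

  set.seed(99); a <- simulate_null_threshold(depth = 25, n_sites = 10)
  set.seed(99); b <- simulate_null_threshold(depth = 25, n_sites = 10)
  expect_identical(a, b)

  expect_error(simulate_null_threshold(depth = 25, n_sim = 500), "n_sim")
  expect_error(simulate_null_threshold(depth = 0), "positive")

  # noise vanishes with depth and pool size
  t_big <- simulate_null_threshold(pool_sizes = c(5000L, 5000L), depth = 5000,
                                   n_sites = 50, n_sim = 2000)
  expect_lt(t_big, 0.02)
})

test_that("region calling merges supra-threshold runs and respects NA breaks", {
  w <- tibble::tibble(chrom = "A10",
                      start = seq(1, 1e6, 1e5),
                      end = seq(1, 1e6, 1e5) + 1e5 - 1,
                      n_sites = 5,
                      delta = c(0.1, 0.6, 0.7, NA, 0.8, 0.1, 0.9, 0.9, 0.1, 0.1))
  none <- call_regions(dplyr::mutate(w, delta = 0.01), threshold = 0.5)
  expect_equal(nrow(none), 0)

  regs <- call_regions(w, threshold = 0.5, source = "SNP")
  # NA at window 4 breaks the first run even though window 5 is high
  expect_equal(nrow(regs), 3)
  expect_equal(regs$start, c(100001, 400001, 600001))
  expect_equal(regs$end, c(300000, 500000, 800000))
  expect_equal(regs$peak_delta, c(0.7, 0.8, 0.9))
  expect_true(all(regs$length == regs$end - regs$start))

  # one continuous run -> one region spanning it
  one <- call_regions(dplyr::mutate(w, delta = 0.9), threshold = 0.5)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(1, 1e6))

  # median + k*SD fallback method (median 0.6, sd ~0.37)
  ms <- call_regions(w, method = "median_sd", k = 0.5)
  expect_true(nrow(ms) >= 1)
  expect_true(all(ms$peak_delta > 0.6))
  expect_error(call_regions(dplyr::mutate(w, delta = NA_real_), threshold = 1),
               "all windows")
})

test_that("region intersection is idempotent, empty on disjoint, and exact on containment", {
  mk <- function(start, end, src = "SNP") {
    tibble::tibble(chrom = "A10", start = start, end = end, source = src,
                   peak_delta = 0.5, n_windows = 1L, length = end - start)
  }
  a <- mk(c(1e6, 5e6), c(2e6, 6e6))
  expect_equal(intersect_regions(a, a)[, c("start", "end")],
               a[, c("start", "end")])
  expect_equal(nrow(intersect_regions(mk(1e6, 2e6), mk(3e6, 4e6))), 0)
  out <- intersect_regions(mk(10e6, 20e6), mk(16388840, 21907658, "InDel"))
  expect_equal(out$start, 16388840)
  expect_equal(out$end, 20e6)
  expect_equal(out$source, "overlap")
})

test_that("region length follows the end-minus-start convention", {
  expect_equal(region_length(list(start = 16388840, end = 21907658)), 5518818)
  expect_equal(region_length(list(start = 21326670, end = 21361732)), 35062)
  expect_error(region_length(list(start = 5, end = 5)), "start < end")
})

test_that("genes are counted when their transcript span intersects the region", {
  genes <- dplyr::bind_rows(
    gene_model("gA", "A10", "+", data.frame(start = 100, end = 900)),
    gene_model("gB", "A10", "+", data.frame(start = 2000, end = 2500)),
    gene_model("gC", "A2", "+", data.frame(start = 100, end = 900)))
  region <- list(chrom = "A10", start = 800, end = 2100)
  expect_setequal(genes_in_region(region, genes), c("gA", "gB"))
  expect_equal(genes_in_region(list(chrom = "A10", start = 1000, end = 1500),
                               genes), character(0))
})

test_that("gene models round-trip through GFF3", {
  genes <- dplyr::bind_rows(
    gene_model("gA", "A10", "+", data.frame(start = c(100, 400), end = c(200, 900)),
               cds = data.frame(start = c(150, 400), end = c(200, 500))),
    gene_model("gB", "A10", "-", data.frame(start = 2000, end = 2500)))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(genes, path)
  back <- read_gene_models(path)
  back <- back[match(genes$gene_id, back$gene_id), ]
  expect_equal(back$strand, genes$strand)
  expect_equal(back$tx_start, genes$tx_start)
  for (i in 1:2) {
    expect_equal(as.data.frame(back$exons[[i]]), as.data.frame(genes$exons[[i]]))
    expect_equal(as.data.frame(back$cds[[i]]), as.data.frame(genes$cds[[i]]))
  }
})
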