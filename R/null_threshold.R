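#' Monte-Carlo null threshold for the window delta index
#'
#' Simulates the delta index of a window under the no-association null and
#' returns the upper `level` quantile of its absolute value. One replicate
#' draws each pool's allele frequency from the family null (each pool
#' member is an independent selfing product, so at a founder-heterozygous
#' unlinked site the pool's M-chromosome count is Binomial(2 x pool size,
#' 1/2); a pure Binomial(., 0.5) read-only null is available via
#' `null = "binom"` which skips the pool-sampling stage), then adds
#' sequencing noise: the mean index over `n_sites` member sites at depth
#' `d` is Binomial(`n_sites * d`, f) / (`n_sites * d`), because within a
#' window the pool frequency is shared (tight linkage) while read noise is
#' independent across sites. Replicates where both simulated indices fall
#' below `low_index` are discarded, mirroring the per-site filter.
#'
#' @param pool_sizes Length-2 integer vector, c(normal, abnormal) pool
#'   sizes (default c(20, 19)).
#' @param depth Representative per-site depth; length 1 or 2 (per pool).
#' @param n_sites Representative number of member sites per window
#'   (default 1 gives the per-site null).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param n_sim Number of null replicates (>= 1000).
#' @param null `"family"` (1:2:1 founder-het pool sampling, the default) or
#'   `"binom"` (fixed f = 0.5).
#' @param low_index Low-index filter applied to the simulated indices
#'   (default 0.3; set 0 to disable).
#' @return A single number: the `level` quantile of |delta| under the null.
#' @export
#' @examples
#' set.seed(1)
#' simulate_null_threshold(depth = 27.6, n_sites = 40)
simulate_null_threshold <- function(pool_sizes = c(20L, 19L), depth,
                                    n_sites = 1L, level = 0.95,
                                    n_sim = 10000L,
                                    null = c("family", "binom"),
                                    low_index = 0.3) {
  null <- match.arg(null)
  if (n_sim < 1000) abort("`n_sim` must be >= 1000")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  if (any(depth <= 0) || any(pool_sizes < 1) || n_sites < 1) {
    abort("`depth`, `pool_sizes` and `n_sites` must be positive")
  }
  depth <- rep(depth, length.out = 2)
  f1 <- if (null == "family") {
    rbinom(n_sim, 2L * pool_sizes[1], 0.5) / (2 * pool_sizes[1])
  } else rep(0.5, n_sim)
  f2 <- if (null == "family") {
    rbinom(n_sim, 2L * pool_sizes[2], 0.5) / (2 * pool_sizes[2])
  } else rep(0.5, n_sim)
  reads1 <- round(n_sites * depth[1]); reads2 <- round(n_sites * depth[2])
  i1 <- rbinom(n_sim, reads1, f1) / reads1
  i2 <- rbinom(n_sim, reads2, f2) / reads2
  keep <- !(i1 < low_index & i2 < low_index)
  d <- abs(i2 - i1)[keep]
  unname(quantile(d, level, names = FALSE))
}

#' Per-window null thresholds
#'
#' Computes a threshold for every window using that window's median pool
#' depths and member-site count as the representative null parameters;
#' thresholds are cached over unique (depth, depth, n_sites) combinations.
#' Empty windows get `NA`.
#'
#' @param windows Window table from [sliding_windows()].
#' @inheritParams simulate_null_threshold
#' @return Numeric vector of thresholds, one per window row.
#' @export
window_thresholds <- function(windows, pool_sizes = c(20L, 19L),
                              level = 0.95, n_sim = 2000L,
                              null = c("family", "binom"), low_index = 0.3) {
  null <- match.arg(null)
  key <- paste(windows$depth_pool1, windows$depth_pool2, windows$n_sites)
  thr <- rep(NA_real_, nrow(windows))
  nonempty <- windows$n_sites > 0
  for (k in unique(key[nonempty])) {
    idx <- which(key == k & nonempty)
    i <- idx[1]
    thr[idx] <- simulate_null_threshold(
      pool_sizes = pool_sizes,
      depth = c(windows$depth_pool1[i], windows$depth_pool2[i]),
      n_sites = windows$n_sites[i], level = level, n_sim = n_sim,
      null = null, low_index = low_index)
  }
  thr
}
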