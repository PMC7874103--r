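#' Compute per-site SNP/InDel indices and their difference
#'
#' The index of a pool at a site is the fraction of its reads carrying the
#' mutant-parent (M) allele: `index = dp_m / (dp_m + dp_p)`. The delta index
#' is `index(abnormal pool) - index(normal pool)`; genome-wide it hovers
#' near the null expectation and rises toward the selected locus.
#'
#' @param sites Canonical site table that has passed the parental and depth
#'   filters. A site with zero total depth in either pool is an error (such
#'   sites must be removed by [filter_min_depth()] first).
#' @return A tibble of per-site index records: `chrom`, `pos`,
#'   `variant_class`, `index_pool1`, `index_pool2`, `delta`, plus per-pool
#'   total depths `depth_pool1`, `depth_pool2`.
#' @export
#' @examples
#' s <- tibble::tibble(chrom = "A10", pos = 100, variant_class = "SNP",
#'   dp_pool1_m = 0L, dp_pool1_p = 12L, dp_pool2_m = 10L, dp_pool2_p = 5L)
#' compute_indices(s)
compute_indices <- function(sites) {
  d1 <- sites$dp_pool1_m + sites$dp_pool1_p
  d2 <- sites$dp_pool2_m + sites$dp_pool2_p
  if (any(d1 == 0 | d2 == 0)) {
    abort("zero total depth in a pool; filter sites with filter_min_depth() first")
  }
  tibble(chrom = sites$chrom, pos = sites$pos,
         variant_class = sites$variant_class,
         index_pool1 = sites$dp_pool1_m / d1,
         index_pool2 = sites$dp_pool2_m / d2,
         delta = sites$dp_pool2_m / d2 - sites$dp_pool1_m / d1,
         depth_pool1 = d1, depth_pool2 = d2)
}

#' Drop sites whose index is low in both pools
#'
#' Sites where the M-allele fraction is below `threshold` in *both* pools
#' carry no association signal in either direction (typically spurious
#' calls or repeat-collapsed sites) and are removed; a site with either
#' index at or above the threshold is kept.
#'
#' @param records Index records from [compute_indices()].
#' @param threshold Low-index cutoff in (0, 1); default 0.3, and an index
#'   exactly at the threshold is kept.
#' @return The filtered records.
#' @export
filter_low_index <- function(records, threshold = 0.3) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  keep <- !(records$index_pool1 < threshold & records$index_pool2 < threshold)
  records[keep, , drop = FALSE]
}
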