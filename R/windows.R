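#' Average index records in sliding windows along each chromosome
#'
#' Windows of `window_size` bp tile each chromosome at `step` bp (window
#' starts 1, 1+step, ...; terminal partial windows included). A site at
#' position `p` belongs to the window starting at `s` iff
#' `s <= p <= s + window_size - 1`. Window values are arithmetic means of
#' the member sites' per-pool indices and deltas; empty windows carry `NA`,
#' never 0. Median per-pool depths and the member count are carried along
#' for the null-threshold machinery.
#'
#' @param records Index records ([compute_indices()]), any order.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp);
#'   must cover every chromosome in `records` and must be non-empty.
#' @param window_size Window size in bp (default 1e6).
#' @param step Step size in bp (default 1e4); must be `<= window_size`.
#' @return A tibble of window values: `chrom`, `start`, `end` (1-based
#'   inclusive, end clipped to the chromosome), `n_sites`, `index_pool1`,
#'   `index_pool2`, `delta`, `depth_pool1`, `depth_pool2` (medians).
#' @export
sliding_windows <- function(records, chrom_lengths,
                            window_size = 1e6, step = 1e4) {
  if (length(chrom_lengths) == 0) abort("`chrom_lengths` must be non-empty")
  if (step > window_size || step <= 0 || window_size <= 0) {
    abort("need 0 < step <= window_size")
  }
  out <- lapply(names(chrom_lengths), function(cc) {
    L <- chrom_lengths[[cc]]
    starts <- seq(1, L, by = step)
    ends_full <- starts + window_size - 1          # membership bound
    r <- records[records$chrom == cc, , drop = FALSE]
    r <- r[order(r$pos), , drop = FALSE]
    n_in <- findInterval(ends_full, r$pos) - findInterval(starts - 1, r$pos)
    csum <- function(x) cumsum(c(0, x))
    wmean <- function(x) {
      cs <- csum(x)
      (cs[findInterval(ends_full, r$pos) + 1] -
         cs[findInterval(starts - 1, r$pos) + 1]) / ifelse(n_in > 0, n_in, NA)
    }
    lo <- findInterval(starts - 1, r$pos) + 1
    hi <- findInterval(ends_full, r$pos)
    med <- function(x) {
      vapply(seq_along(starts), function(i) {
        if (n_in[i] == 0) NA_real_ else median(x[lo[i]:hi[i]])
      }, numeric(1))
    }
    tibble(chrom = cc, start = starts, end = pmin(ends_full, L),
           n_sites = n_in,
           index_pool1 = wmean(r$index_pool1),
           index_pool2 = wmean(r$index_pool2),
           delta = wmean(r$delta),
           depth_pool1 = med(r$depth_pool1),
           depth_pool2 = med(r$depth_pool2))
  })
  bind_rows(out)
}
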