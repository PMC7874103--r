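#' Call associated regions from a window profile
#'
#' Maximal runs of consecutive windows whose mean delta index exceeds the
#' threshold are merged into regions: the region start is the first
#' window's start, the end is the last window's end. `NA` windows never
#' join a run. Two threshold methods are available: `"ci"` uses a supplied
#' Monte-Carlo threshold (scalar or per-window vector, see
#' [simulate_null_threshold()] / [window_thresholds()]); `"median_sd"`
#' derives the threshold from the profile itself as
#' `median(delta) + k * sd(delta)` over non-empty windows.
#'
#' By default the positive (abnormal-minus-normal) side is tested — the
#' side on which selection for the mutant-parent allele pushes the delta;
#' `use_abs = TRUE` tests `|delta|`.
#'
#' @param windows Window table from [sliding_windows()].
#' @param threshold Numeric scalar or per-window vector (required for
#'   `method = "ci"`).
#' @param method `"ci"` (default) or `"median_sd"`.
#' @param k SD multiplier for `median_sd` (default 1).
#' @param use_abs Call on `|delta|` instead of `delta` (default `FALSE`).
#' @param source Label stored on the regions (e.g. `"SNP"`, `"InDel"`);
#'   defaults to the records' variant class if constant.
#' @return A tibble of regions: `chrom`, `start`, `end`, `source`,
#'   `peak_delta`, `length` (= `end - start`), `n_windows`.
#' @export
call_regions <- function(windows, threshold = NULL,
                         method = c("ci", "median_sd"), k = 1,
                         use_abs = FALSE, source = NA_character_) {
  method <- match.arg(method)
  if (all(is.na(windows$delta))) abort("all windows are NA; nothing to call")
  if (method == "ci") {
    if (is.null(threshold)) abort("method \"ci\" needs a `threshold`")
    thr <- rep(threshold, length.out = nrow(windows))
  } else {
    d <- windows$delta[!is.na(windows$delta)]
    thr <- rep(median(d) + k * sd(d), nrow(windows))
  }
  stat <- if (use_abs) abs(windows$delta) else windows$delta
  above <- !is.na(stat) & !is.na(thr) & stat > thr

  out <- list()
  for (cc in unique(windows$chrom)) {
    idx <- which(windows$chrom == cc)
    idx <- idx[order(windows$start[idx])]
    ab <- above[idx]
    if (!any(ab)) next
    r <- rle(ab)
    stops <- cumsum(r$lengths); starts_r <- stops - r$lengths + 1
    for (j in which(r$values)) {
      w <- idx[starts_r[j]:stops[j]]
      out[[length(out) + 1L]] <- tibble(
        chrom = cc,
        start = min(windows$start[w]),
        end = max(windows$end[w]),
        source = source,
        peak_delta = max(windows$delta[w]),
        n_windows = length(w))
    }
  }
  regions <- if (length(out)) bind_rows(out) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           source = character(), peak_delta = numeric(), n_windows = integer())
  mutate(regions, length = .data$end - .data$start)
}

#' Intersect SNP- and InDel-derived region sets
#'
#' Pairwise interval intersections between the two region lists; empty
#' intersections are dropped. The overlap region's peak delta is the larger
#' of the two parents' peaks.
#'
#' @param snp_regions,indel_regions Region tibbles from [call_regions()].
#' @return A region tibble with `source = "overlap"`.
#' @export
intersect_regions <- function(snp_regions, indel_regions) {
  out <- list()
  for (i in seq_len(nrow(snp_regions))) {
    a <- snp_regions[i, ]
    b <- indel_regions[indel_regions$chrom == a$chrom, , drop = FALSE]
    if (nrow(b) == 0) next
    s <- pmax(a$start, b$start); e <- pmin(a$end, b$end)
    keep <- s < e
    if (!any(keep)) next
    out[[length(out) + 1L]] <- tibble(
      chrom = a$chrom, start = s[keep], end = e[keep], source = "overlap",
      peak_delta = pmax(a$peak_delta, b$peak_delta[keep]),
      n_windows = NA_integer_)
  }
  regions <- if (length(out)) bind_rows(out) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           source = character(), peak_delta = numeric(), n_windows = integer())
  arrange(mutate(regions, length = .data$end - .data$start),
          .data$chrom, .data$start)
}

#' Physical length of a region or marker interval
#'
#' Length is `end - start` bp — the convention under which the printed
#' endpoints of a mapped interval reproduce its reported length (e.g.
#' 21,361,732 - 21,326,670 = 35,062 bp, reported as 35.1 kb).
#'
#' @param region A one-row region (list/tibble with `start`, `end`) or a
#'   region tibble (vectorized).
#' @return Numeric length(s) in bp.
#' @export
#' @examples
#' region_length(list(start = 16388840, end = 21907658))  # 5518818
region_length <- function(region) {
  if (any(region$start >= region$end)) abort("region must have start < end")
  region$end - region$start
}

#' Genes whose transcript span intersects a region
#'
#' @param region A one-row region with `chrom`, `start`, `end`.
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @return Character vector of gene ids.
#' @export
genes_in_region <- function(region, genes) {
  if (region$start >= region$end) abort("region must have start < end")
  hit <- genes$chrom == region$chrom &
    genes$tx_start <= region$end & genes$tx_end >= region$start
  genes$gene_id[hit]
}

#' Write regions as a BED file
#'
#' In-memory coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start - 1` and `end` are written.
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- tibble(chrom = regions$chrom,
               start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
               end = format(regions$end, scientific = FALSE, trim = TRUE),
               name = regions$source)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
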