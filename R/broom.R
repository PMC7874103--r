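#' Tidy an association scan
#'
#' @param x A `bsa_scan` from [run_association()].
#' @param what `"windows"` (default), `"regions"` or `"sites"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bsa_scan <- function(x, what = c("windows", "regions", "sites"), ...) {
  what <- match.arg(what)
  switch(what, windows = as_tibble(x$windows),
         regions = as_tibble(x$regions), sites = as_tibble(x$records))
}

#' One-row summary of an association scan
#'
#' @param x A `bsa_scan`.
#' @param ... Unused.
#' @return A one-row tibble: sites retained at each filter stage, number of
#'   regions per source, and the peak window delta.
#' @export
glance.bsa_scan <- function(x, ...) {
  ov <- x$regions[x$regions$source == "overlap", , drop = FALSE]
  tibble(n_sites_loaded = unname(x$counts["loaded"]),
         n_sites_analyzed = unname(x$counts[length(x$counts)]),
         n_regions_snp = sum(x$regions$source == "SNP", na.rm = TRUE),
         n_regions_indel = sum(x$regions$source == "InDel", na.rm = TRUE),
         n_regions_overlap = nrow(ov),
         peak_delta = if (nrow(x$windows) > 0 && any(!is.na(x$windows$delta)))
           max(x$windows$delta, na.rm = TRUE) else NA_real_,
         overlap_length = if (nrow(ov) > 0) sum(ov$length) else NA_real_)
}

#' Tidy a fine-mapped locus interval
#'
#' @param x A `locus_interval`.
#' @param ... Unused.
#' @return The interval tibble (one row per admissible run).
#' @export
tidy.locus_interval <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a fine-mapped interval
#'
#' @param x A `locus_interval`.
#' @param ... Unused.
#' @return A one-row tibble: number of admissible runs, total span,
#'   ambiguity flag and individuals used.
#' @export
glance.locus_interval <- function(x, ...) {
  tibble(n_runs = nrow(x), total_span = sum(x$span),
         ambiguous = isTRUE(attr(x, "ambiguous")),
         n_individuals = attr(x, "n_individuals"))
}
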