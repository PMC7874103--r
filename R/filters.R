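#' Keep sites homozygous-divergent between the parents
#'
#' Retains sites where the mutant parent is homozygous for one allele, the
#' normal parent homozygous for a different allele — the sites at which a
#' pooled allele frequency is informative about parental origin. Sites whose
#' orientation could not be determined at load time (`m_allele` is `NA`) are
#' removed by the same rule. Idempotent.
#'
#' @param sites Canonical site table ([load_sites()]).
#' @return The filtered site table.
#' @export
#' @examples
#' s <- tibble::tibble(chrom = "A10", pos = 1:2, ref = "A", alt = "G",
#'   variant_class = "SNP", m_allele = c("ref", NA),
#'   gt_parent_m = c("A/A", "A/G"), gt_parent_p = "G/G",
#'   dp_parent_m = 10L, dp_parent_p = 10L,
#'   dp_pool1_m = 5L, dp_pool1_p = 5L, dp_pool2_m = 5L, dp_pool2_p = 5L)
#' filter_parental_homozygous_divergent(s)
filter_parental_homozygous_divergent <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  hom_div <- function(gm, gp) {
    am <- strsplit(ifelse(is.na(gm), "?/?", gm), "/", fixed = TRUE)
    ap <- strsplit(ifelse(is.na(gp), "?/?", gp), "/", fixed = TRUE)
    f <- function(a, i) vapply(a, `[`, character(1), i)
    f(am, 1) == f(am, 2) & f(ap, 1) == f(ap, 2) &
      f(am, 1) != f(ap, 1) & f(am, 1) != "?" & f(ap, 1) != "?"
  }
  keep <- hom_div(sites$gt_parent_m, sites$gt_parent_p) & !is.na(sites$m_allele)
  sites[keep, , drop = FALSE]
}

#' Exclude sites with insufficient pooled read depth
#'
#' A site is kept only if the total depth (M-allele plus P-allele reads) in
#' *each* pool reaches `min_depth`. Idempotent.
#'
#' @param sites Canonical site table.
#' @param min_depth Minimum per-pool total depth (default 7; sites with
#'   depth `< 7` in either pool are excluded, so depth exactly 7 is kept).
#' @return The filtered site table.
#' @export
filter_min_depth <- function(sites, min_depth = 7) {
  if (min_depth < 1) abort("`min_depth` must be >= 1")
  keep <- (sites$dp_pool1_m + sites$dp_pool1_p) >= min_depth &
    (sites$dp_pool2_m + sites$dp_pool2_p) >= min_depth
  sites[keep, , drop = FALSE]
}
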