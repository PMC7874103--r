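#' Pooled sequencing depth model
#'
#' Per-site, per-pool total read depth is Poisson with mean `lambda`; each
#' read reports the wrong allele with probability `error_rate`. Defaults
#' follow the resequencing depths the analysis is tuned for: ~27.6x pools
#' and ~15.8x parents.
#'
#' @param lambda_pool Mean depth per site for each offspring pool.
#' @param lambda_parent Mean depth per site for each parental sample.
#' @param error_rate Probability a read reports the wrong allele
#'   (`0 <= error_rate < 0.5`; default 0.001).
#' @return An object of class `depth_model`.
#' @export
depth_model <- function(lambda_pool = 27.6, lambda_parent = 15.8,
                        error_rate = 0.001) {
  if (lambda_pool <= 0 || lambda_parent <= 0) abort("depth means must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) abort("`error_rate` must be in [0, 0.5)")
  structure(list(lambda_pool = lambda_pool, lambda_parent = lambda_parent,
                 error_rate = error_rate), class = "depth_model")
}

# count of mutant-parent origins among pool haplotypes at each site position
pool_m_counts <- function(family, ids, positions) {
  counts <- integer(length(positions))
  for (id in ids) {
    ind <- family$individuals[[id]]
    counts <- counts + (origin_at(ind$h1, positions) == "M") +
      (origin_at(ind$h2, positions) == "M")
  }
  counts
}

#' Simulate pooled allele depths at every mapped site
#'
#' For each site and pool, the true mutant-parent (M) allele frequency `f` is
#' the fraction of M-origin chromosomes among the `2 * pool size` pool
#' chromosomes. Total depth is Poisson(`lambda_pool`); M-allele reads are
#' binomial with success probability `f (1 - e) + (1 - f) e` where `e` is the
#' sequencing error rate. Parental samples are emitted homozygous (M parent
#' for the M allele, P parent for the other) with Poisson(`lambda_parent`)
#' depths. Each site's M allele is randomly oriented to REF or ALT so that
#' downstream allele-orientation logic is exercised.
#'
#' @param family An [simulate_f23_family()] result.
#' @param pools A [select_pools()] result.
#' @param depth A [depth_model()].
#' @return A tibble of pooled site counts — the package's canonical site
#'   table with columns `chrom`, `pos`, `ref`, `alt`, `variant_class`,
#'   `m_allele` (`"ref"`/`"alt"`), `gt_parent_m`, `gt_parent_p`,
#'   `dp_parent_m`, `dp_parent_p`, and per-pool M/P-allele depths
#'   `dp_pool1_m`, `dp_pool1_p` (normal pool), `dp_pool2_m`, `dp_pool2_p`
#'   (abnormal pool).
#' @export
simulate_pooled_depths <- function(family, pools, depth = depth_model()) {
  if (length(pools$normal) == 0 || length(pools$abnormal) == 0) {
    abort("pools must be non-empty")
  }
  sites <- family$map$sites[family$map$sites$chrom == family$chrom, , drop = FALSE]
  if (nrow(sites) == 0) abort("genome map has no sites on the simulated chromosome")
  eps <- depth$error_rate
  k <- nrow(sites)

  draw_pool <- function(ids) {
    n_chr <- 2L * length(ids)
    f <- pool_m_counts(family, ids, sites$pos) / n_chr
    p_read_m <- f * (1 - eps) + (1 - f) * eps
    total <- rpois(k, depth$lambda_pool)
    m <- rbinom(k, total, p_read_m)
    list(m = m, p = total - m)
  }
  p1 <- draw_pool(pools$normal)
  p2 <- draw_pool(pools$abnormal)

  m_is_ref <- runif(k) < 0.5
  m_base <- ifelse(m_is_ref, sites$ref, sites$alt)
  p_base <- ifelse(m_is_ref, sites$alt, sites$ref)
  tibble(chrom = sites$chrom, pos = sites$pos,
         ref = sites$ref, alt = sites$alt,
         variant_class = sites$variant_class,
         m_allele = ifelse(m_is_ref, "ref", "alt"),
         gt_parent_m = paste(m_base, m_base, sep = "/"),
         gt_parent_p = paste(p_base, p_base, sep = "/"),
         dp_parent_m = rpois(k, depth$lambda_parent),
         dp_parent_p = rpois(k, depth$lambda_parent),
         dp_pool1_m = p1$m, dp_pool1_p = p1$p,
         dp_pool2_m = p2$m, dp_pool2_p = p2$p)
}
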