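#' @section Haplotype representation:
#' A haplotype along one chromosome is a mosaic of parental origins, encoded
#' as the origin of the leftmost segment (`"M"` for the mutant parent,
#' `"P"` for the normal parent) plus the ordered breakpoint positions at
#' which the origin switches. Origin at any position is resolved by counting
#' breakpoints to its left.
#' @name haplotype
#' @keywords internal
NULL

new_haplotype <- function(first, breaks = numeric(0)) {
  list(first = first, breaks = breaks)
}

#' Parental origin of a haplotype at given positions
#'
#' @param hap A haplotype (see [simulate_gamete()]).
#' @param pos Numeric vector of 1-based bp positions.
#' @return Character vector in `{"M","P"}`, one per position.
#' @export
origin_at <- function(hap, pos) {
  k <- findInterval(pos, hap$breaks)
  other <- if (hap$first == "M") "P" else "M"
  ifelse(k %% 2 == 0, hap$first, other)
}

# collapse runs of equal origin into a minimal breakpoint encoding
compress_haplotype <- function(first, breaks, origins) {
  keep <- c(TRUE, origins[-1] != origins[-length(origins)])
  new_haplotype(origins[1], breaks[keep[-1]])
}

#' Simulate one meiotic gamete from a diploid parent
#'
#' Crossover counts per chromosome are Poisson with mean equal to the genetic
#' length in Morgans (`length_bp * recomb_rate / 100 / 1e6`); crossover
#' positions are uniform along the chromosome (Haldane model, no
#' interference). The starting chromatid is chosen with probability 1/2.
#'
#' @param parent A list with haplotypes `h1`, `h2` for one chromosome.
#' @param map A [genome_map()].
#' @param chrom Chromosome name (default: first chromosome of the map).
#' @return A recombinant haplotype.
#' @export
#' @examples
#' f1 <- list(h1 = list(first = "M", breaks = numeric(0)),
#'            h2 = list(first = "P", breaks = numeric(0)))
#' g <- simulate_gamete(f1, genome_map())
simulate_gamete <- function(parent, map, chrom = map$chromosomes$chrom[1]) {
  stopifnot(!is.null(parent$h1), !is.null(parent$h2))
  len <- chrom_length(map, chrom)
  morgans <- len * map$recomb_rate / 100 / 1e6
  n_xo <- rpois(1L, morgans)
  xo <- if (n_xo > 0) sort(runif(n_xo, 1, len)) else numeric(0)
  start <- sample(c("h1", "h2"), 1L)
  haps <- list(h1 = parent$h1, h2 = parent$h2)
  cand <- sort(unique(c(haps$h1$breaks, haps$h2$breaks, xo)))
  # evaluate origin just right of every candidate breakpoint (and at 1)
  probe <- c(1, cand + 0.5)
  use_h1 <- (findInterval(probe, xo) %% 2 == 0) == (start == "h1")
  o1 <- origin_at(haps$h1, probe)
  o2 <- origin_at(haps$h2, probe)
  origins <- ifelse(use_h1, o1, o2)
  compress_haplotype(origins[1], cand, origins)
}
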