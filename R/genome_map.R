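#' Describe the simulated genome: chromosomes, recombination and variant sites
#'
#' A genome map holds the coordinate system the forward simulator works in:
#' chromosome names and physical lengths, a uniform recombination rate, the
#' positions (and alleles) of segregating variant sites, and the subset of
#' positions that are assayable markers. The default emulates the distal
#' chromosome of a ~26.6 Mbp rapeseed A10-like chromosome at 4 cM/Mbp.
#'
#' @param chromosomes Data frame with columns `chrom` and `length`
#'   (bp). Defaults to a single 26.6 Mbp chromosome named `"A10"`.
#' @param recomb_rate Recombination rate in cM per Mbp, uniform along each
#'   chromosome. Must be `>= 0` (0 is allowed for degenerate no-crossover
#'   checks).
#' @param sites Data frame of segregating sites with columns `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`, `variant_class` (`"SNP"` or `"InDel"`).
#'   Positions must be strictly increasing within a chromosome and lie in
#'   `[1, length]`. If `NULL`, an empty site table is used.
#' @param marker_positions Data frame with columns `chrom`, `pos` flagging
#'   which site positions double as assayable markers; may be `NULL`.
#'
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes`, `recomb_rate`, `sites`, `marker_positions`.
#' @export
#' @examples
#' gm <- genome_map()
#' gm$chromosomes
genome_map <- function(chromosomes = tibble::tibble(chrom = "A10", length = 26.6e6),
                       recomb_rate = 4,
                       sites = NULL,
                       marker_positions = NULL) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (!is.numeric(recomb_rate) || length(recomb_rate) != 1L || recomb_rate < 0) {
    abort("`recomb_rate` must be a single non-negative number (cM/Mbp).")
  }
  if (any(chromosomes$length < 1)) abort("chromosome lengths must be >= 1 bp")
  if (anyDuplicated(chromosomes$chrom)) abort("duplicated chromosome names")

  if (is.null(sites)) {
    sites <- tibble(chrom = character(), pos = numeric(),
                    ref = character(), alt = character(),
                    variant_class = character())
  }
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "variant_class") %in% names(sites)))
  for (cc in unique(sites$chrom)) {
    len <- chromosomes$length[match(cc, chromosomes$chrom)]
    if (is.na(len)) abort(paste0("site chromosome not in map: ", cc))
    p <- sites$pos[sites$chrom == cc]
    if (any(p < 1 | p > len)) abort("site position outside chromosome bounds")
    if (is.unsorted(p, strictly = TRUE)) abort("site positions must be strictly increasing")
  }
  if (!is.null(marker_positions)) {
    marker_positions <- as_tibble(marker_positions)
    stopifnot(all(c("chrom", "pos") %in% names(marker_positions)))
  }
  structure(list(chromosomes = chromosomes,
                 recomb_rate = recomb_rate,
                 sites = sites,
                 marker_positions = marker_positions),
            class = "genome_map")
}

#' Lay down random segregating sites on a genome map
#'
#' Draws site positions uniformly along each chromosome (then sorts and
#' de-duplicates), assigns random homozygous-divergent alleles, and labels a
#' fraction of sites as short insertion/deletion variants. SNP sites get two
#' distinct single bases; InDel sites get an anchored allele pair in VCF
#' style (shared leading base).
#'
#' @param map A [genome_map()].
#' @param n_sites Number of sites per chromosome (integer, recycled across
#'   chromosomes).
#' @param indel_fraction Fraction of sites emitted as InDels (default 0.25,
#'   roughly the SNP:InDel proportion seen in resequencing panels).
#' @param max_indel_len Maximum inserted/deleted length in bp (default 6).
#' @return The map with its `sites` table filled in.
#' @export
populate_sites <- function(map, n_sites, indel_fraction = 0.25, max_indel_len = 6) {
  stopifnot(inherits(map, "genome_map"), n_sites >= 1)
  bases <- c("A", "C", "G", "T")
  out <- purrr::map2(map$chromosomes$chrom, map$chromosomes$length, function(cc, len) {
    pos <- sort(unique(floor(runif(n_sites, 1, len + 1))))
    k <- length(pos)
    is_indel <- runif(k) < indel_fraction
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    # anchored indels: insertion extends the alt, deletion extends the ref
    if (any(is_indel)) {
      idx <- which(is_indel)
      ins <- runif(length(idx)) < 0.5
      ext <- vapply(idx, function(i) {
        paste(sample(bases, sample.int(max_indel_len, 1L), replace = TRUE),
              collapse = "")
      }, character(1))
      alt[idx[ins]] <- paste0(ref[idx[ins]], ext[ins])
      ref[idx[!ins]] <- paste0(ref[idx[!ins]], ext[!ins])
      alt[idx[!ins]] <- substr(ref[idx[!ins]], 1, 1)
    }
    tibble(chrom = cc, pos = pos, ref = ref, alt = alt,
           variant_class = ifelse(is_indel, "InDel", "SNP"))
  })
  map$sites <- bind_rows(out)
  map
}

chrom_length <- function(map, chrom) {
  len <- map$chromosomes$length[match(chrom, map$chromosomes$chrom)]
  if (is.na(len)) abort(paste0("unknown chromosome: ", chrom))
  len
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$sites), " sites, ", x$recomb_rate, " cM/Mbp\n", sep = "")
  invisible(x)
}
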