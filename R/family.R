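#' Simulate an F2:3 family by selfing a heterozygous founder
#'
#' The founder is the single F2 plant that seeds the family: heterozygous at
#' the causal locus B (one chromosome of mutant-parent origin, one of
#' normal-parent origin) and fixed at the background locus A. Each progeny
#' receives two independent meiotic gametes from the founder; phenotypes are
#' assigned by the trait model from the allele dose at locus B.
#'
#' @param n Number of progeny (>= 1).
#' @param map A [genome_map()].
#' @param trait A [trait_model()]; `trait$locus_B$chrom` must be on the map.
#' @param founder Optional founder individual (list with `h1`, `h2`); default
#'   is the F1-chromosome founder, heterozygous M/P along the whole
#'   chromosome (hence at every emitted site linked to B).
#' @param chrom Chromosome simulated (default: the causal locus' chromosome).
#' @return An object of class `f23_family`: list with `individuals` (list of
#'   `list(h1, h2)`), tibble `info` (`id`, `phenotype`, `dose_B`), plus the
#'   `map`, `trait` and `chrom` used.
#' @export
#' @examples
#' tm <- trait_model(locus_B = list(chrom = "A10", pos = 2.14e7))
#' fam <- simulate_f23_family(40, genome_map(), tm)
#' table(fam$info$phenotype)
simulate_f23_family <- function(n, map, trait, founder = NULL,
                                chrom = trait$locus_B$chrom) {
  if (n < 1) abort("`n` must be >= 1")
  chrom_length(map, chrom)                      # validates chromosome
  if (is.null(founder)) {
    founder <- list(h1 = new_haplotype("M"), h2 = new_haplotype("P"))
  }
  individuals <- vector("list", n)
  dose_B <- integer(n)
  at <- trait$locus_B$pos
  for (i in seq_len(n)) {
    ind <- list(h1 = simulate_gamete(founder, map, chrom),
                h2 = simulate_gamete(founder, map, chrom))
    individuals[[i]] <- ind
    dose_B[i] <- sum(origin_at(ind$h1, at) == "M", origin_at(ind$h2, at) == "M")
  }
  info <- tibble(id = sprintf("ind%04d", seq_len(n)),
                 phenotype = phenotype_from_dose(trait, dose_B),
                 dose_B = dose_B)
  structure(list(individuals = setNames(individuals, info$id),
                 info = info, map = map, trait = trait, chrom = chrom),
            class = "f23_family")
}

#' @export
print.f23_family <- function(x, ...) {
  tb <- table(x$info$phenotype)
  cat("<f23_family> ", nrow(x$info), " individuals on ", x$chrom, " (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Select the two phenotypic pools from a family
#'
#' Uniform random sampling without replacement within each phenotype class:
#' a normal pool (pool 1) and an abnormal pool (pool 2), mirroring the
#' bulked-segregant design of sampling phenotypic extremes from one family.
#'
#' @param family An [simulate_f23_family()] result.
#' @param n_normal,n_abnormal Pool sizes (default 20 and 19).
#' @return A list of class `pool_pair` with elements `normal` and `abnormal`,
#'   each a character vector of individual ids, plus `sizes`.
#' @export
select_pools <- function(family, n_normal = 20L, n_abnormal = 19L) {
  if (n_normal < 1 || n_abnormal < 1) abort("pool sizes must be >= 1")
  ids_n <- family$info$id[family$info$phenotype == "normal"]
  ids_a <- family$info$id[family$info$phenotype == "abnormal"]
  if (length(ids_n) < n_normal) {
    abort(sprintf("need %d normal individuals, family has %d", n_normal, length(ids_n)))
  }
  if (length(ids_a) < n_abnormal) {
    abort(sprintf("need %d abnormal individuals, family has %d", n_abnormal, length(ids_a)))
  }
  structure(list(normal = sample(ids_n, n_normal),
                 abnormal = sample(ids_a, n_abnormal),
                 sizes = c(normal = n_normal, abnormal = n_abnormal)),
            class = "pool_pair")
}
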