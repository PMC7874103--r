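#' Two-locus dominance/epistasis trait model
#'
#' Phenotype is a pure function of genotype at two loci, A and B, each with a
#' dominant allele derived from the mutant parent. The family under study is
#' founded by a single F2 plant that is fixed homozygous-dominant at locus A
#' ("AABb"), so only locus B segregates; locus A is therefore carried as a
#' fixed allele dose rather than a simulated chromosome.
#'
#' Under `"REQUIRE_BOTH"` (complementary dominant epistasis, the default)
#' the abnormal phenotype needs at least one dominant allele at *both* loci;
#' selfing an AABb founder then segregates abnormal:normal = 3:1.
#' `"EITHER"` (duplicate dominant epistasis) needs a dominant allele at
#' either locus; `"B_ONLY"` ignores locus A entirely.
#'
#' @param locus_B `(chrom, pos)` of the segregating causal locus, as a list
#'   or data frame row with `chrom` and `pos`.
#' @param epistasis One of `"REQUIRE_BOTH"`, `"EITHER"`, `"B_ONLY"`.
#' @param dose_A Fixed dominant-allele dose at the background locus A
#'   (0, 1 or 2; default 2, the AABb design).
#' @return An object of class `trait_model`.
#' @export
#' @examples
#' tm <- trait_model(locus_B = list(chrom = "A10", pos = 21340000))
#' enumerate_selfing(tm)
trait_model <- function(locus_B,
                        epistasis = c("REQUIRE_BOTH", "EITHER", "B_ONLY"),
                        dose_A = 2L) {
  epistasis <- match.arg(epistasis)
  stopifnot(!is.null(locus_B$chrom), !is.null(locus_B$pos))
  if (!dose_A %in% 0:2) abort("`dose_A` must be 0, 1 or 2")
  structure(list(locus_B = list(chrom = locus_B$chrom, pos = as.numeric(locus_B$pos)),
                 epistasis = epistasis, dose_A = as.integer(dose_A)),
            class = "trait_model")
}

#' Phenotype from allele doses
#'
#' @param trait A [trait_model()].
#' @param dose_B Integer vector of dominant-allele doses at locus B (0-2).
#' @return Character vector, `"abnormal"` or `"normal"`.
#' @export
phenotype_from_dose <- function(trait, dose_B) {
  has_A <- trait$dose_A >= 1L
  has_B <- dose_B >= 1L
  abn <- switch(trait$epistasis,
                REQUIRE_BOTH = has_A & has_B,
                EITHER = has_A | has_B,
                B_ONLY = has_B)
  ifelse(abn, "abnormal", "normal")
}

#' Exact Punnett enumeration of selfing a locus-B heterozygote
#'
#' Enumerates the four equiprobable progeny gametic combinations at the
#' segregating locus (doses 2:1:1:0, i.e. BB:Bb:bB:bb), classifies each with
#' the trait model, and tabulates expected phenotype probabilities. This is
#' the closed-form oracle behind the simulator's segregation checks.
#'
#' @param trait A [trait_model()]; the founder is heterozygous at locus B.
#' @return A tibble with columns `phenotype`, `prob`, and attribute-free
#'   exact fractions; under `REQUIRE_BOTH` with `dose_A = 2` the
#'   abnormal:normal odds are 3:1.
#' @export
enumerate_selfing <- function(trait) {
  doses <- c(2L, 1L, 1L, 0L)                     # four equiprobable gametes pairs
  ph <- phenotype_from_dose(trait, doses)
  tibble(phenotype = c("abnormal", "normal"),
         prob = c(mean(ph == "abnormal"), mean(ph == "normal")))
}

#' Expected abnormal:normal odds from the enumeration
#'
#' @inheritParams enumerate_selfing
#' @return A single number, `P(abnormal) / P(normal)` (`Inf` if no normals).
#' @export
selfing_odds <- function(trait) {
  e <- enumerate_selfing(trait)
  p <- e$prob[e$phenotype == "abnormal"]
  q <- e$prob[e$phenotype == "normal"]
  if (q == 0) Inf else p / q
}
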