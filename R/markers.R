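#' Genotype a family at a panel of ordered markers
#'
#' Each cell codes the individual's two haplotype origins at the marker:
#' `M` (both mutant-parent), `H` (heterozygous), `P` (both normal-parent).
#' Genotyping is error-free by default; `miscall_rate` replaces a cell with
#' one of the other two codes uniformly at random.
#'
#' @param family An [simulate_f23_family()] result.
#' @param markers Data frame of markers with columns `name`, `chrom`, `pos`;
#'   positions must lie on the simulated chromosome and within its length.
#' @param miscall_rate Per-cell miscall probability (default 0).
#' @return A tibble (the marker-genotype matrix): columns `id`, `phenotype`,
#'   then one column per marker (in panel order) with values in
#'   `{"M","H","P"}`.
#' @export
simulate_marker_panel <- function(family, markers, miscall_rate = 0) {
  markers <- as_tibble(markers)
  stopifnot(all(c("name", "chrom", "pos") %in% names(markers)))
  len <- chrom_length(family$map, family$chrom)
  if (any(markers$chrom != family$chrom) || any(markers$pos < 1 | markers$pos > len)) {
    abort("marker off the simulated chromosome")
  }
  if (anyDuplicated(markers$name) || is.unsorted(markers$pos, strictly = TRUE)) {
    abort("marker names must be unique and positions strictly increasing")
  }
  geno <- vapply(family$individuals, function(ind) {
    m <- (origin_at(ind$h1, markers$pos) == "M") +
      (origin_at(ind$h2, markers$pos) == "M")
    c("P", "H", "M")[m + 1L]
  }, character(nrow(markers)))
  geno <- matrix(geno, nrow = nrow(markers))    # markers x individuals
  if (miscall_rate > 0) {
    flip <- which(runif(length(geno)) < miscall_rate)
    for (i in flip) geno[i] <- sample(setdiff(c("M", "H", "P"), geno[i]), 1L)
  }
  out <- as_tibble(t(geno), .name_repair = "minimal")
  names(out) <- markers$name
  dplyr::bind_cols(family$info[, c("id", "phenotype")], out)
}

#' Read / write a marker panel table
#'
#' The panel TSV mirrors a published marker list: columns `name`, `chrom`,
#' `pos` (1-based bp) and the allele pair `allele_m`, `allele_p`.
#'
#' @param path File path.
#' @return `read_marker_panel()` returns a tibble sorted by position.
#' @export
read_marker_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(pos = readr::col_double(),
                                               .default = readr::col_character()))
  stopifnot(all(c("name", "chrom", "pos") %in% names(x)))
  arrange(x, .data$chrom, .data$pos)
}

#' Bundled A10 marker panel
#'
#' Nine allele-specific PCR markers spanning the distal associated region of
#' chromosome A10 (18.55-21.38 Mbp), shipped as
#' `inst/extdata/parms_markers_a10.tsv`.
#'
#' @return A tibble as from [read_marker_panel()].
#' @export
#' @examples
#' a10_marker_panel()
a10_marker_panel <- function() {
  read_marker_panel(system.file("extdata", "parms_markers_a10.tsv",
                                package = "bsaseq", mustWork = TRUE))
}

#' Write / read a marker-genotype matrix as TSV
#'
#' Columns: `id`, `phenotype`, then one column per marker with cells in
#' `{M, H, P}` (missing cells as `NA`).
#'
#' @param matrix A marker-genotype tibble ([simulate_marker_panel()]).
#' @param path File path.
#' @return `write_genotypes_tsv()` returns `path` invisibly;
#'   `read_genotypes_tsv()` returns the tibble.
#' @export
write_genotypes_tsv <- function(matrix, path) {
  readr::write_tsv(matrix, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
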