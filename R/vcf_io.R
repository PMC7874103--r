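#' Write a pooled site table as VCF 4.2
#'
#' Emits one biallelic record per site with four samples in fixed order —
#' mutant parent, normal parent, normal pool, abnormal pool — carrying
#' `GT:AD`. Parents are written as homozygous calls; pools, being mixtures,
#' carry `./.` genotypes and informative allele depths. The file
#' round-trips losslessly through [load_sites()] followed by
#' [filter_parental_homozygous_divergent()].
#'
#' @param sites Canonical site table (see [simulate_pooled_depths()]).
#' @param path Output file path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsaseq",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "parent_m", "parent_p", "pool1", "pool2",
                      sep = "\t"))
  m_ref <- sites$m_allele == "ref"
  gt_m <- ifelse(m_ref, "0/0", "1/1")
  gt_p <- ifelse(m_ref, "1/1", "0/0")
  ad2 <- function(dp_m, dp_p) {
    ifelse(m_ref, paste(dp_m, dp_p, sep = ","), paste(dp_p, dp_m, sep = ","))
  }
  rows <- if (nrow(sites) == 0) character(0) else
    paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt, ".", "PASS", ".", "GT:AD",
                paste0(gt_m, ":", ad2(sites$dp_parent_m, 0L)),
                paste0(gt_p, ":", ad2(0L, sites$dp_parent_p)),
                paste0("./.:", ad2(sites$dp_pool1_m, sites$dp_pool1_p)),
                paste0("./.:", ad2(sites$dp_pool2_m, sites$dp_pool2_p)),
                sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

# "0/0" etc. to base-level genotype strings like "A/A"; NA for missing
numeric_gt_to_bases <- function(gt, ref, alt) {
  out <- rep(NA_character_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  if (any(ok)) {
    parts <- strsplit(gsub("\\|", "/", gt[ok]), "/", fixed = TRUE)
    a1 <- vapply(parts, `[`, character(1), 1L)
    a2 <- vapply(parts, `[`, character(1), 2L)
    pick <- function(idx, i) ifelse(idx == "0", ref[ok][i], alt[ok][i])
    i <- seq_along(a1)
    out[ok] <- paste(pick(a1, i), pick(a2, i), sep = "/")
  }
  out
}

#' Load pooled variant calls from a VCF
#'
#' Expects exactly four samples in declared order (mutant parent, normal
#' parent, normal pool, abnormal pool), each with an `AD` FORMAT field.
#' Multiallelic records are skipped. Allele depths are mapped onto the
#' mutant/normal-parent (M/P) orientation wherever the parental genotypes
#' determine it (both parents homozygous for different alleles); elsewhere
#' the oriented columns are `NA` and the site is removed by
#' [filter_parental_homozygous_divergent()].
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @return The canonical site table (see [simulate_pooled_depths()]).
#' @export
load_sites <- function(vcf_path) {
  empty <- tibble(chrom = character(), pos = numeric(), ref = character(),
                  alt = character(), variant_class = character(),
                  m_allele = character(),
                  gt_parent_m = character(), gt_parent_p = character(),
                  dp_parent_m = integer(), dp_parent_p = integer(),
                  dp_pool1_m = integer(), dp_pool1_p = integer(),
                  dp_pool2_m = integer(), dp_pool2_p = integer())
  # vcfR chokes on record-less files; short-circuit them
  head_lines <- readLines(vcf_path)
  if (!any(!startsWith(head_lines, "#"))) return(empty)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(v@gt) == 0) return(empty)
  if (ncol(v@gt) != 5L) {                        # FORMAT + 4 samples
    abort(sprintf("expected 4 samples (parent_m, parent_p, pool1, pool2), found %d",
                  ncol(v@gt) - 1L))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (all(is.na(ad))) abort("VCF has no AD FORMAT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- fix[keep, , drop = FALSE]
  ad <- ad[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  ref <- fix$REF; alt <- fix$ALT
  ad_split <- function(j) {
    m <- do.call(rbind, strsplit(ifelse(is.na(ad[, j]), "0,0", ad[, j]), ",", fixed = TRUE))
    cbind(as.integer(m[, 1]), as.integer(m[, 2]))
  }
  ad1 <- ad_split(1); ad2 <- ad_split(2); ad3 <- ad_split(3); ad4 <- ad_split(4)

  gt_m <- numeric_gt_to_bases(gt[, 1], ref, alt)
  gt_p <- numeric_gt_to_bases(gt[, 2], ref, alt)
  al_m <- strsplit(ifelse(is.na(gt_m), "?/?", gt_m), "/", fixed = TRUE)
  al_p <- strsplit(ifelse(is.na(gt_p), "?/?", gt_p), "/", fixed = TRUE)
  hom <- function(a) vapply(a, function(x) x[1] == x[2] && x[1] != "?", logical(1))
  first <- function(a) vapply(a, `[`, character(1), 1L)
  oriented <- hom(al_m) & hom(al_p) & first(al_m) != first(al_p)
  m_is_ref <- oriented & first(al_m) == ref
  m_is_alt <- oriented & first(al_m) == alt
  m_allele <- ifelse(m_is_ref, "ref", ifelse(m_is_alt, "alt", NA_character_))

  orient <- function(adm, col_m) {
    # col_m TRUE -> M allele is REF for that row
    list(m = ifelse(is.na(m_allele), NA_integer_, ifelse(col_m, adm[, 1], adm[, 2])),
         p = ifelse(is.na(m_allele), NA_integer_, ifelse(col_m, adm[, 2], adm[, 1])))
  }
  o1 <- orient(ad1, m_is_ref); o2 <- orient(ad2, m_is_ref)
  o3 <- orient(ad3, m_is_ref); o4 <- orient(ad4, m_is_ref)

  tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = ref, alt = alt,
         variant_class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel"),
         m_allele = m_allele,
         gt_parent_m = gt_m, gt_parent_p = gt_p,
         dp_parent_m = o1$m, dp_parent_p = o2$p,
         dp_pool1_m = o3$m, dp_pool1_p = o3$p,
         dp_pool2_m = o4$m, dp_pool2_p = o4$p)
}
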