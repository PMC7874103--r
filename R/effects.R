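#' Classify variant effects against gene models
#'
#' Re-implementation of the standard variant-effect category scheme used by
#' resequencing annotation tools, with one category per variant. Per-gene
#' precedence is exonic > splicing > intronic > upstream/downstream >
#' intergenic; across overlapping genes the most severe assignment wins.
#' A variant within 1 kb of one gene's end and 1 kb of another's start gets
#' the joint `upstream/downstream` category.
#'
#' Exonic subtypes: a coding SNP is translated before/after through the
#' standard genetic code (`synonymous`, `non-synonymous`, `stopgain`,
#' `stoploss`); an in-frame coding InDel is `non-frameshift
#' insertion`/`deletion` unless it creates or destroys a stop codon
#' (`stopgain`/`stoploss`); a coding InDel whose length is not a multiple of
#' 3 is a `frameshift insertion`/`deletion`. InDels touching an exon/intron
#' boundary are kept exonic (severity precedence) and typed by length alone.
#'
#' @param sites Site table with `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class` (anchored VCF-style indel alleles).
#' @param genes Gene-model tibble (see [gene_model()], [read_gene_models()]).
#' @param genome Named genome sequence: a `Biostrings::DNAStringSet` or a
#'   named character vector of chromosome sequences.
#' @param upstream_bp Up/downstream window from transcript ends (default 1000).
#' @param splice_bp Splice-region width inside each intron end (default 2).
#' @return `sites` with columns `category`, `subtype`, `gene_id` added.
#' @export
classify_variant_effect <- function(sites, genes, genome,
                                    upstream_bp = 1000, splice_bp = 2) {
  n <- nrow(sites)
  category <- character(n); subtype <- rep(NA_character_, n)
  gene_hit <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- classify_one(sites$chrom[i], sites$pos[i], sites$ref[i],
                        sites$alt[i], genes, genome, upstream_bp, splice_bp)
    category[i] <- res$category
    subtype[i] <- res$subtype
    gene_hit[i] <- res$gene_id
  }
  dplyr::bind_cols(as_tibble(sites),
                   tibble(category = category, subtype = subtype,
                          gene_id = gene_hit))
}

# affected genomic interval of an anchored variant, for feature overlap
affected_interval <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1 && la == 1) c(pos, pos)                  # SNP
  else if (la > lr) c(pos, pos + 1)                    # insertion point
  else c(pos + 1, pos + lr - 1)                        # deleted bases
}

severity_rank <- c(exonic = 1, splicing = 2, intronic = 3,
                   upstream = 4, downstream = 4, "upstream/downstream" = 4,
                   intergenic = 5)
subtype_rank <- c(stopgain = 1, stoploss = 2,
                  "frameshift insertion" = 3, "frameshift deletion" = 3,
                  "non-synonymous" = 4,
                  "non-frameshift insertion" = 4, "non-frameshift deletion" = 4,
                  synonymous = 5)

classify_one <- function(chrom, pos, ref, alt, genes, genome,
                         upstream_bp, splice_bp) {
  len <- genome_length(genome, chrom)
  if (pos < 1 || pos + nchar(ref) - 1 > len) {
    abort(sprintf("site %s:%d beyond sequence bounds", chrom, pos))
  }
  iv <- affected_interval(pos, ref, alt)
  gs <- genes[genes$chrom == chrom, , drop = FALSE]
  hits <- list()
  for (k in seq_len(nrow(gs))) {
    g <- gs[k, ]
    cat_k <- classify_vs_gene(iv, pos, ref, alt, g, genome, upstream_bp, splice_bp)
    if (!is.null(cat_k)) hits[[length(hits) + 1L]] <- cat_k
  }
  if (length(hits) == 0) {
    return(list(category = "intergenic", subtype = NA_character_,
                gene_id = NA_character_))
  }
  ranks <- vapply(hits, function(h) severity_rank[[h$category]], numeric(1))
  best <- min(ranks)
  top <- hits[ranks == best]
  if (best == 4) {
    cats <- vapply(top, `[[`, character(1), "category")
    if (any(cats == "upstream") && any(cats == "downstream")) {
      return(list(category = "upstream/downstream", subtype = NA_character_,
                  gene_id = top[[1]]$gene_id))
    }
  }
  if (length(top) > 1 && best == 1) {
    sr <- vapply(top, function(h) {
      if (is.na(h$subtype)) 6 else subtype_rank[[h$subtype]]
    }, numeric(1))
    top <- top[order(sr)]
  }
  top[[1]]
}

classify_vs_gene <- function(iv, pos, ref, alt, g, genome, upstream_bp, splice_bp) {
  ex <- g$exons[[1]]; cd <- g$cds[[1]]
  ovl <- function(s, e) any(iv[1] <= e & s <= iv[2])
  hit <- function(category, subtype = NA_character_) {
    list(category = category, subtype = subtype, gene_id = g$gene_id)
  }
  if (nrow(cd) > 0 && ovl(cd$start, cd$end)) {
    return(hit("exonic", coding_subtype(pos, ref, alt, g, genome)))
  }
  if (ovl(ex$start, ex$end)) return(hit("exonic"))
  if (iv[1] >= g$tx_start && iv[2] <= g$tx_end) {
    # inside the transcript but not exonic: intron; splice region first
    if (nrow(ex) > 1) {
      int_s <- ex$end[-nrow(ex)] + 1; int_e <- ex$start[-1] - 1
      sp <- any((iv[1] <= int_s + splice_bp - 1 & int_s <= iv[2]) |
                  (iv[1] <= int_e & int_e - splice_bp + 1 <= iv[2]))
      if (sp) return(hit("splicing"))
    }
    return(hit("intronic"))
  }
  before <- iv[2] < g$tx_start && iv[2] >= g$tx_start - upstream_bp
  after <- iv[1] > g$tx_end && iv[1] <= g$tx_end + upstream_bp
  if (before) return(hit(if (g$strand == "+") "upstream" else "downstream"))
  if (after) return(hit(if (g$strand == "+") "downstream" else "upstream"))
  NULL
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

translate_dna <- function(x) {
  # trim to whole codons, translate with the standard code
  x <- substr(x, 1, 3 * (nchar(x) %/% 3))
  if (nchar(x) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# subtype of a coding variant for one gene
coding_subtype <- function(pos, ref, alt, g, genome) {
  cd <- g$cds[[1]]
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1 && la == 1) return(snp_subtype(pos, ref, alt, g, genome))
  dlen <- la - lr
  kind <- if (dlen > 0) "insertion" else "deletion"
  if (abs(dlen) %% 3 != 0) return(paste("frameshift", kind))
  # in-frame: rebuild the CDS with the variant applied if it is fully coding
  contained <- any(pos >= cd$start & (pos + lr - 1) <= cd$end)
  if (!contained) return(paste("non-frameshift", kind))
  plus <- paste(vapply(seq_len(nrow(cd)), function(j) {
    fetch_seq(genome, g$chrom, cd$start[j], cd$end[j])
  }, character(1)), collapse = "")
  offs <- cumsum(c(0, cd$end - cd$start + 1))
  j <- which(pos >= cd$start & pos <= cd$end)[1]
  at <- offs[j] + (pos - cd$start[j]) + 1          # 1-based in plus CDS
  mut_plus <- paste0(substr(plus, 1, at - 1), alt,
                     substr(plus, at + lr, nchar(plus)))
  ref_cds <- if (g$strand == "+") plus else revcomp(plus)
  mut_cds <- if (g$strand == "+") mut_plus else revcomp(mut_plus)
  ref_aa <- translate_dna(ref_cds); mut_aa <- translate_dna(mut_cds)
  ref_internal_stop <- grepl("\\*.", ref_aa)
  mut_internal_stop <- grepl("\\*.", mut_aa)
  ref_ends_stop <- grepl("\\*$", ref_aa)
  mut_ends_stop <- grepl("\\*$", mut_aa)
  if (mut_internal_stop && !ref_internal_stop) return("stopgain")
  if (ref_ends_stop && !mut_ends_stop && !mut_internal_stop) return("stoploss")
  paste("non-frameshift", kind)
}

snp_subtype <- function(pos, ref, alt, g, genome) {
  cd <- g$cds[[1]]
  offs <- cumsum(c(0, cd$end - cd$start + 1))
  total <- offs[length(offs)]
  j <- which(pos >= cd$start & pos <= cd$end)[1]
  at_plus <- offs[j] + (pos - cd$start[j]) + 1
  if (g$strand == "+") {
    ci <- at_plus; cref <- ref; calt <- alt
  } else {
    ci <- total - at_plus + 1
    cref <- chartr("ACGT", "TGCA", ref); calt <- chartr("ACGT", "TGCA", alt)
  }
  codon_i <- (ci - 1) %/% 3
  codon_start_plus <- function(ci0) {
    # map coding index back to plus-CDS index
    if (g$strand == "+") ci0 else total - ci0 + 1
  }
  # extract the ref codon from the genome via the CDS map
  coding_base <- function(cidx) {
    pidx <- codon_start_plus(cidx)
    jj <- findInterval(pidx, offs + 1)
    gpos <- cd$start[jj] + (pidx - offs[jj] - 1)
    b <- fetch_seq(genome, g$chrom, gpos, gpos)
    if (g$strand == "+") b else chartr("ACGT", "TGCA", b)
  }
  idxs <- codon_i * 3 + 1:3
  codon <- paste(vapply(idxs, coding_base, character(1)), collapse = "")
  within <- ci - codon_i * 3
  stopifnot(substr(codon, within, within) == cref)
  mut <- codon
  substr(mut, within, within) <- calt
  aa_ref <- translate_dna(codon); aa_mut <- translate_dna(mut)
  if (aa_ref == "*" && aa_mut != "*") return("stoploss")
  if (aa_mut == "*" && aa_ref != "*") return("stopgain")
  if (aa_ref == aa_mut) "synonymous" else "non-synonymous"
}

effect_label <- function(category, subtype) {
  lab <- ifelse(category == "exonic" & !is.na(subtype), subtype, category)
  pretty <- c(upstream = "Upstream", downstream = "Downstream",
              "upstream/downstream" = "Upstream/downstream",
              intergenic = "Intergenic", intronic = "Intronic",
              splicing = "Splicing", exonic = "Exonic",
              synonymous = "Synonymous", "non-synonymous" = "Non-synonymous",
              stopgain = "Stop gain", stoploss = "Stop loss",
              "frameshift insertion" = "Frameshift insertion",
              "frameshift deletion" = "Frameshift deletion",
              "non-frameshift insertion" = "Non-frameshift insertion",
              "non-frameshift deletion" = "Non-frameshift deletion")
  unname(pretty[lab])
}

#' Summarize classified variants into a category count table
#'
#' Produces the familiar per-sample annotation summary: counts per effect
#' category (exonic rows broken out by subtype), a `Total` row, and — for
#' SNPs — transition/transversion counts and their ratio (`ts` counts
#' A<->G and C<->T substitutions; `tv` all other base pairs; the ratio is
#' `NA` when there are no transversions).
#'
#' @param classified Output of [classify_variant_effect()].
#' @return A tibble with columns `variant_class`, `category`, `n`; for SNPs
#'   the rows `ts`, `tv`, `ts/tv` are appended after `Total`.
#' @export
summarize_effects <- function(classified) {
  if (nrow(classified) == 0) {
    return(tibble(variant_class = character(), category = character(),
                  n = numeric()))
  }
  lab <- effect_label(classified$category, classified$subtype)
  counts <- tibble(variant_class = classified$variant_class, category = lab) |>
    dplyr::count(.data$variant_class, .data$category) |>
    mutate(n = as.numeric(n))
  out <- counts |>
    group_by(.data$variant_class) |>
    dplyr::group_modify(function(d, key) {
      d <- bind_rows(d, tibble(category = "Total", n = sum(d$n)))
      if (key$variant_class == "SNP") {
        snps <- classified[classified$variant_class == "SNP", ]
        pair <- paste0(pmin(snps$ref, snps$alt), pmax(snps$ref, snps$alt))
        ts <- sum(pair %in% c("AG", "CT"))
        tv <- sum(!pair %in% c("AG", "CT"))
        d <- bind_rows(d, tibble(category = c("ts", "tv", "ts/tv"),
                                 n = c(ts, tv, if (tv > 0) ts / tv else NA_real_)))
      }
      d
    }) |>
    ungroup()
  out
}
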