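# Fixture generator and brute-force oracle for the variant-effect classifier.
# The oracle is deliberately independent of the package implementation: it
# annotates every base of the toy chromosome, rebuilds the whole mutant
# chromosome sequence, re-splices the CDS in shifted coordinates and
# translates with its own codon table.

ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  # standard-order codons: third base varies fastest (TTT, TTC, TTA, ...)
  codons <- paste0(rep(bases, each = 16), rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), NULL)[[1]]), collapse = "")
}

oracle_translate <- function(x) {
  n <- nchar(x) %/% 3
  if (n == 0) return("")
  paste(ORACLE_CODONS[substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

# random single-gene (or two-gene) toy fixture on a short chromosome
random_toy_fixture <- function(two_genes = FALSE, chrom_len = 3000) {
  bases <- c("A", "C", "G", "T")
  genome <- paste(sample(bases, chrom_len, replace = TRUE), collapse = "")
  make_gene <- function(gene_id, lo, hi, strand = sample(c("+", "-"), 1)) {
    n_ex <- sample(1:5, 1)
    # random exon/intron layout inside [lo, hi]
    repeat {
      cuts <- sort(sample(seq(lo, hi), 2 * n_ex))
      starts <- cuts[seq(1, 2 * n_ex, 2)]; ends <- cuts[seq(2, 2 * n_ex, 2)]
      if (all(ends - starts + 1 >= 9) &&
          (n_ex == 1 || all(starts[-1] - ends[-n_ex] > 10))) break
    }
    # trim last exon so total CDS length is a codon multiple
    total <- sum(ends - starts + 1)
    ends[n_ex] <- ends[n_ex] - (total %% 3)
    total <- sum(ends - starts + 1)
    # coding sequence without internal stops, ending in a stop codon
    sense <- names(ORACLE_CODONS)[!ORACLE_CODONS %in% "*"]
    cds_seq <- paste(c(sample(sense, total / 3 - 1, replace = TRUE), "TAA"),
                     collapse = "")
    plus_seq <- if (strand == "+") cds_seq else oracle_revcomp(cds_seq)
    off <- 0
    for (j in seq_len(n_ex)) {
      w <- ends[j] - starts[j] + 1
      substr(genome, starts[j], ends[j]) <<- substr(plus_seq, off + 1, off + w)
      off <- off + w
    }
    gene_model(gene_id, "toy", strand,
               exons = data.frame(start = starts, end = ends))
  }
  if (two_genes) {
    g1 <- make_gene("g1", 300, 1300)
    g2 <- make_gene("g2", 1700, 2700)
    genes <- dplyr::bind_rows(g1, g2)
  } else {
    genes <- make_gene("g1", 500, 2500)
  }
  list(genome = c(toy = genome), genes = genes)
}

# random variant on the fixture chromosome
random_toy_variant <- function(fix, max_len = 5) {
  genome <- fix$genome[["toy"]]
  len <- nchar(genome)
  kind <- sample(c("SNP", "ins", "del"), 1, prob = c(0.5, 0.25, 0.25))
  pos <- sample(seq(20, len - 20), 1)
  refb <- substr(genome, pos, pos)
  if (kind == "SNP") {
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    ref <- refb
  } else if (kind == "ins") {
    k <- sample(max_len, 1)
    ref <- refb
    alt <- paste0(refb, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = ""))
  } else {
    k <- sample(max_len, 1)
    ref <- substr(genome, pos, pos + k)
    alt <- refb
  }
  tibble::tibble(chrom = "toy", pos = pos, ref = ref, alt = alt,
                 variant_class = if (kind == "SNP") "SNP" else "InDel")
}

# --- brute-force oracle ----------------------------------------------------

# per-base severity labels for one gene; 1 = most severe
oracle_base_labels <- function(g, len, upstream_bp = 1000, splice_bp = 2) {
  lab <- rep("intergenic", len)
  ex <- g$exons[[1]]; cd <- g$cds[[1]]
  up_iv <- if (g$strand == "+") c(g$tx_start - upstream_bp, g$tx_start - 1)
  else c(g$tx_end + 1, g$tx_end + upstream_bp)
  dn_iv <- if (g$strand == "+") c(g$tx_end + 1, g$tx_end + upstream_bp)
  else c(g$tx_start - upstream_bp, g$tx_start - 1)
  paint <- function(iv, what) {
    s <- max(1, iv[1]); e <- min(len, iv[2])
    if (s <= e) lab[s:e] <<- what
  }
  paint(up_iv, "upstream"); paint(dn_iv, "downstream")
  paint(c(g$tx_start, g$tx_end), "intronic")
  if (nrow(ex) > 1) {
    for (j in seq_len(nrow(ex) - 1)) {
      paint(c(ex$end[j] + 1, ex$end[j] + splice_bp), "splicing")
      paint(c(ex$start[j + 1] - splice_bp, ex$start[j + 1] - 1), "splicing")
    }
  }
  for (j in seq_len(nrow(ex))) paint(c(ex$start[j], ex$end[j]), "exonic")
  lab
}

oracle_affected <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1 && la == 1) c(pos, pos)
  else if (la > lr) c(pos, pos + 1)
  else c(pos + 1, pos + lr - 1)
}

# full-rebuild subtype for a coding variant on gene g
oracle_coding_subtype <- function(pos, ref, alt, g, genome_str) {
  lr <- nchar(ref); la <- nchar(alt); dlen <- la - lr
  mut_genome <- paste0(substr(genome_str, 1, pos - 1), alt,
                       substr(genome_str, pos + lr, nchar(genome_str)))
  cd <- g$cds[[1]]
  if (dlen != 0 && !any(pos >= cd$start & (pos + lr - 1) <= cd$end)) {
    # boundary-spanning indel: typed by length alone (declared contract)
    kind0 <- if (dlen > 0) "insertion" else "deletion"
    return(paste(if (abs(dlen) %% 3 == 0) "non-frameshift" else "frameshift",
                 kind0))
  }
  # shift CDS interval bounds past the variant into mutant coordinates
  shift <- function(x) ifelse(x > pos + lr - 1, x + dlen, x)
  grab <- function(gseq, s, e) substr(gseq, s, e)
  ref_plus <- paste(mapply(grab, list(genome_str), cd$start, cd$end),
                    collapse = "")
  ms <- shift(cd$start); me <- shift(cd$end)
  # an interval containing the variant keeps its start, its end absorbs dlen
  inside <- pos >= cd$start & pos <= cd$end
  me[inside] <- cd$end[inside] + dlen
  mut_plus <- paste(mapply(grab, list(mut_genome), ms, me), collapse = "")
  ref_cds <- if (g$strand == "+") ref_plus else oracle_revcomp(ref_plus)
  mut_cds <- if (g$strand == "+") mut_plus else oracle_revcomp(mut_plus)
  kind <- if (dlen > 0) "insertion" else if (dlen < 0) "deletion" else "SNP"
  if (kind != "SNP" && abs(dlen) %% 3 != 0) return(paste("frameshift", kind))
  ref_aa <- oracle_translate(ref_cds); mut_aa <- oracle_translate(mut_cds)
  internal_stop <- function(aa) grepl("\\*.", aa)
  ends_stop <- function(aa) grepl("\\*$", aa)
  if (internal_stop(mut_aa) && !internal_stop(ref_aa)) return("stopgain")
  if (kind == "SNP") {
    if (ends_stop(ref_aa) && !ends_stop(mut_aa) && !internal_stop(mut_aa)) {
      return("stoploss")
    }
    return(if (ref_aa == mut_aa) "synonymous" else "non-synonymous")
  }
  if (ends_stop(ref_aa) && !ends_stop(mut_aa) && !internal_stop(mut_aa)) {
    return("stoploss")
  }
  paste("non-frameshift", kind)
}

oracle_classify <- function(variant, genes, genome,
                            upstream_bp = 1000, splice_bp = 2) {
  genome_str <- genome[[variant$chrom]]
  len <- nchar(genome_str)
  iv <- oracle_affected(variant$pos, variant$ref, variant$alt)
  sev <- c(exonic = 1, splicing = 2, intronic = 3, upstream = 4,
           downstream = 4, intergenic = 5)
  per_gene <- lapply(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    lab <- oracle_base_labels(g, len, upstream_bp, splice_bp)
    piece <- lab[iv[1]:iv[2]]
    best <- piece[which.min(sev[piece])]
    list(gene = g, label = best)
  })
  ranks <- vapply(per_gene, function(h) sev[[h$label]], numeric(1))
  best <- min(ranks)
  top <- per_gene[ranks == best]
  if (best == 5) return(list(category = "intergenic", subtype = NA_character_))
  if (best == 4) {
    labs <- vapply(top, `[[`, character(1), "label")
    if (any(labs == "upstream") && any(labs == "downstream")) {
      return(list(category = "upstream/downstream", subtype = NA_character_))
    }
    return(list(category = labs[1], subtype = NA_character_))
  }
  if (best != 1) return(list(category = top[[1]]$label, subtype = NA_character_))
  # exonic: coding when the affected interval touches CDS of the gene
  sub <- NA_character_
  for (h in top) {
    cd <- h$gene$cds[[1]]
    if (any(iv[1] <= cd$end & cd$start <= iv[2])) {
      sub <- oracle_coding_subtype(variant$pos, variant$ref, variant$alt,
                                   h$gene, genome_str)
      break
    }
  }
  list(category = "exonic", subtype = sub)
}
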