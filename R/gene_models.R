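#' Construct a single gene model
#'
#' A minimal one-transcript gene model: a transcript span with sorted,
#' non-overlapping exons and CDS intervals (1-based inclusive). CDS must be
#' contained in exons.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`.
#' @param cds Data frame with columns `start`, `end` (may be empty).
#' @return A one-row tibble with list-columns `exons` and `cds`; rows of
#'   several calls can be bound into a gene-model table.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- arrange(as_tibble(exons)[, c("start", "end")], .data$start)
  cds <- arrange(as_tibble(cds)[, c("start", "end")], .data$start)
  if (any(exons$start > exons$end)) abort("exon start > end")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons overlap")
  }
  for (i in seq_len(nrow(cds))) {
    if (!any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)) {
      abort("CDS interval not contained in an exon")
    }
  }
  tibble(gene_id = gene_id, chrom = chrom, strand = strand,
         tx_start = min(exons$start), tx_end = max(exons$end),
         exons = list(exons), cds = list(cds))
}

#' Read gene models from a GFF3 file
#'
#' Collapses `gene`/`mRNA`/`exon`/`CDS` features into the package's
#' one-transcript-per-gene model table, resolving `Parent` chains
#' (exon/CDS -> transcript -> gene). Files with exon/CDS attached directly
#' to a gene feature are also accepted.
#'
#' @param gff_path Path to a GFF3 file.
#' @return A gene-model tibble as built by [gene_model()].
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path)
  df <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               type = as.character(gr$type),
               id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
               parent = vapply(if (!is.null(gr$Parent)) as.list(gr$Parent) else
                                 rep(list(character(0)), length(gr)),
                               function(p) if (length(p)) p[[1]] else NA_character_,
                               character(1)))
  tx2gene <- setNames(df$parent[df$type %in% c("mRNA", "transcript")],
                      df$id[df$type %in% c("mRNA", "transcript")])
  gene_ids <- df$id[df$type == "gene"]
  resolve_gene <- function(parent) {
    ifelse(parent %in% names(tx2gene), unname(tx2gene[parent]), parent)
  }
  feats <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  feats$gene <- resolve_gene(feats$parent)
  out <- lapply(unique(feats$gene), function(g) {
    fx <- feats[feats$gene == g, , drop = FALSE]
    ex <- fx[fx$type == "exon", c("start", "end")]
    cd <- fx[fx$type == "CDS", c("start", "end")]
    if (nrow(ex) == 0) ex <- cd
    gene_model(g, fx$chrom[1], fx$strand[1], ex, cd)
  })
  bind_rows(out)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()] for the package's toy fixtures: each gene
#' becomes a `gene` + `mRNA` pair with `exon` and `CDS` children.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    tx <- paste0(g$gene_id, ".t1")
    mk <- function(type, s, e, attrs) {
      paste(g$chrom, "bsaseq", type, s, e, ".", g$strand, ".", attrs, sep = "\t")
    }
    lines <- c(lines,
               mk("gene", g$tx_start, g$tx_end, paste0("ID=", g$gene_id)),
               mk("mRNA", g$tx_start, g$tx_end,
                  paste0("ID=", tx, ";Parent=", g$gene_id)))
    ex <- g$exons[[1]]; cd <- g$cds[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, mk("exon", ex$start[j], ex$end[j],
                           paste0("ID=", tx, ".e", j, ";Parent=", tx)))
    }
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, mk("CDS", cd$start[j], cd$end[j],
                           paste0("ID=", tx, ".c", j, ";Parent=", tx)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# fetch genomic sequence [start, end] from DNAStringSet or named character
fetch_seq <- function(genome, chrom, start, end) {
  if (methods::is(genome, "DNAStringSet")) {
    as.character(Biostrings::subseq(genome[[chrom]], start, end))
  } else {
    substr(genome[[chrom]], start, end)
  }
}

genome_length <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) length(genome[[chrom]]) else nchar(genome[[chrom]])
}
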