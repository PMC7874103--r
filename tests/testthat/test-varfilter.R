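make_sites <- function(gt_m, gt_p, d1m = 10L, d1p = 10L, d2m = 10L, d2p = 10L,
                       m_allele = "ref") {
  tibble::tibble(chrom = "A10", pos = seq_along(gt_m) * 100,
                 ref = "A", alt = "G", variant_class = "SNP",
                 m_allele = m_allele, gt_parent_m = gt_m, gt_parent_p = gt_p,
                 dp_parent_m = 12L, dp_parent_p = 12L,
                 dp_pool1_m = d1m, dp_pool1_p = d1p,
                 dp_pool2_m = d2m, dp_pool2_p = d2p)
}

test_that("parental filter keeps only homozygous-divergent sites and is idempotent", {
  s <- make_sites(gt_m = c("A/A", "A/G", "A/A", "A/A"),
                  gt_p = c("G/G", "G/G", "A/A", "G/G"),
                  m_allele = c("ref", NA, NA, "ref"))
  out <- filter_parental_homozygous_divergent(s)
  expect_equal(out$pos, c(100, 400))      # het parent and non-divergent removed
  expect_identical(filter_parental_homozygous_divergent(out), out)
})

test_that("depth filter is per-pool, keeps the boundary, and is idempotent", {
  s <- make_sites(rep("A/A", 3), rep("G/G", 3),
                  d1m = c(5L, 4L, 0L), d1p = c(5L, 2L, 5L),
                  d2m = c(4L, 4L, 4L), d2p = c(3L, 3L, 3L))
  # totals pool1: 10, 6, 5; pool2: 7, 7, 7
  out <- filter_min_depth(s, 7)
  expect_equal(out$pos, 100)              # (10,7) kept; (6,7) and (5,7) removed
  expect_identical(filter_min_depth(out, 7), out)
  expect_equal(nrow(filter_min_depth(s[0, ], 7)), 0)
  expect_error(filter_min_depth(s, 0), "min_depth")
})

test_that("VCF writing round-trips losslessly through the loader", {
  withr::local_seed(21)
  cfg <- bsa_config(seed = 21, n_sites = 150, n_family = 160)
  sim <- run_simulation(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sites_vcf(sim$sites, path, contigs = c(A10 = 26.6e6))
  back <- load_sites(path)
  back <- filter_parental_homozygous_divergent(back)
  orig <- filter_parental_homozygous_divergent(sim$sites)
  for (col in names(orig)) {
    expect_equal(back[[col]], orig[[col]], info = col)
  }
  expect_error(load_sites(write_sites_vcf(sim$sites[0, ], path)), NA)
})

test_that("loader rejects VCFs without four samples", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2", sep = "\t"),
               paste("A10", "100", ".", "A", "G", ".", "PASS", ".", "GT:AD",
                     "0/0:9,0", "1/1:0,9", sep = "\t")), path)
  expect_error(load_sites(path), "4 samples")
})

test_that("hand-built classifier cases: degenerate codon, in-frame insertion, upstream rule", {
  # + strand gene, one exon: CDS = ATG GAA (GCT)x16 TAA at 101..157
  cds <- paste0("ATG", "GAA", strrep("GCT", 16), "TAA")
  genome <- c(toy = paste0(strrep("T", 100), cds, strrep("T", 2000)))
  g <- gene_model("g1", "toy", "+", exons = data.frame(start = 101, end = 157))

  v <- tibble::tibble(chrom = "toy",
                      pos = c(106, 104, 106, 106, 102, 1500, 1161),
                      ref = c("A", "G", "A", "A", "T", "T", "T"),
                      alt = c("G", "C", "ACTG", "AGCATCA", "C", "A", "C"),
                      variant_class = c("SNP", "SNP", "InDel", "InDel",
                                        "SNP", "SNP", "SNP"))
  out <- classify_variant_effect(v, g, genome)
  # GAA -> GAG, both Glu
  expect_equal(out$subtype[1], "synonymous")
  # GAA -> CAA (Gln)
  expect_equal(out$subtype[2], "non-synonymous")
  # CTG inserted at a codon boundary: adds one Leu, keeps the frame
  expect_equal(out$category[3], "exonic")
  expect_equal(out$subtype[3], "non-frameshift insertion")
  # 6-bp in-frame insertion without a stop
  expect_equal(out$subtype[4], "non-frameshift insertion")
  # ATG -> ACG start-codon change is a non-synonymous coding SNP
  expect_equal(out$category[5], "exonic")
  expect_equal(out$subtype[5], "non-synonymous")
  # far from the gene, and just past the 1 kb downstream window
  expect_equal(out$category[6], "intergenic")
  expect_equal(out$category[7], "intergenic")

  # 500 bp 5' of a transcript start -> upstream; same point for a "-"
  # strand gene is downstream (interior gene so the window fits)
  gmid <- gene_model("g3", "toy", "+",
                     exons = data.frame(start = 1101, end = 1157))
  v2 <- tibble::tibble(chrom = "toy", pos = 1101 - 500, ref = "T", alt = "A",
                       variant_class = "SNP")
  expect_equal(classify_variant_effect(v2, gmid, genome)$category, "upstream")
  gneg <- gene_model("g4", "toy", "-",
                     exons = data.frame(start = 1101, end = 1157))
  expect_equal(classify_variant_effect(v2, gneg, genome)$category, "downstream")
})

test_that("stop gain and loss are detected for SNPs and in-frame indels", {
  cds <- paste0("ATG", "TGG", strrep("GCT", 16), "TAA")   # TGG = Trp
  genome <- c(toy = paste0(strrep("C", 100), cds, strrep("C", 500)))
  g <- gene_model("g1", "toy", "+", exons = data.frame(start = 101, end = 157))
  v <- tibble::tibble(
    chrom = "toy",
    pos = c(105, 156, 106),
    ref = c("G", "A", "G"),
    alt = c("A", "C", "GTAA"),   # TGG->TAG stop; TAA->TCA lost; insert TAA
    variant_class = c("SNP", "SNP", "InDel"))
  out <- classify_variant_effect(v, g, genome)
  expect_equal(out$subtype, c("stopgain", "stoploss", "stopgain"))
})

test_that("splicing, intronic and joint upstream/downstream categories resolve", {
  genome <- c(toy = paste(rep("A", 4000), collapse = ""))
  g1 <- gene_model("g1", "toy", "+",
                   exons = data.frame(start = c(1001, 1501), end = c(1200, 1700)),
                   cds = data.frame(start = numeric(0), end = numeric(0)))
  v <- tibble::tibble(chrom = "toy",
                      pos = c(1201, 1202, 1203, 1499, 1350),
                      ref = "A", alt = "C", variant_class = "SNP")
  out <- classify_variant_effect(v, g1, genome)
  expect_equal(out$category, c("splicing", "splicing", "intronic",
                               "splicing", "intronic"))

  # between two genes within 1 kb of both: downstream of g1, upstream of g2
  g2 <- gene_model("g2", "toy", "+",
                   exons = data.frame(start = 2500, end = 2800),
                   cds = data.frame(start = numeric(0), end = numeric(0)))
  genes <- dplyr::bind_rows(g1, g2)
  vb <- tibble::tibble(chrom = "toy", pos = 2000, ref = "A", alt = "G",
                       variant_class = "SNP")
  expect_equal(classify_variant_effect(vb, genes, genome)$category,
               "upstream/downstream")
})

test_that("classifier agrees with the brute-force rebuild-and-translate oracle", {
  withr::local_seed(22)
  n_checked <- 0
  for (rep in 1:12) {
    fix <- random_toy_fixture(two_genes = rep %% 3 == 0)
    for (k in 1:25) {
      v <- random_toy_variant(fix)
      got <- classify_variant_effect(v, fix$genes, fix$genome)
      want <- oracle_classify(v, fix$genes, fix$genome)
      expect_equal(got$category, want$category,
                   info = paste("category at", v$pos, v$ref, ">", v$alt))
      expect_equal(got$subtype, want$subtype,
                   info = paste("subtype at", v$pos, v$ref, ">", v$alt))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 300)
})

test_that("exonic subtype is invariant under reverse-complementing the fixture", {
  withr::local_seed(23)
  for (rep in 1:6) {
    fix <- random_toy_fixture()
    len <- nchar(fix$genome[["toy"]])
    g <- fix$genes
    mirror_iv <- function(s, e) data.frame(start = len - e + 1, end = len - s + 1)
    ex <- g$exons[[1]]
    gm <- gene_model(g$gene_id, "toy", if (g$strand == "+") "-" else "+",
                     exons = mirror_iv(ex$start, ex$end)[nrow(ex):1, ])
    genome_rc <- c(toy = oracle_revcomp(fix$genome[["toy"]]))
    for (k in 1:15) {
      repeat {
        v <- random_toy_variant(fix)
        if (v$variant_class == "SNP") break
      }
      v_rc <- v
      v_rc$pos <- len - v$pos + 1
      v_rc$ref <- chartr("ACGT", "TGCA", v$ref)
      v_rc$alt <- chartr("ACGT", "TGCA", v$alt)
      a <- classify_variant_effect(v, g, fix$genome)
      b <- classify_variant_effect(v_rc, gm, genome_rc)
      expect_equal(b$subtype, a$subtype)
      if (a$category %in% c("exonic", "splicing", "intronic", "intergenic")) {
        expect_equal(b$category, a$category)
      }
    }
  }
})

test_that("every variant gets exactly one category and counts partition the input", {
  withr::local_seed(24)
  fix <- random_toy_fixture(two_genes = TRUE)
  vs <- dplyr::bind_rows(lapply(1:120, function(i) random_toy_variant(fix)))
  out <- classify_variant_effect(vs, fix$genes, fix$genome)
  expect_false(any(is.na(out$category)))
  expect_equal(nrow(out), nrow(vs))
  sm <- summarize_effects(out)
  for (cls in unique(out$variant_class)) {
    tot <- sm$n[sm$variant_class == cls & sm$category == "Total"]
    expect_equal(tot, sum(out$variant_class == cls))
  }
})

test_that("ts/tv summary matches hand counts and handles edge cases", {
  mk <- function(ref, alt) {
    tibble::tibble(chrom = "c", pos = seq_along(ref), ref = ref, alt = alt,
                   variant_class = "SNP", category = "intergenic",
                   subtype = NA_character_, gene_id = NA_character_)
  }
  # 4 transitions (A<->G, C<->T), 3 transversions
  s <- mk(c("A", "G", "C", "T", "A", "A", "C"),
          c("G", "A", "T", "C", "C", "T", "G"))
  sm <- summarize_effects(s)
  expect_equal(sm$n[sm$category == "ts"], 4)
  expect_equal(sm$n[sm$category == "tv"], 3)
  expect_equal(round(sm$n[sm$category == "ts/tv"], 3), 1.333)

  # no transversions: zero denominator -> NA
  s2 <- mk(c("A", "G"), c("G", "A"))
  sm2 <- summarize_effects(s2)
  expect_true(is.na(sm2$n[sm2$category == "ts/tv"]))
  # all transversions is defined: ratio 0
  sm3 <- summarize_effects(mk(c("A", "C"), c("C", "A")))
  expect_equal(sm3$n[sm3$category == "ts/tv"], 0)

  expect_equal(nrow(summarize_effects(s[0, ])), 0)
})
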