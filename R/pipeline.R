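#' Pipeline configuration
#'
#' One configuration object drives both the synthetic and the real-data
#' modes. All analysis defaults are the pipeline's canonical settings:
#' per-pool depth filter 7, low-index filter 0.3, 1 Mb windows at 10 kb
#' steps, 95% Monte-Carlo confidence threshold, pools of 20 normal / 19
#' abnormal plants at ~27.6x pooled depth on a 26.6 Mbp chromosome.
#' Round-trips through YAML via [write_config()] / [read_config()].
#'
#' @param chrom,chrom_length Simulated chromosome name and length (bp).
#' @param recomb_rate cM per Mbp.
#' @param causal_pos Causal-locus position (bp).
#' @param n_family F2:3 family size.
#' @param n_sites Segregating sites simulated on the chromosome.
#' @param indel_fraction Fraction of sites emitted as InDels.
#' @param pool_normal,pool_abnormal Pool sizes.
#' @param lambda_pool,lambda_parent,error_rate Depth model parameters.
#' @param min_depth,low_index Site filters.
#' @param window_size,step Sliding-window geometry (bp).
#' @param level,n_sim Null-threshold confidence level and replicates.
#' @param epistasis Trait model epistasis mode.
#' @param seed Integer seed for all randomness.
#' @return A list of class `bsa_config`.
#' @export
bsa_config <- function(chrom = "A10", chrom_length = 26.6e6, recomb_rate = 4,
                       causal_pos = 21.34e6, n_family = 200L,
                       n_sites = 2000L, indel_fraction = 0.25,
                       pool_normal = 20L, pool_abnormal = 19L,
                       lambda_pool = 27.6, lambda_parent = 15.8,
                       error_rate = 0.001,
                       min_depth = 7, low_index = 0.3,
                       window_size = 1e6, step = 1e4,
                       level = 0.95, n_sim = 2000L,
                       epistasis = "REQUIRE_BOTH", seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "bsa_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [bsa_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the `bsa_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(bsa_config, yaml::read_yaml(path))
}

#' Simulate a full study scenario and write its inputs to disk
#'
#' Builds the genome map, simulates the F2:3 family, selects the pools,
#' simulates pooled depths and the marker panel, and writes the pipeline
#' inputs: a 4-sample VCF (`sites.vcf`), a marker-genotype TSV
#' (`genotypes.tsv`), and a truth file (`truth.yaml`) recording the causal
#' position and per-individual causal-allele doses for downstream oracles.
#'
#' @param config A [bsa_config()].
#' @param outdir Output directory (created if needed); `NULL` returns the
#'   in-memory objects without writing.
#' @param markers Optional marker panel (`name`, `chrom`, `pos`); defaults
#'   to the bundled A10 panel when it fits on the simulated chromosome.
#' @return Invisibly, a list with `sites`, `genotypes`, `family`, `pools`,
#'   `truth`, and (if written) `paths`.
#' @export
run_simulation <- function(config, outdir = NULL, markers = NULL) {
  set.seed(config$seed)
  map <- genome_map(tibble(chrom = config$chrom, length = config$chrom_length),
                    recomb_rate = config$recomb_rate)
  map <- populate_sites(map, config$n_sites, config$indel_fraction)
  trait <- trait_model(list(chrom = config$chrom, pos = config$causal_pos),
                       epistasis = config$epistasis)
  fam <- simulate_f23_family(config$n_family, map, trait)
  pools <- select_pools(fam, config$pool_normal, config$pool_abnormal)
  dm <- depth_model(config$lambda_pool, config$lambda_parent, config$error_rate)
  sites <- simulate_pooled_depths(fam, pools, dm)
  if (is.null(markers)) {
    markers <- a10_marker_panel()
    markers$chrom <- config$chrom
    markers <- markers[markers$pos <= config$chrom_length, , drop = FALSE]
  }
  genotypes <- simulate_marker_panel(fam, markers)
  truth <- list(causal_chrom = config$chrom, causal_pos = config$causal_pos,
                dose_B = setNames(as.list(fam$info$dose_B), fam$info$id),
                pool_normal = pools$normal, pool_abnormal = pools$abnormal)
  out <- list(sites = sites, genotypes = genotypes, family = fam,
              pools = pools, truth = truth, markers = markers)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(outdir, "sites.vcf"),
                  genotypes = file.path(outdir, "genotypes.tsv"),
                  truth = file.path(outdir, "truth.yaml"),
                  config = file.path(outdir, "config.yaml"))
    write_sites_vcf(sites, paths$vcf,
                    contigs = setNames(config$chrom_length, config$chrom))
    write_genotypes_tsv(genotypes, paths$genotypes)
    yaml::write_yaml(truth, paths$truth)
    write_config(config, paths$config)
    out$paths <- paths
  }
  invisible(out)
}

#' Run the association scan: filters, indices, windows, thresholds, regions
#'
#' The full chain from a loaded (or simulated) site table to called
#' regions: parental homozygous-divergent filter, per-pool depth filter,
#' per-site indices, low-index filter, sliding windows per variant class,
#' per-window Monte-Carlo thresholds, region calling, and the SNP/InDel
#' region intersection. Filter input/output counts are recorded.
#'
#' @param sites Canonical site table, or a path to a VCF readable by
#'   [load_sites()].
#' @param config A [bsa_config()] providing thresholds and geometry.
#' @param chrom_lengths Named vector of chromosome lengths; default derived
#'   from the config.
#' @param method Threshold method passed to [call_regions()].
#' @param outdir Optional directory to write per-site and per-window TSVs
#'   and a region BED into.
#' @return An object of class `bsa_scan`: list with `records` (per-site
#'   indices), `windows` (with `threshold` and `call` columns), `regions`
#'   (SNP, InDel and overlap rows), `counts` (filter bookkeeping) and
#'   `params`.
#' @export
run_association <- function(sites, config = bsa_config(),
                            chrom_lengths = NULL,
                            method = c("ci", "median_sd"), outdir = NULL) {
  method <- match.arg(method)
  set.seed(config$seed + 1L)
  if (is.character(sites)) sites <- load_sites(sites)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(config$chrom_length, config$chrom)
  }
  counts <- c(loaded = nrow(sites))
  sites <- filter_parental_homozygous_divergent(sites)
  counts["parental_filter"] <- nrow(sites)
  sites <- filter_min_depth(sites, config$min_depth)
  counts["depth_filter"] <- nrow(sites)
  if (nrow(sites) == 0) {
    warn("no sites left after filtering; empty scan")
    empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                    source = character(), peak_delta = numeric(),
                    n_windows = integer(), length = numeric())
    return(structure(list(records = sites, windows = sites, regions = empty,
                          counts = counts, params = config),
                     class = "bsa_scan"))
  }
  records <- compute_indices(sites)
  records <- filter_low_index(records, config$low_index)
  counts["low_index_filter"] <- nrow(records)

  pool_sizes <- c(config$pool_normal, config$pool_abnormal)
  scan_class <- function(cls) {
    r <- records[records$variant_class == cls, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    w <- sliding_windows(r, chrom_lengths, config$window_size, config$step)
    if (method == "ci") {
      thr <- window_thresholds(w, pool_sizes, level = config$level,
                               n_sim = config$n_sim,
                               low_index = config$low_index)
    } else {
      d <- w$delta[!is.na(w$delta)]
      thr <- rep(median(d) + sd(d), nrow(w))
    }
    w$threshold <- thr
    w$call <- !is.na(w$delta) & !is.na(thr) & w$delta > thr
    w$variant_class <- cls
    list(windows = w,
         regions = call_regions(w, threshold = thr, method = "ci", source = cls))
  }
  snp <- scan_class("SNP"); ind <- scan_class("InDel")
  windows <- bind_rows(if (!is.null(snp)) snp$windows,
                       if (!is.null(ind)) ind$windows)
  regions <- bind_rows(if (!is.null(snp)) snp$regions,
                       if (!is.null(ind)) ind$regions)
  if (!is.null(snp) && !is.null(ind)) {
    regions <- bind_rows(regions,
                         intersect_regions(snp$regions, ind$regions))
  }
  scan <- structure(list(records = records, windows = windows,
                         regions = regions, counts = counts, params = config),
                    class = "bsa_scan")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(records, file.path(outdir, "site_indices.tsv"))
    readr::write_tsv(windows, file.path(outdir, "window_profile.tsv"))
    write_regions_bed(regions, file.path(outdir, "regions.bed"))
  }
  scan
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("<bsa_scan> ", paste(names(x$counts), x$counts, sep = "=", collapse = " -> "),
      "\n", sep = "")
  n_over <- sum(x$regions$source == "overlap")
  cat("  regions: ", nrow(x$regions), " (", n_over, " overlap)\n", sep = "")
  invisible(x)
}

#' Run fine mapping on a marker-genotype matrix
#'
#' Thin orchestration over [infer_locus_interval()]: accepts a genotype
#' matrix (tibble or TSV path) and a marker panel (tibble or TSV path) and
#' returns the inferred `locus_interval`, optionally writing a report TSV.
#'
#' @param genotypes Marker-genotype tibble or TSV path.
#' @param markers Marker panel tibble or TSV path (default: bundled A10
#'   panel).
#' @param outdir Optional output directory for `locus_interval.tsv`.
#' @return A `locus_interval`.
#' @export
run_fine_mapping <- function(genotypes, markers = a10_marker_panel(),
                             outdir = NULL) {
  if (is.character(genotypes)) genotypes <- read_genotypes_tsv(genotypes)
  if (is.character(markers)) markers <- read_marker_panel(markers)
  interval <- infer_locus_interval(genotypes, markers)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(as_tibble(interval), file.path(outdir, "locus_interval.tsv"))
  }
  interval
}
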