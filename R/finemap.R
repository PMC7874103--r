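#' Individuals recombinant between two flanking markers
#'
#' An individual is recombinant in the bracket if its genotypes at the two
#' flanks differ (both non-missing), i.e. it carries at least one crossover
#' between them.
#'
#' @param matrix Marker-genotype tibble (`id`, `phenotype`, one column per
#'   marker with values in `{M, H, P}` or `NA`).
#' @param flank_pair Character vector of two marker names present in the
#'   matrix.
#' @return Character vector of individual ids.
#' @export
find_recombinants <- function(matrix, flank_pair) {
  if (!all(flank_pair %in% names(matrix))) {
    abort(paste0("unknown marker name(s): ",
                 paste(setdiff(flank_pair, names(matrix)), collapse = ", ")))
  }
  g1 <- matrix[[flank_pair[1]]]; g2 <- matrix[[flank_pair[2]]]
  matrix$id[!is.na(g1) & !is.na(g2) & g1 != g2]
}

# per-individual excluded marker runs under dominant-M trait logic:
# a normal (bb) individual excludes markers where it is M or H; an abnormal
# individual excludes markers where it is P; a run of consecutive excluded
# markers excludes the closed interval spanning them (the flanking gaps stay
# admissible because the crossover could sit anywhere inside them).
excluded_runs <- function(genos, phenotype, positions, mut = "M") {
  wt <- if (mut == "M") "P" else "M"
  excl <- if (phenotype == "normal") !is.na(genos) & genos %in% c(mut, "H")
  else !is.na(genos) & genos == wt
  if (!any(excl)) return(NULL)
  r <- rle(excl)
  stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1
  keep <- which(r$values)
  tibble(from = starts[keep], to = stops[keep],
         start = positions[starts[keep]], end = positions[stops[keep]])
}

#' Infer the locus interval from recombinant genotypes and phenotypes
#'
#' Constraint propagation for a dominant mutant-parent allele: every
#' individual excludes the marker positions incompatible with its phenotype
#' (see Details), the exclusions are unioned across individuals, and the
#' admissible locus region is what remains between the outermost markers.
#' Each admissible run is reported by its flanking markers — the nearest
#' excluded markers on each side (panel-edge markers when unconstrained).
#' With error-free data the true locus always lies inside. When exclusions
#' leave several disjoint admissible runs, all are reported and the result
#' is flagged ambiguous; when they leave none, an error signals a
#' genotype/phenotype inconsistency.
#'
#' @details A normal individual must be homozygous for the normal allele at
#' the locus, so any marker where it is `M` or `H` is excluded; an abnormal
#' individual carries at least one mutant allele, so any marker where it is
#' `P` is excluded. Missing genotypes impose no constraint. A run of
#' consecutive excluded markers excludes the closed interval spanning them;
#' the gaps flanking a run remain admissible (the informative crossover may
#' lie anywhere inside the gap).
#'
#' @param matrix Marker-genotype tibble (`id`, `phenotype`, marker columns).
#' @param markers Marker panel tibble (`name`, `pos`), ordered by position;
#'   only panel markers present in the matrix are used.
#' @param dominance Which parental allele is the dominant trait allele:
#'   `"M"` (default) or `"P"`. Relabeling every genotype M<->P while
#'   flipping `dominance` leaves the inferred interval unchanged.
#' @return An object of class `locus_interval`: a tibble of admissible
#'   intervals with columns `left_marker`, `right_marker`, `left_pos`,
#'   `right_pos`, `span` (= right - left bp), `left_support`,
#'   `right_support` (individuals whose exclusions cover each flank), with
#'   attributes `ambiguous` and `n_individuals`.
#' @export
infer_locus_interval <- function(matrix, markers, dominance = c("M", "P")) {
  dominance <- match.arg(dominance)
  markers <- as_tibble(markers)
  markers <- markers[markers$name %in% names(matrix), , drop = FALSE]
  markers <- arrange(markers, .data$pos)
  m <- nrow(markers)
  if (m < 2) abort("need at least two panel markers present in the matrix")
  if (nrow(matrix) == 0) abort("empty genotype matrix")
  geno <- as.matrix(matrix[, markers$name, drop = FALSE])

  excluded <- rep(FALSE, m)                 # marker-position exclusions
  gap_excluded <- rep(FALSE, m - 1)         # gap i = (marker i, marker i+1)
  support <- rep(0L, m)
  for (i in seq_len(nrow(matrix))) {
    runs <- excluded_runs(geno[i, ], matrix$phenotype[i], markers$pos,
                          mut = dominance)
    if (is.null(runs)) next
    for (j in seq_len(nrow(runs))) {
      idx <- runs$from[j]:runs$to[j]
      excluded[idx] <- TRUE
      support[idx] <- support[idx] + 1L
      if (runs$to[j] > runs$from[j]) {
        gap_excluded[runs$from[j]:(runs$to[j] - 1)] <- TRUE
      }
    }
  }

  # admissible elements along the panel: markers and the gaps between them
  # element order: m1, gap1, m2, gap2, ..., m_m
  adm <- logical(2 * m - 1)
  adm[seq(1, 2 * m - 1, by = 2)] <- !excluded
  adm[seq(2, 2 * m - 2, by = 2)] <- !gap_excluded
  if (!any(adm)) {
    abort("contradictory constraints: no admissible interval (genotype or phenotype error?)")
  }
  r <- rle(adm)
  stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1
  runs <- which(r$values)
  iv <- lapply(runs, function(j) {
    # flanking markers: nearest excluded marker outside the run (panel edge
    # marker if the run reaches the edge)
    # an excluded gap implies both adjacent markers excluded, so admissible
    # runs start/end on gap elements unless they reach the panel edge
    left_el <- starts[j]; right_el <- stops[j]
    li <- if (left_el == 1L) 1L else left_el %/% 2L
    ri <- if (right_el == 2L * m - 1L) m else right_el %/% 2L + 1L
    tibble(left_marker = markers$name[li], right_marker = markers$name[ri],
           left_pos = markers$pos[li], right_pos = markers$pos[ri],
           span = markers$pos[ri] - markers$pos[li],
           left_support = support[li], right_support = support[ri])
  })
  res <- bind_rows(iv)
  structure(res, class = c("locus_interval", class(res)),
            ambiguous = nrow(res) > 1, n_individuals = nrow(matrix))
}

#' Physical span of a locus interval
#'
#' @param interval A `locus_interval` (or any tibble with `left_pos`,
#'   `right_pos`).
#' @return Numeric span(s) in bp, `right_pos - left_pos`.
#' @export
#' @examples
#' interval_span(tibble::tibble(left_pos = 21326670, right_pos = 21361732))
interval_span <- function(interval) {
  if (any(interval$left_pos >= interval$right_pos)) {
    abort("interval must have left_pos < right_pos")
  }
  interval$right_pos - interval$left_pos
}

#' @export
print.locus_interval <- function(x, ...) {
  cat("<locus_interval> from", attr(x, "n_individuals"), "individuals",
      if (isTRUE(attr(x, "ambiguous"))) "(ambiguous: multiple admissible runs)",
      "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s (%s bp) .. %s (%s bp): span %s bp\n",
                x$left_marker[i], format(x$left_pos[i], big.mark = ","),
                x$right_marker[i], format(x$right_pos[i], big.mark = ","),
                format(x$span[i], big.mark = ",")))
  }
  invisible(x)
}
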