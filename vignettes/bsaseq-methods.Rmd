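---
title: "Mapping a dominant locus from pooled resequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant locus from pooled resequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaseq)
```

# The mapping problem

bsaseq implements bulked-segregant association mapping from pooled
whole-genome resequencing (QTL-seq / BSA-seq) for a dominant locus
segregating in a single selfed family, followed by recombinant-marker fine
mapping. The motivating design is an F2:3 family in an allotetraploid crop:
a mutant line (call its genome contribution *M*) carrying a dominant
trait allele is crossed to a normal line (*P*), and one F2 plant —
heterozygous at the causal locus B, with the second required locus A fixed
homozygous dominant ("AABb") — is selfed. Its progeny segregate
abnormal:normal = 3:1, and two phenotypic bulks (about 20 plants each) are
resequenced together with the parents.

At every site where the parents are homozygous for different alleles, the
**SNP-index** of a pool is the fraction of its reads carrying the M allele,

$$\mathrm{index}_k = \frac{D^M_k}{D^M_k + D^P_k},$$

and the association statistic is the between-pool difference
$\Delta = \mathrm{index}_{\text{abnormal}} - \mathrm{index}_{\text{normal}}$.
Genome-wide, $\Delta$ fluctuates around 0; near the selected locus the
abnormal pool is enriched for M (expected index 2/3 at the locus itself,
because surviving abnormal genotypes are BB:Bb = 1:2) while the normal pool
is fixed for P (index 0), so $\Delta \to 2/3$. InDels are processed through
the identical machinery, and a region is only reported when the SNP-based
and InDel-based calls agree (their intersection).

# Pipeline and parameters

`run_association()` chains the stages; each is exported on its own.

1. **Parental filter** (`filter_parental_homozygous_divergent()`): keep
   sites homozygous in both parents for different alleles — the only sites
   at which pooled allele counts are informative about parental origin.
2. **Depth filter** (`filter_min_depth()`, default 7): a site must reach
   total depth 7 in *each* pool. The per-pool reading is the stricter of
   the two interpretations of a bare "depth < 7" rule and is the
   conventional one in QTL-seq practice; the spec of the depth rule never
   says whether it applies per pool or to the sum, so this is an explicit
   design choice.
3. **Indices** (`compute_indices()`): per-site per-pool index and
   $\Delta$. Zero total depth is an error by contract — such sites must be
   removed by the depth filter, not silently NA'd.
4. **Low-index filter** (`filter_low_index()`, default 0.3): drop sites
   whose index is below 0.3 in *both* pools (no signal in either
   direction; typically repeat-collapsed or spurious calls). Applied
   per-site, before windowing — the conventional order.
5. **Sliding windows** (`sliding_windows()`, default 1 Mb window, 10 kb
   step): window values are arithmetic means of member-site values; empty
   windows are `NA`, never 0, and `NA` windows break region runs.
6. **Null threshold** (`simulate_null_threshold()`,
   `window_thresholds()`): Monte-Carlo, see below. Confidence level 0.95.
7. **Region calling** (`call_regions()`): maximal runs of consecutive
   windows with mean $\Delta$ above threshold. The default tests the
   positive side — the side selection for the M allele pushes — with
   `use_abs` available. A `median_sd` fallback thresholds at
   `median(delta) + k * sd(delta)` (`k` is exposed rather than guessed,
   since the prose this rule descends from is ambiguous about the
   multiplier and the centre).
8. **Intersection** (`intersect_regions()`): pairwise SNP x InDel interval
   intersections, reported as `source = "overlap"`.

Region length follows the `end - start` convention: the published interval
endpoints 21,326,670 and 21,361,732 reproduce the reported "35.1 kb" only
under subtraction without the +1, and the package adopts that convention
everywhere (`region_length()`, `interval_span()`).

# The Monte-Carlo null model

The null question is: how large can a *window's* mean $\Delta$ get at a
founder-heterozygous site unlinked to any selected locus? Two noise
sources matter:

* **Pool composition.** Each pool member is an independent selfing
  product, so a pool of $n$ plants carries
  $\mathrm{Binom}(2n, \tfrac12)$ M chromosomes (the 1:2:1 genotype null).
  This component is *shared* by all sites in a window — within 1 Mb
  (about 4 cM here) the members' parental origins barely recombine.
* **Read sampling.** Given the pool frequency $f$, each site contributes
  $\mathrm{Binom}(d, f)$ M reads independently; over $m$ member sites the
  window mean index is $\mathrm{Binom}(m d, f) / (m d)$.

A per-site null (pool draw + one site's read noise) is therefore *not* the
null of the window statistic: averaging shrinks read noise but leaves the
shared pool-composition noise untouched. bsaseq simulates the window mean
directly — one pool-frequency draw per pool, then aggregated binomial read
noise over the window's representative site count at its representative
depth (the member median; robust and cheap) — and takes the `level`
quantile of $|\Delta|$. Thresholds are computed per window and cached over
unique (depth, site-count) combinations. The per-site low-index rule is
applied to the simulated indices (replicates with both below 0.3 are
dropped); at null $f \approx 0.5$ and depth $\ge 7$ it almost never fires.
A pure $f = 0.5$ read-only null (`null = "binom"`) is available for pools
drawn from material without family structure.

With this construction, $|\Delta|$ exceeds its 95% threshold on about 5%
of null windows, which the test suite verifies on simulations with the
phenotype-genotype link broken. Two caveats: calls on neighbouring windows
are strongly correlated (one pool-frequency excursion spans many
overlapping windows), so per-replicate flagged fractions are dispersed and
only the average is calibrated; and on a chromosome that *does* carry the
selected locus, elevated $\Delta$ far from the peak is genuine linkage
signal, not miscalibration — with a single simulated chromosome of
~106 cM everything is partially linked, and called regions are
correspondingly broad.

# The synthetic family generator

`run_simulation()` (and the underlying `simulate_*` functions) generates
data with exactly the statistical structure the analysis assumes:

* **Meiosis**: crossover counts per chromosome are Poisson with mean equal
  to the genetic length in Morgans; positions uniform — the Haldane model,
  no interference. The simplest standard model; nothing in the design
  requires interference.
* **Family**: `n` progeny of a selfed founder that is heterozygous M/P
  along the whole simulated chromosome. Only the causal-locus chromosome
  is simulated (default one 26.6 Mbp "A10"-like chromosome at 4 cM/Mbp);
  the second trait locus A is carried as a fixed allele dose because the
  family design fixes it homozygous. The trait model defaults to
  `REQUIRE_BOTH` (complementary dominant epistasis) — the only two-locus
  model under which an AABb founder yields 3:1 — with `EITHER` and
  `B_ONLY` available for exploration. A cited prior analysis of the
  original mutant could be read as implying duplicate dominant action
  (15:1 in an unstructured F2), which contradicts the 3:1 deduction under
  `EITHER`; the generator follows the 3:1 logic of the family actually
  sampled.
* **Pools**: uniform sampling without replacement within phenotype
  classes; defaults 20 normal / 19 abnormal.
* **Depths**: per-site per-pool totals Poisson (defaults 27.6x for pools
  and 15.8x for parents, the depths the analysis is tuned for);
  M-allele reads binomial at the pool's true M frequency perturbed by a
  symmetric read error rate (default 0.001). Each site's M allele is
  randomly assigned to REF or ALT so the VCF orientation logic is
  exercised.
* **Sites**: positions uniform, default 25% InDels with anchored VCF-style
  alleles. By default the founder is heterozygous at every emitted site
  (they all ride the same F1-derived chromosome); homozygous tracts can be
  emulated by placing sites on a second, unlinked chromosome.

What the generator does *not* emulate: read-level artifacts (mapping
error, duplicates, base-quality structure), multi-chromosome backgrounds,
segregation distortion, genotyping batch effects, and reference bias.
Passing tests therefore demonstrate the statistical machinery is correct
under the stated model, not that any particular real dataset is clean.

# Variant-effect classification

`classify_variant_effect()` re-implements the familiar annotation category
scheme (the package never shells out to an annotation tool): per-gene
precedence **exonic > splicing > intronic > upstream/downstream >
intergenic**, most severe gene wins when genes overlap, and a variant
within 1 kb of one gene's end and 1 kb of another's start receives the
joint `upstream/downstream` category. The windows are the standard ones —
1 kb for upstream/downstream, 2 bp inside each intron end for splicing.

Coding subtypes: SNPs are translated before/after through the standard
genetic code (`synonymous`, `non-synonymous`, `stopgain`, `stoploss`);
InDels are split by `length %% 3` into frameshift and non-frameshift
insertion/deletion, with in-frame indels re-translated to detect
`stopgain`/`stoploss`. An InDel touching an exon/intron boundary stays
exonic (severity precedence) and is typed by length alone — the in-frame
rebuild is only well defined when the allele lies in one CDS interval.
`summarize_effects()` tabulates the categories and the transition /
transversion ratio (ts = A&harr;G plus C&harr;T; `NA` when there are no
transversions).

The test suite checks the classifier against a brute-force oracle that
annotates every base of a toy chromosome, rebuilds the whole mutant
sequence, re-splices and re-translates with its own codon table — 100%
agreement on 1000 random variants, plus strand-mirror invariance.

# Fine mapping

`infer_locus_interval()` performs dominant-trait constraint propagation on
a marker-genotype matrix (individuals x ordered markers, cells M/H/P):
a normal plant must be homozygous wild-type at the locus, so markers where
it is M or H are excluded; an abnormal plant carries at least one mutant
allele, so markers where it is P are excluded; missing cells impose no
constraint. A run of consecutive excluded markers excludes the interval
spanning them, but the gaps flanking a run stay admissible — the
informative crossover can sit anywhere inside a gap. Exclusions are
unioned across individuals; the admissible remainder is reported by its
flanking markers. Multiple disjoint admissible runs are all reported and
flagged ambiguous; an empty admissible set raises an error (it implies a
genotyping or phenotyping mistake). On error-free data the true locus is
always inside the interval, and adding individuals can only shrink it —
both properties are tested on simulated families with known crossovers.
Relabeling M&harr;P while flipping the `dominance` argument leaves the
interval unchanged.

# Numerical and interface choices

* Coordinates are 1-based inclusive in memory and in every TSV; BED output
  converts to 0-based half-open at the boundary.
* All index/delta values are exact double ratios of integer depths; window
  means are cumulative-sum based and tested against brute-force
  recomputation.
* Every random stage consumes the ordinary R RNG, so a single
  `set.seed()` (or the `seed` field of `bsa_config()`) makes simulated
  tables, thresholds and region calls bit-identical.
* Thresholds with fewer than 1000 Monte-Carlo replicates are refused.

# Problem sizes used in the tests

The suite exercises the study conditions at desk scale: association-scan
replicates use 1,200-1,500 segregating sites on the 26.6 Mbp chromosome
(one site per ~18 kb; enough for ~50 SNP sites per 1 Mb window) and
families of 150-200 plants; recovery is measured over 100 seeded
replicates and null calibration over 40. Fine-mapping convergence uses a
6,000-plant family, the scale of a real recombinant screen. These sizes
were chosen so each property is measured with useful Monte-Carlo precision
while the whole suite stays comfortably interactive.
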