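---
title: "Tracing the source of insect incursions from genome-wide SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the source of insect incursions from genome-wide SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incursr)
```

## The problem

Invasive insects intercepted at ports and airports ("incursives") carry no
label saying where they came from. When reference collections from the
species' known range are genotyped at thousands of genome-wide SNPs, each
incursive can be assigned to its most likely source population by
comparing its multilocus genotype with the references. `incursr`
implements that workflow end to end for biallelic SNP dosage data: QC of
the reference panel, delineation of distinguishable reference
populations, dual-method individual assignment, a combined confidence
classification, and classification of pyrethroid-resistance genotypes at
the voltage-sensitive sodium channel (*Vssc*) gene, whose *kdr* point
mutations are themselves informative about origin (and about whether
insecticide-based disinsection can be expected to work).

All downstream analyses operate on a `geno_matrix`: individuals × loci
alt-allele dosages in {0, 1, 2, NA} with physical locus coordinates, plus
a `sample_panel` splitting individuals into labelled reference samples
and unlabelled incursives.

## The synthetic-data generator

Real data of this kind comes from RADseq genotyping of field
collections. So that every stage is testable without sequencing data,
`simulate_panel()` generates structured panels under the
Balding–Nichols model: for a locus with ancestral frequency $p$, each
daughter population's frequency is drawn from

$$p_k \sim \mathrm{Beta}\!\left(p\,\tfrac{1-F}{F},\;
  (1-p)\,\tfrac{1-F}{F}\right),$$

and genotypes are $\mathrm{Binomial}(2, p_k)$ draws, i.e.
Hardy–Weinberg holds within populations and $F$ is (approximately) the
inter-population $F_{ST}$. We chose this model over coalescent
simulation because it directly parameterises the one quantity the
assignment methods exploit — differentiation — and is exactly checkable:
the suite verifies a Weir–Cockerham estimate of $F_{ST} \in [0.08,
0.12]$ for panels simulated at $F = 0.1$.

Generator defaults are the study conditions the package is tested
under: 18 diploid individuals per reference sample, ancestral
frequencies uniform on [0.1, 0.5] (keeping the post-filter MAF spectrum
realistic), loci every 50 kbp on three synthetic chromosomes (so the
250-kbp thinning filter has real work), heterogeneous per-individual
missingness, incursives drawn from a named source population's
frequencies, parent–offspring pairs built by allele-level inheritance
(one allele copy from the parent, one from the population pool, so the
pair's expected Loiselle kinship is 0.25), and three-locus *Vssc*
genotype strings drawn from per-population class frequencies.
`simulate_study_panel()` mirrors the scale of the motivating study: 13
populations × 18 individuals at $F = 0.1$, with 11,000 simulated loci
chosen so that roughly 2,000 SNPs survive the full QC chain (call
rate/MAF pass ≈ 97%, per-population HWE ≈ 76%, 250-kbp thinning on a
50-kbp grid ≈ 20%).

What the generator does **not** emulate: linkage disequilibrium beyond
physical spacing, selection, allele dropout or genotyping error
structure, isolation-by-distance within populations, and — importantly —
*unsampled* source populations. Passing tests therefore demonstrate the
machinery is correct under its own assumptions, not that any particular
real panel is adequate for assignment.

## The QC chain

`qc_reference()` applies, in order (each step logged with before/after
counts):

1. **Call rate and MAF** (`filter_loci()`): a locus is kept iff called
   in ≥ 75% of the individuals of *every* group (boundary inclusive)
   and its overall minor allele frequency is ≥ 0.05.
2. **Hardy–Weinberg** (`hwe_filter()`): the exact test on genotype
   counts; a locus is removed when rejected at α = 0.05 within any
   reference sample. The per-sample default (with a pooled mode
   available) avoids confusing the Wahlund effect with genotyping
   artefacts; no multiple-testing correction is applied, which is the
   aggressive-but-conventional per-locus reading. Configurable via
   `filter_config(hwe_alpha=, hwe_mode=)`.
3. **Physical thinning** (`thin_by_distance()`): greedy left-to-right
   walk per chromosome keeping the first locus and dropping any locus
   closer than 250 kbp to the last kept one. Keeping the leftmost
   rather than the highest-MAF SNP is deterministic and matches the
   simplest reading of "thinning".
4. **Individual missingness** (`filter_individuals_missing()`):
   reference individuals with ≥ 30% missing genotypes are removed
   (exactly 30% is out).
5. **Kinship pruning** (`loiselle_kinship()` + `prune_related()`):
   pairs with Loiselle kinship ≥ 0.1875 (halfway between first- and
   second-degree expectations) are treated as putative first-degree
   relatives; the member with more missing data is removed iteratively
   (ties: more flagged pairs, then the lexicographically later id)
   until no flagged pair remains.
6. **Capping** (`cap_population()`): samples larger than 18 are
   trimmed by missingness (ties: drop the lexicographically later id),
   normalising reference sample sizes.

The Loiselle estimator uses half-dosages $x_{il} \in \{0, \frac12, 1\}$
and sample reference-allele frequencies $p_l$ computed from the
individuals passed in (the reference sample, not the global panel):

$$k_{ij} = \frac{\sum_l \left[(x_{il}-p_l)(x_{jl}-p_l) +
  \frac{p_l(1-p_l)}{2n_l-1}\right]}{\sum_l p_l(1-p_l)},$$

summing numerators and denominators over loci before dividing. The
small-sample bias term counts the $2n_l$ *allele copies* sampled at
locus $l$; with the correction written over individuals instead, every
unrelated pair inherits a spurious $+\tfrac{1}{2(n-1)}$ offset (≈ 0.06
at $n = 10$), which breaks both the ≈ 0 expectation for unrelated pairs
and the ≈ 0.25 expectation for parent–offspring. Pairs with no jointly
typed loci are reported as `NA`, never silently 0. Monomorphic loci are
excluded from both sums.

The exact HWE test conditions on observed allele counts and sums the
probabilities of all heterozygote counts whose configuration is no more
probable than the observed one, computed by the numerically stable
ratio recurrence. The suite checks it against an independent
log-factorial enumeration for every genotype triple with $n \le 50$ at
tolerance 1e-12.

## Delineating reference populations

Reference samples that cannot be told apart (time-replicated
collections from one city, adjacent cities with weak structure) must be
merged before assignment, or the classifier will split their posterior
mass arbitrarily. `mc_cross_validate()` repeatedly holds out a
proportion (defaults 0.1, 0.2, 0.3; `ceiling(p·n)` individuals each, so
someone is always tested) of every sample, trains the assignment model
on the rest, and accumulates confusion counts; misassignment is
aggregated over all proportions and replicates.
`build_merge_plan()` flags any pair whose cross-misassignment rate
reaches `merge_rate` in either direction and merges connected
components of the flagged-pair graph into composites (labels
concatenated with `+`); `apply_merge()` relabels and re-caps composites
at 18 by missingness. The default `merge_rate = 0.05` sits below the
7–10% cross-assignment at which such samples are conventionally
merged, while samples with perfect self-assignment stay separate; the
threshold is a package decision (the underlying criterion is
qualitative) and is printed prominently with every plan. The default
200 replicates per proportion follow the field's convention; at
two-sample desk scale the merge decision stabilises far earlier, so the
test suite and the acceptance script run 15 replicates per proportion.

## Cluster-detection assignment across a K range

Assignment route one is PCA + k-means cluster detection. `fit_pca()`
centers dosages per locus (no scaling by default — a flag exists — since
dosage variances are already comparable), imputes missing calls with
per-locus mean dosage, and decomposes by SVD; incursives are imputed
and centered with the *reference* means and projected, so a fully
missing individual lands at the origin (maximally uninformative) rather
than anywhere biased.

`kscan()` runs best-of-`n_start` k-means for each $K$ and scores

$$\mathrm{BIC}(K) = n\ln(\mathrm{WSS}_K/n) + K\ln n, \qquad
  \mathrm{AIC}(K) = n\ln(\mathrm{WSS}_K/n) + 2K,$$

the spherical-cluster forms used by PCA-based cluster detection in
population genetics. The assignment range runs from the BIC argmin
(conservative) to the AIC argmin (liberal); since $\ln n > 2$ for any
realistic panel the AIC argmin is at or above the BIC argmin, and the
degenerate reversal, undefined in the source methodology, is handled by
spanning the two argmins with a warning. WSS is forced non-increasing
across $K$ (`cummin`) so a poorly converged restart can never make a
coarser solution look better than a finer one. We run k-means to
convergence (tolerance of the underlying Hartigan–Wong implementation,
iteration cap 10,000, default 50 restarts for scans and 10 inside
per-incursive loops) rather than any fixed astronomically large
iteration budget: the fixed points are identical and the runtime is
tractable.

`assign_by_clusters()` reproduces the leave-one-in design: the
references plus a *single* incursive are decomposed and partitioned at
each $K$ in the range; the incursive's assignment at $K$ is the set of
reference populations sharing its cluster, and at the top of the range
(the number of populations, where each population should sit in its own
cluster) the majority population of its cluster — or `NA`
("unresolved") when it sits alone or the majority ties, never an
arbitrary population. `consistency_across_k()` is true iff the final
single-population assignment is contained in the cluster-mate set at
every smaller $K$ (a length-1 range is trivially consistent; an
unresolved final is never consistent). The pipeline computes the K
range once from the reference panel — the design the range is reported
for — rather than once per leave-one-in subset; on well-separated
panels the reference cluster structure is unchanged by any single
incursive (tested), so the shared range is the same.

`regional_refinement()` re-filters loci on a regional subset of
populations (fewer per-group call-rate constraints, so more SNPs
survive) and repeats cluster assignment there, mirroring the two-stage
global-then-regional design that raises confidence among closely
related populations.

## SVM assignment with calibrated posteriors

Route two (`assign_train()` / `assign_posteriors()`) fits PCA on the
references only, retains components by the Kaiser rule (covariance
eigenvalue > 1 — note the eigenvalue scale of centered dosage data
grows with locus count, so "1" is a lenient bar at thousands of loci),
and trains a linear soft-margin SVM (`e1071::svm`) with pairwise
sigmoid probability calibration on the retained scores. Calibration
uses internal cross-validation, so the trainer seeds the RNG:
retraining under the same seed reproduces probabilities to 1e-12.
Calibrated posteriors are never exactly 0 or 1. The
**relative probability** is the top posterior divided by the
second-best (ties give 1; a zero second-best yields `Inf` with a
message), and the conventional confidence threshold is a *strict*
`> 2`. A population with a single individual makes calibration
impossible and is rejected by name.

## Confidence classification and diagnostics

`classify_confidence()` labels an incursive `WELL_ASSIGNED` iff (i) its
cluster assignment is consistent across the whole K range, (ii) the
final-K cluster assignment equals the posterior argmax, and (iii) the
relative probability strictly exceeds 2; otherwise `POORLY_ASSIGNED`
with the failed criteria listed. After regional refinement the regional
posterior is reported, but criterion (ii) is still judged at the global
level. `missingness_regression()` fits OLS of the top posterior on the
missing-data fraction within each confidence group: a strong negative
slope among the well-assigned says their weaker posteriors are a
missing-data artefact; low-posterior *low*-missingness incursives are
the signature of unsampled source populations, which this package flags
but deliberately does not model.

## Resistance genotypes

`parse_vssc()` validates three-locus genotype strings
(V1016G / F1534C / S989P, e.g. `"GG/TT/CC"`; wild/mutant bases T/G,
T/G, T/C). `classify_resistance()` applies the default rule table:
homozygous-mutant 1016 → strong Type I + II resistance (hom-mutant 989
is a Type-II synergist with no solo effect); hom-mutant 1534 with
wild-type 1016 → strong Type I; all wild-type → susceptible; every
heterozygous combination → intermediate/unknown, since heterozygote
phenotypes vary — the rule table is exposed so users can refine them.
The aggregate "strong Type I" flag is hom-mutant at 1016 *or* 1534.
`incursive_status()` implements the definition rule: an individual is
incursive iff collected outside the endemic region, or inside it while
carrying a resistance allele absent from local populations.

## Numerical choices and degenerate inputs

* Posterior vectors must sum to 1 ± 1e-9 (asserted in tests);
  Vssc class frequencies must sum to 1 ± 1e-6.
* All tie-breaks (pruning, capping, cluster majority) are deterministic
  and documented above; cluster labels themselves are arbitrary and all
  outputs are label-invariant.
* Empty inputs return empty outputs (`thin_by_distance`,
  `summarize_assignments`); zero-locus matrices, all-missing loci,
  all-missing individuals, single-individual populations and
  single-population regions raise informative errors.
* Every stochastic step (simulation, holdout, k-means restarts, SVM
  calibration) flows from explicit seeds; no hidden global state.

## Problem sizes in the shipped checks

The test suite exercises the study-mirror condition (13 × 18
references, ~2,000 post-filter SNPs, 50 incursives) over 20 seeds for
end-to-end recovery, 20 seeds of two-sample merge/no-merge delineation,
parent–offspring kinship at 5,000 loci, the exhaustive HWE sweep to
n = 50, and the missingness-response design (10 incursives × 6 nested
missingness levels, 0–0.5). The acceptance script runs one full
study-mirror trace with heterogeneous incursive missingness (0–40%)
plus the delineation and kinship checks. These sizes are the package's
own desk-scale choices; the methods scale to real panels (hundreds of
individuals, tens of thousands of SNPs) without modification.

## Known limitations

* Assignment is closed-world: an incursive from an unsampled source is
  forced onto the sampled populations, flagged only indirectly by low
  posterior and low missingness.
* The Balding–Nichols generator cannot probe robustness to LD,
  genotyping error or within-population structure.
* The WSS-based BIC/AIC forms assume spherical clusters in PC space;
  strongly elongated population clouds can shift the K range.
* Probability calibration with few individuals per population yields
  posteriors well inside (0, 1); relative probabilities are the more
  stable confidence signal at n = 18.
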