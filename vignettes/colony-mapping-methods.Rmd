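---
title: "Mapping a recessive trait in a closed colony: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive trait in a closed colony: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonymap)
```

`colonymap` implements the desk-side analysis that localizes a fully
penetrant autosomal recessive trait segregating in a closed breeding colony
to a single causal variant, and then validates that variant at the
expression level. This vignette explains each model, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic colony generator does and does not emulate.

## The mapping problem

A closed colony of about 123 cats segregates a recessive
neurodevelopmental trait (25 affected animals). With whole-genome and
RNA-seq genotypes for a handful of affected animals and obligate carriers,
the localization strategy is:

1. **Zygosity filtering** — keep variants homozygous for the alternate
   allele in every called affected animal and heterozygous in every called
   obligate carrier.
2. **Cluster testing** — ask whether passing variants pile up in one
   genomic window rather than scattering genome-wide.
3. **Parametric linkage** — confirm cosegregation with exact two-point LOD
   scores under a rare recessive model.
4. **Haplotype fine-mapping** — reconstruct diplotypes, find the run of
   markers over which all affected animals are homozygous for the shared
   disease haplotype, and bound it by recombinants.
5. **Prioritization** — rank the interval's variants by consequence,
   population allele frequency, CADD score and tissue expression.
6. **Expression validation** — test for nonsense-mediated decay (NMD) of
   the candidate transcript, allele-specific read loss in heterozygotes,
   differential expression, and cell-type composition shifts.

## The synthetic colony generator

The colony's real genotypes are not publicly available, so every stage is
exercised against a generator (`colony_config()`, `simulate_colony()`)
that reproduces the *statistical structure* the analysis assumes.

**Breeding structure.** Colonies descend from 4 founders. Each breeding
round, one stud male drawn from the whole colony sires all litters
(Poisson litter size, mean 4; overlapping generations; growth stops at 123
animals). The single-stud scheme is what small research colonies actually
do, and it is the design's engine of inbreeding: with random outbred-style
mating, a single-copy founder allele essentially never reaches the dozens of
homozygotes such colonies accumulate. With these defaults, ascertained colonies
carry a median of roughly 15–20 affected animals (range ~8–35), a
distribution that comfortably covers the motivating colony's 25.

**Ascertainment.** Exactly one founder haplotype carries the causal
allele. Whether it drifts to high frequency is stochastic, so colonies are
resimulated until at least 8 affected animals exist (the number of
affected animals the zygosity filter is labeled with). This conditioning
mirrors reality: a colony becomes a mapping study only because affected
animals were observed in it.

**Genome and recombination.** Six autosomes (62–240 Mb, including a
71.5 Mb chromosome carrying the causal locus at 66,768,323 bp) with a
linear 1 cM/Mb map. Meioses follow the Haldane model: crossover counts are
Poisson with mean equal to the map length in Morgans, positions uniform,
no interference — standard, and testable in closed form (the crossover-count
test asserts the Poisson mean to within three standard errors over 10,000
meioses). Variants are placed uniformly at 10 per Mb; this is far sparser
than a real genome but preserves the geometry the window statistics and a
26-marker fine-mapping panel need, at desk scale.

**The disease haplotype.** Sites within 650 kb of the causal position
(1.3 Mb total) carry the alternate allele on the carrier founder haplotype
and are rare (Bernoulli 0.1) on all others, making the segment haplotype
effectively unique; the causal allele itself is private to that haplotype.
Every transmitted allele carries a founder-origin label, so
identity-by-descent can be asserted exactly in tests rather than inferred.

**What is not emulated.** Genotyping error beyond simple per-call dropout,
sex chromosomes, mutation during breeding, selection, variable
recombination rates, linkage disequilibrium between founder haplotypes
beyond the planted segment, and read-level sequencing artifacts. Passing
tests on this generator show the pipeline's logic and statistics are
sound under its assumptions; they do not show robustness to the noise
modes of real sequencing.

## Zygosity filtering and the cluster test

A site passes `zygosity_filter()` iff every *called* affected animal has
dosage 2, every *called* carrier has dosage 1, and at least `min_called`
labeled animals are called (default 11, an "11 of 14" rule tolerating
missing calls in low-coverage regions). A single called violation fails the
site regardless of missingness; carriers must be exactly heterozygous
because obligate carriers of a fully penetrant recessive cannot be
homozygous alternate. Adding a labeled animal can only shrink the passing
set (tested as an invariant).

`cluster_enrichment()` partitions the genome into fixed windows (default
5 Mb, the scale at which such clusters are typically reported), with trailing
windows shorter than half the width merged leftward to avoid
small-expectation cells. Expected counts are uniform per window — matching
a "random genome-wide distribution" null — with a
proportional-to-tested-variants null available for real data where
callable density varies. The statistic is Pearson's X² with
`df = windows − 1` and an upper-tail chi-square p-value; standardized
residuals identify the peak window. The chi-square approximation is
asymptotic: the calibration test exercises it at expected counts of 20 per
window, where the nominal 5% level is held; with expected counts below ~5
the p-value is indicative only (in the pipeline it is the *peak residual*,
not the p-value, that drives the next stage).

## Exact parametric linkage

`two_point_lod()` computes `LOD = log10 L(θ=0) − log10 L(θ=0.5)` per
marker. The likelihood sums, over all phased two-locus genotype
assignments, the product of founder Hardy–Weinberg priors (disease allele
frequency `q`, marker allele frequencies equal by default), per-meiosis
transmission probabilities with recombination fraction θ, penetrance
terms, and marker-observation indicators. The sum is evaluated exactly by
variable elimination on the pedigree's factor graph (one variable per
individual, `(2k)²` phased states for a `k`-allele marker), which handles
the looped pedigrees of closed colonies without loop-breaking
approximations. An explicit state budget turns oversized problems into an
error — never a silent approximation — with per-nuclear-family summed LOD
(`lod_by_families()`) as the documented decomposition for colony-scale
pedigrees.

Defaults: penetrance `(0, 0, 1)` (fully penetrant recessive, no
phenocopies); unknown phenotypes get penetrance 1 for every genotype;
`q = 0.001` ("rare recessive"). At θ=0 the LOD is insensitive to `q` for
within-pedigree data — a test sweeps `q` over two orders of magnitude and
bounds the LOD change by 1e-9.

Correctness rests on a brute-force oracle (`lod_enumeration_oracle()`)
that enumerates founder diplotypes and every transmission outcome
explicitly and must agree with the elimination engine to 1e-9 log10 units
(randomized sweeps over 100+ pedigrees), plus a closed form: for a
phase-unknown carrier×carrier nuclear family with `n` affected children
sharing one fully informative marker genotype, `LOD = (n−1)·log10 4`.

## Diplotypes and the critical interval

`reconstruct_diplotypes()` is deliberately rule-based: homozygotes are
trivially phased; a heterozygous child is phased wherever a parent's
genotype forces the transmitted allele; rules iterate to a fixed point.
Founders' haplotype pairs have no inherent order, so a founder's first
haplotype is anchored per marker to the allele it transmitted to its first
phase-resolved child. Ungenotyped animals with genotyped mates and progeny
are imputed (the transmitted haplotype is the child haplotype not
attributable to the other parent); everything unresolvable stays `NA` —
uncertain, never guessed. Mendelian-inconsistent markers are excluded from
trio rules for that family and reported. Against the simulator's true
haplotypes, every resolved phase must match (tested over multiple seeded
colonies).

`delineate_critical_interval()` finds the maximal run of contiguous
markers at which all affected animals are homozygous for one shared
allele (or, with origin-labeled input, homozygous identical-by-descent for
the labeled disease haplotype), reporting conservative *inner* bounds
(first/last run markers) and recombinant-bounded *outer* bounds (nearest
flanking violations, or chromosome/panel ends). In a heavily inbred colony
other autozygous runs can by chance be as long as the disease-haplotype
run, so the pipeline anchors the choice at the mapping signal: the run
whose outer span contains the most zygosity-passing variants is taken.
This mirrors practice — the interval is delineated around the implicated
locus, not discovered de novo from homozygosity alone. The analysis
delineates on all typed variants in the peak window (every simulated
animal is fully genotyped; the amplicon-style 26 + 4 + 20 panel is still
constructed and used for the LOD table and diplotype display). Both inner
and outer spans are reported because the convention behind a reported
"1.3 Mb" span is rarely stated.

## Prioritization rules

`filter_and_rank()` drops variants at population allele frequency ≥ 5%
(absent = private, reported "Absent", never coerced to numeric zero), then
orders by (1) consequence tier — frameshift and other loss-of-function
above missense above synonymous/noncoding — (2) usable CADD descending,
and (3) tissue expression (CPM ≥ 1) as a tie-break flag, with final
deterministic tie-breaks on coordinates. A CADD score is *unusable* when
the variant is synonymous in the target species but the score derives from
a non-synonymous human liftover (`cadd_consequence_mismatch`), or when the
variant did not lift over; such scores never outrank direct evidence. The
CPM threshold is a flag and tie-break rather than a hard filter so a
low-expression true positive cannot be silently discarded; GERP is
reported but unranked (configurable). Ranking is verified against a
brute-force pairwise-comparator sort on random tables.

`annotate_coding_effect()` classifies variants against a transcript model
(strand-aware, standard codon table via Biostrings): SNVs are translated
codon-by-codon; indels are frameshift iff the CDS length change is not
divisible by 3. `hgvs_codon_index()` is the codon arithmetic
`floor((pos−1)/3)+1` — coding position 176 falls in codon 59.
`hwe_extrapolate()` converts a heterozygote count in a reference cohort to
an expected worldwide homozygote count under Hardy–Weinberg
(`population · (n_het / 2N)²`).

## Expression validation

The NMD model is one parameter: the retention fraction λ, the mutant
allele's transcript output relative to wild type. It implies two
observables: homozygote total-expression reduction `r = 1 − λ` and
heterozygote mutant-read fraction `π = λ/(1+λ)`. The default λ = 0.41
corresponds to the 59% homozygote reduction seen for a decayed frameshift
transcript (π ≈ 0.29). The simulator draws negative-binomial counts
(shared dispersion 0.05, per-gene log-normal baselines) with target-gene
group means `λ·baseline` (homozygous mutant) and `(1+λ)/2·baseline`
(heterozygous), binomial allele-specific reads at 24–3,000 informative
reads per heterozygous animal, and group sizes 4/3/3 — the analyzed
design. Parameter-recovery tests require the mean estimated reduction
within ±5 points of 59% and the mean estimated π within ±0.03 over 50
seeds.

`expression_reduction_test()` and `allele_bias_test()` are one-way ANOVAs
with Tukey post-hoc contrasts, using per-animal values (CPM, or per-animal
mutant-read fractions) as the units of comparison; fractions are
unweighted by depth, with the caveat that depth-weighting is a defensible
alternative the original description does not resolve.

**Differential expression.** The scientific content is the contrast design
— homozygous mutant vs non-mutant, and homozygous mutant vs all unaffected
— and the strict dual-significance intersection (`de_intersection()`:
q < 0.05 in *both* contrasts with concordant effect sign; discordant genes
are reported separately). The per-gene engine (`de_contrast()`) is a
negative-binomial likelihood-ratio test with a common genome-wide
dispersion (Pearson-pooled, approximately unbiased where per-gene moment
estimators are not) and TMM-corrected effective library sizes
(`effective_lib_sizes()`, via edgeR). Two simpler engines were evaluated
and set aside: a per-gene Welch t on log2(CPM+1) (retained as
`engine = "welch"`) has an intrinsic sensitivity ceiling at 3–4 samples
per group because per-gene variance estimates are unstable, and raw
library sizes let strongly shifted genes depress the apparent expression
of everything else (a compositional artifact); a moderated-t alternative
over-rejected on the intersection because the two contrasts share the
mutant samples and moderation compounds the dependence. Full-featured
DE frameworks with per-gene shrinkage are deliberately out of scope; the
common-dispersion LRT is the smallest engine that is both calibrated
(null rejection within the binomial interval; BH-controlled empirical FDR
on planted-truth simulations) and powered for the design.

**Cell-type composition.** `select_celltype_markers()` implements the
reference rule: a gene is a marker of the cell type where its mean is at
least 2-fold (boundary included) above every other type *and* a Welch test
against the runner-up type gives raw p < 0.2 (strict). The generous p
threshold is the deconvolution reference method's own; the two-sample test choice is
ours, since the reference method leaves it unstated. `celltype_shift_test()` then fits,
per cell type, a two-way ANOVA of log2(CPM+1) on genotype group and gene,
reporting the genotype main effect and its direction. Outlier or
immature-animal exclusions are handled as an explicit sample-exclusion
list upstream (reproducible and transparent), not an automated gate.

`brain_weight_contrast()` is the phenotype-level ratio arithmetic: brain
weight per kilogram body weight, percent decrease
`(1 − mean_affected/mean_control)·100`, rounded to the nearest percent for
reporting (4.3 vs 7.8 g/kg gives 44.87 → 45%).

## Numerical and edge-case behavior

* Likelihood-impossible marker configurations at θ=0 yield `LOD = −Inf`,
  flagged, never clamped; Mendelian-inconsistent genotypes at θ=0.5 are an
  error.
* `cluster_enrichment()` with zero passing variants is an explicit error —
  no p-value is fabricated.
* Missing annotation fields are `NA`, never zeros; missing genotype calls
  are `NA` dosages.
* All simulators route randomness through an internal seed guard: the same
  (config, seed) gives byte-identical output, and the caller's RNG state
  is untouched.
* Identical-fraction allele-bias input returns `NA` for the ANOVA p rather
  than a 0/0 floating-point artifact.

## Problem sizes

Defaults were chosen so the whole validation battery runs on one CPU at
desk scale: colonies of 123 animals over a 913 Mb six-chromosome genome at
10 variants/Mb; 100-colony end-to-end recovery sweeps; 100-pedigree LOD
equivalence sweeps with the enumeration oracle capped at 12 meioses;
2,000-replicate null calibrations for scalar tests (500–1,000 for the
two-way ANOVA); 50-seed parameter-recovery runs with 500–2,000 background
genes. These sizes are stated here as the package's validation design.

## Known limitations

* Exact joint linkage likelihoods are limited by the elimination budget;
  colony-scale pedigrees use the summed nuclear-family decomposition,
  which discards cross-family phase information (the summed LOD is
  conservative relative to the joint pedigree likelihood).
* Diplotype reconstruction is rule-based and leaves genuinely ambiguous
  phase unresolved rather than sampling it; it does not perform
  population-style statistical phasing.
* The critical-interval rule assumes the disease haplotype is observable
  as shared homozygosity at typed markers; with sparse panels and a narrow
  identical-by-descent core the interval can be bounded only as tightly as
  marker spacing allows.
* The cluster test's p-value is asymptotic; at very low expected counts
  per window it should be read as a ranking statistic.
* The expression simulator shares one dispersion across genes by default;
  real per-gene dispersion trends (and their interaction with moderated
  tests) are outside its scope.
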