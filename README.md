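# colonymap

Mendelian mapping and validation of recessive traits in closed breeding
colonies.

When a recessive phenotype appears in a small, closed colony — here, a
cerebral dysgenesis segregating among ~123 cats, 25 of them affected — the
route from phenotype to causal variant is a fixed sequence of analyses:

1. **Zygosity mapping.** Keep variants homozygous alt in every called
   affected animal and heterozygous in every called obligate carrier
   (≥ 11 of 14 labeled animals called), then test clustering of passing
   variants in 5 Mb genome windows with Pearson's
   `X² = Σ (obs − exp)²/exp` against a uniform genome-wide null.
2. **Parametric linkage.** Exact two-point
   `LOD = log₁₀ L(θ=0) − log₁₀ L(θ=0.5)` under a rare, fully penetrant
   recessive model (penetrance (0,0,1), disease allele frequency
   q = 0.001), computed by variable elimination over phased two-locus
   genotype states and verified against a brute-force enumeration oracle.
3. **Haplotype fine-mapping.** Rule-based diplotype reconstruction with
   progeny imputation, and delineation of the critical interval — the
   maximal marker run where all affected animals are homozygous for the
   shared disease haplotype — with recombinant-bounded outer limits.
4. **Prioritization.** Rank interval variants by consequence tier
   (frameshift/LoF > missense > silent), usable CADD score, allele
   frequency (< 5%, "Absent" = private) and tissue expression, flagging
   CADD scores inflated by cross-species liftover.
5. **Expression validation.** Nonsense-mediated decay leaves one free
   parameter, the mutant-allele retention λ: homozygote reduction
   `r = 1 − λ` and heterozygote mutant-read fraction `π = λ/(1+λ)`
   (λ = 0.41 → 59% reduction, π ≈ 0.29). Tested by one-way ANOVA on CPM,
   allele-bias ANOVA on per-animal read fractions, a dual-contrast
   FDR-intersection differential-expression list, and two-way ANOVA
   genotype effects on cell-type marker panels.

Because the underlying colony data are not public, the package ships a
gene-drop simulator (`simulate_colony()`) that reproduces the statistical
structure the analysis assumes — a ~123-animal single-stud colony, a causal
allele on one founder haplotype inside a unique 1.3 Mb identical-by-descent
segment, a 26 + 4 + 20 amplicon marker panel, and RNA-seq-style counts with
the NMD structure above — so every stage is testable end to end.

## Worked example

```r
library(colonymap)

cfg <- colony_config(seed = 7)          # ~123 cats, causal at F1:66768323
col <- simulate_colony(cfg)
ped <- col$pedigree
aff <- ped$id[ped$phenotype == "affected"]

zy <- zygosity_filter(col$genotypes, head(aff, 8),
                      head(obligate_carriers(ped), 6), min_called = 11)
ct <- cluster_enrichment(zy$sites[zy$pass_idx, ], cfg$genome,
                         tested = col$genotypes$sites)
print(ct)
#> cluster enrichment: X2 = 2084.07, df = 181, p = 2.49e-320 (15 passing variants, 182 windows)
#> peak window: F1:65000001-71500000 (observed 13, expected 0.08)
```

Fifteen variants survive the filter and thirteen of them sit in one 5 Mb
window at the end of chromosome F1 — the candidate region. Linkage over the
50-marker panel and haplotype fine-mapping then bound the locus:

```r
#> Peak LOD 9.77 at F1:66552401; off-chromosome maximum 2.02.
#> critical interval: F1:65107866-67664566 (inner, 2.56 Mb; outer 65107866-67905116), 23 markers
#> Causal site 66768323 inside the outer interval: TRUE
```

Ranking the packaged candidate table (the coding and high-CADD variants of the
1.3 Mb critical interval) puts the frameshift first, with the two
liftover-inflated CADD scores flagged and excluded from ordering:

```r
an <- read_annotation_table(system.file("extdata/table1_candidates.tsv",
                                        package = "colonymap"))
head(filter_and_rank(an), 3)[, c("rank", "gene", "hgvs_dna", "consequence",
                                 "af_label", "cadd", "cpm")]
#>  rank  gene  hgvs_dna consequence af_label cadd    cpm
#>     1 PEA15 c.176delA  frameshift   Absent 29.7 1075.2
#>     2  CD48  c.695G>A    missense   Absent  6.6    3.2
#>     3   LY9  c.478A>G    missense   Absent  0.0    3.3

hgvs_codon_index(176)        # codon containing coding position 176
#> [1] 59
hwe_extrapolate(11, 198527, 7.7e9)  # expected human homozygotes worldwide
#> [1] 5.909857
```

Expression validation on a simulated cortex bundle (4 homozygous mutant /
3 het / 3 reference animals, λ = 0.41):

```r
#> Target transcript reduction in homozygotes: 61.9% (one-way ANOVA p = 0.0096)
#> Heterozygote mutant-read fraction at the target: 0.289 (controls ~0.5; ANOVA p = 1.4e-07)
#> Brain weight: affected 4.3 vs control 7.8 g/kg -> 45% decrease
```

A single 4/3/3 bundle estimates the reduction noisily (61.9% here against
the generating 59%); averaged over 50 seeds the estimate recovers 59% to
within ±5 points and π to within ±0.03 (asserted in the test suite).

The full narrative is in the numbered drivers under `analysis/`
(`01_simulate_colony.R` … `05_expression_validation.R`), which write their
tables under `results/`; the methods vignette
(`vignettes/colony-mapping-methods.Rmd`) documents the models, defaults and
design choices.

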