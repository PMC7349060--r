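# yieldvar

Selection of high- and stable-yielding crop genotypes from
multi-environment trials, paired with the summarization of a multi-sample
genotyping-by-sequencing (GBS) variant panel. The package targets the
workflow used to characterize heat-resilient tomato landraces: phenotype a
set of genotypes across hot location-year environments, pick the one whose
yield is high *and* environmentally stable, then mine its variant panel
for private markers, protein-disrupting mutations, and chromosome segments
introgressed from wild relatives.

## What it computes

**Stability engine.** For a genotype x environment table of mean yield
per plant `Y_ij`, the environment index is the field-mean deviation

    EI_j = sum_i(Y_ij)/v − sum_ij(Y_ij)/(v·l),  with  sum_j EI_j = 0,

and each genotype's environment means are regressed on EI: slope `b_i`
(b = 1 is average environmental sensitivity), intercept (= pooled mean),
`r²`, and the average deviation from linearity

    ADL_i = sum_j( μ̂Q_ij − μ̂L_ij )² / μ̄_i

comparing the quadratic and linear fits, with an extra-sum-of-squares
F-test for its significance. A genotype is selected when its pooled mean
exceeds the grand mean, `b ≤ 1` and/or b lies inside `mean(b) ± SD(b)`,
`r² > 0.50`, and ADL is not significantly different from 0.

**Supporting statistics.** Trait aggregation (NFL, FS, TNF, FW, YP) from
raw plant/truss records; pooled-variance Student t-tests against control
hybrids with significance stars and direction; balanced three-way
fixed-effects ANOVA (genotype x location x year) with per-source TSS%;
Pearson trait correlations per field and per genotype.

**Variant engine.** VCF in/out; filtering (≥ 50% called, mean depth over
called samples ≥ 5, monomorphic sites dropped); genotype-class
composition; per-sample private SNP/InDel counts with a chromosome
breakdown; identity-by-state similarity `(N_ibs2 + 0.5·N_ibs1)/N`;
windowed marker-density BED tracks; SnpEff-style consequence terms with
high/moderate/low/modifier impact tiers; and wild-relative origin
assignment of informative InDels (≥ 5 nt or SSR with a whole-repeat
shift) by aligning 100-bp flank queries with a seed-and-extend banded
aligner, accepting species with 100% identity over the InDel region and
more than 90% overall.

**Synthetic data.** Generators for the trial, a toy genome with gene
models (FASTA/GFF3), the variant panel (VCF + truth TSVs), and diverged
wild genomes with planted introgressions, so the whole pipeline round-trips
against known ground truth. See the methods vignette
(`vignettes/yieldvar-methods.Rmd`) for the model details and every
numerical convention.

## Worked example

```r
library(yieldvar)

genotypes <- c("E7","E8","E17","E36","E37","E42","E45","E53",
               "E76","E107","DOCET","JAG8810")
cfg <- trial_config(genotype_names = genotypes, seed = 42)
trial <- generate_yield_trial(cfg)      # 12 x 4 x 3 replicate-level table
res <- stability_analysis(trial)

round(res$ei, 3)
#> Campania_2016 Campania_2017   Puglia_2016   Puglia_2017
#>        -1.577        -0.366         0.269         1.673

subset(res$fits, genotype %in% c("E42", "E45", "E107"))
#>   genotype    b intercept   r2 pooled_mean   adl adl_p
#>       E107 1.37      2.92 0.99        2.92 0.038  0.16
#>        E42 0.91      2.41 0.99        2.41 0.011  0.20
#>        E45 1.06      2.49 1.00        2.49 0.001  0.83

res$grand_mean                          # 2.38 kg/plant
res$selection$genotype[res$selection$selected]
#> [1] "E42"
```

The environment indices order the four fields from the poorest
(Campania 2016, 1.6 kg/plant below the grand mean) to the most favorable
(Puglia 2017). E42 combines a pooled mean above the 2.38 kg/plant grand
mean with a slope below 1 inside the population band, a high `r²` and a
non-significant ADL, so it is the only genotype selected; E107 yields well
but only in favorable environments (b = 1.37).

## Analysis workflow

The numbered scripts under `analysis/` run the full study pipeline over
the synthetic world and write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | trial, traits, genome (FASTA+GFF3), panel (VCF), wild genomes |
| `02_stability.R` | EI, stability fits, ADL, selection report |
| `03_phenostats.R` | t-tests vs controls, three-way ANOVA + TSS%, correlations |
| `04_variants.R` | filtering, composition, private markers, IBS, density |
| `05_effects.R` | consequence calls, impact summary, high-impact report |
| `06_introgression.R` | candidate InDels, flank-query alignment, origin assignment |

Run them in order with `Rscript analysis/01_simulate.R` (an optional
integer argument sets the seed) through `Rscript analysis/06_introgression.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end from a fresh simulation at the given
seed — stability selection, phenotype statistics, variant filtering and
summaries, effect classification, and the wild-relative introgression scan
with its sensitivity against the planted truth — and writes the acceptance
JSON to `--out`.
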