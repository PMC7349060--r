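---
title: "Methods: yield-stability selection and GBS variant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield-stability selection and GBS variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldvar)
```

# The problem

Selecting crop genotypes that yield well *and* stably across hot, variable
environments requires two complementary analyses. First, a multi-environment
trial (genotypes x location-year environments x replicates) is reduced to a
per-genotype regression on environmental quality, and a small set of rules
picks the genotypes whose yield is both high and insensitive to the
environment. Second, a genotyping-by-sequencing (GBS) variant panel over the
same genotypes is filtered and summarized — private markers, genetic
distances, predicted effects on proteins, and putative introgressions from
wild relatives — to connect the selected genotype's phenotype to its
genetic make-up. `yieldvar` implements both, together with a synthetic-data
generator so that every stage is testable against known truth without the
study's external raw data.

# Stability regression

For a complete genotype x environment table of mean yield per plant
$Y_{ij}$ ($i = 1..v$ genotypes, $j = 1..l$ environments, an environment
being one location-year), the environment index is

$$EI_j = \frac{\sum_i Y_{ij}}{v} - \frac{\sum_i \sum_j Y_{ij}}{vl},
\qquad \sum_j EI_j = 0.$$

Each genotype's environment means are regressed on $EI$: the slope $b_i$
(coefficient of regression) measures environmental sensitivity ($b = 1$
average, $b < 1$ below average), the intercept equals the genotype's pooled
mean because $\overline{EI} = 0$, and $r^2$ gauges model adequacy. When
$EI$ is computed from the same complete table the slopes average exactly 1
— an algebraic identity the tests assert.

The average deviation from linearity compares the best quadratic fit in
$EI$ with the linear one:

$$ADL_i = \frac{\sum_j (\hat\mu_{Q,ij} - \hat\mu_{L,ij})^2}{\bar\mu_i},$$

where $\bar\mu_i$ is the genotype's average yield. $ADL_i = 0$ iff the
quadratic coefficient is zero; a significantly nonzero value makes $b_i$
unreliable. Two choices were genuinely open and are resolved as follows.

* **ADL significance.** No test is named in the source material for this
  statistic; we use the extra-sum-of-squares F-test of the quadratic term
  on the $l$ environment means (df $1$ and $l-3$), the standard
  lack-of-linearity test for the data actually regressed. With $l = 3$ the
  quadratic is saturated and the p-value is reported `NA`; with an ADL of
  exactly zero there is nothing to test and $p = 1$.
* **ADL denominator.** The published equation is typographically garbled;
  we divide by $\bar\mu_i$ because the symbol list defines $\bar\mu$ as
  the genotype's average yield. `compute_adl(denominator = "n_env")`
  divides by $l$ instead for sensitivity analyses.

Selection (`select_stable`) requires, per genotype: pooled mean above the
grand mean; $b_i \le 1$ (boundary inclusive) and/or inside the population
band $\bar b \pm k\,\mathrm{SD}(b)$ with $k = 1$; $r^2 > 0.50$ (strict);
and ADL not significant at $\alpha = 0.05$. The default `slope_rule =
"both"` demands $b \le 1$ *and* band membership, but both flags are always
reported so either reading is auditable. A genotype with zero yield
variance has $SS_{tot} = 0$; its $r^2$ is reported `NA` with a warning
(not 0, not 1) and it fails the $r^2$ criterion.

**Known discrepancy.** The reference analysis reports a slope band
0.77–1.57 around a mean of 1.17, yet the mean slope is algebraically 1
whenever $EI$ derives from the full table; its $EI$ basis (possibly a
genotype subset) is not recoverable. We compute $EI$ from all genotypes in
the table, controls included, and do not guess; external $EI$ vectors can
be supplied to `fit_linear` and are flagged in the output.

# Supporting phenotype statistics

Traits are NFL (flowers/inflorescence, trusses 2–5), FS (fruit-set
proportion per inflorescence, trusses 2–5), TNF (fruits/plant), FW
(g/fruit from a sample of at least 50 fruits), and YP (kg/plant);
`aggregate_traits` computes them from raw plant/truss and harvest records
by the stated ratios. Control comparisons use the classic pooled-variance
Student t-test, two-sided, per trait x field (`var_equal = FALSE` gives
Welch), with per-comparison stars at 0.05/0.01/0.001 and no multiplicity
correction by default (a Benjamini–Hochberg switch exists) — matching the
reported per-cell stars. The three-way ANOVA treats genotype, location and
year as fixed factors on a balanced design only (the Type I/II/III
distinction vanishes under balance; unbalanced input is refused rather than
silently resolved), and reports each source's TSS%, its share of the total
sum of squares. Pearson correlations are computed within fields (across
genotypes) and within genotypes (across fields), with p-values from the
t transform on $n-2$ df.

# Variant panel processing

`read_vcf` (via Bioconductor's VariantAnnotation) yields a biallelic
site x sample dosage matrix; multi-allelic records are split with a
warning, the remaining alternatives folding into the reference class.
Filtering follows the named tool conventions: *max missing 0.50* is read
as the VcfTools `--max-missing` semantics — at least half of the samples
called, boundary inclusive; mean depth is computed over called samples
only and sites without DP fail unless the threshold is 0; monomorphic
sites (fewer than two distinct called genotype classes, e.g. the same
alternative allele in every genotype — a reference-cultivar difference)
are dropped. Filtering is idempotent.

A site is *private* to a sample iff that sample carries at least one
alternative allele and every other called sample is homozygous reference;
because missing genotypes could hide a second carrier, we additionally
require at least 50% of the remaining samples called, otherwise the site
is counted *unassignable* rather than private.

IBS similarity uses the PLINK DST form over co-called loci,
$(N_{ibs2} + 0.5\,N_{ibs1})/N$, consistent with "values tending to 0 mean
higher distance"; the matrix is computed on SNPs by default
(`snps_only = FALSE` includes InDels) and is tested against a brute-force
per-allele enumeration. Marker density uses BED conventions (0-based
half-open windows) while VCF coordinates stay 1-based throughout.

# Effect classification

Consequence terms and the four impact tiers follow SnpEff's defaults:
coding SNVs are translated through the standard genetic code
(minus-strand genes via reverse complement) into stop_gained / stop_lost /
start_lost / missense / synonymous; coding InDels are frameshift when the
net length change is not a multiple of 3, inframe otherwise; the first and
last 2 intronic bases are splice acceptor/donor sites (high, emitted
together with `intron_variant` as combined calls); splice_region spans
exonic 1–3 and intronic 3–8 bases from a junction (low); intron, UTR,
upstream/downstream (5 kb) and intergenic variants are modifiers. InDels
are left-normalized by trimming the shared anchor base. The toy annotation
has one transcript per gene; with overlapping genes the most severe call
is reported. Summaries count affected genes per class and as a union,
since a gene can be hit by both SNPs and InDels.

# Introgression detection

Candidate InDels are either plain (net length change of at least 5 nt,
coded N) or SSR-type (the inserted/deleted sequence is a whole number of
1–6 bp repeat units within a tandem array of at least 3 copies, so the
alleles differ by at least one full repeat; coded S). The SSR motif is
canonicalized to the lexicographically smallest rotation over both
strands.

Queries are 100 bp windows centered on the InDel allele ("about 100 bp"
fixed at exactly 100), built on the *alternative*-allele haplotype (the
putatively introgressed one; a `ref` switch exists) and shifted inward at
chromosome ends. Queries are built on the carrier sample's *local
haplotype*: its other variants inside the window are applied too, because
a genotype's flanking sequence carries all of its variants — with the
reference context instead, a neighbouring deletion alone would cap the
achievable identity below the acceptance threshold and break the
round-trip guarantee.

Alignment replaces BLAST with exact 15-mer seeding on both strands (an
11-mer rescue pass runs when no 15-mer seed exists, since 10 mismatches
over 100 bp only guarantee a 15-bp exact run for five or fewer of them)
followed by a banded affine-gap dynamic program fitting the full query
into the seeded window (match +1, mismatch −1, gap open −2, gap extend −1,
band = 2 x InDel length + 10; free leading/trailing subject gaps). The
banded program is tested to equal the unbanded one and an independent
reference aligner on small instances. Overall identity is matches over
aligned columns; InDel-region identity is computed over the columns
spanning the allele plus one base past the junction, so that for a
deletion the junction itself must align cleanly. A species passes when its
best hit has 100% InDel-region identity and strictly more than 90% overall
identity; exactly one passing species gives "assigned", ties are reported
"ambiguous" and never broken silently.

# The synthetic world

The generators state the world once; tests never tune them toward a pass.

* **Trial**: 12 genotypes (10 landraces, 2 control hybrids) x 4
  location-year environments x 3 replicates. Default environment effects
  are the deviations of the four published field means (1.06, 2.04, 2.62,
  3.86 kg/plant); true slopes span the published 0.51–1.78 range; the
  grand mean is 2.39 kg/plant. Replicate noise is i.i.d. Gaussian with SD
  0.3 kg/plant — the replicate-level variance components are not published,
  so this is a configurable choice of plausible magnitude (about an eighth
  of the grand mean). No block effect is simulated because the regression
  operates on environment means.
* **Genome**: 2 x 50 kb chromosomes at GC 0.38 with simple one-transcript
  gene models (ATG start, clean stop, GT..AG introns). This is artifact
  plumbing, not tomato annotation.
* **Panel**: ~500 sites; per-genotype private counts scaled down
  proportionally from the published panel (E42 holding roughly half);
  shared sites segregate in few samples so the composition lands near the
  published 83% homozygous-reference; hybrids get het fraction 0.6 versus
  0.05 for the inbred landraces. Positions sit on a 40 bp grid so allele
  intervals never overlap; truth tables are written as separate TSVs,
  never embedded in the VCF.
* **Wild genomes**: the reference substituted at 15% outside planted
  intervals (background identity ≈ 85%, safely below the 90% rule) and
  copied exactly inside them, carrying the target sample's alleles.

What a green test does *not* establish: the generator has no linkage
disequilibrium, no read-level errors, no real gene annotation, and its
trial has no block structure — so the tests validate the computations and
their contracts, not the biology of any particular dataset. The published
per-genotype stability values (slope range 0.51–1.78; E42 at $b = 0.96$,
$r^2 = 0.72$, ADL 0) are carried as reference values only: the raw
per-plot yields live in an external appendix repository, so they are not
recomputable here — the acceptance suite instead feeds the printed summary
statistics through the selection rule and checks that exactly E42 emerges.

# Numerical conventions

Boundary conventions are inclusive where the rules say "at least"
(called fraction = 0.50 kept, $b = 1$ selected, 5 nt InDel kept) and
strict where they say "more than" ($r^2 > 0.50$, overall identity > 90%).
Ties between species are ambiguous, never resolved. All generators are
pure functions of their seed; `set.seed` is called once per generator
invocation. EI closure, ANOVA sum-of-squares additivity and TSS% = 100 are
asserted to 1e-9/1e-6 rather than exactly, reflecting double-precision
accumulation.

# Limitations

AMMI/GGE and mixed-model stability approaches are out of scope, as are
variant calling, phasing, imputation, PLINK file formats, real wild
assemblies, and drawing literature QTL maps. The aligner is an identity
filter at toy scale, not a general-purpose search tool.
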