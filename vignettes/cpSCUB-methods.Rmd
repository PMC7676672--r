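---
title: "Methods: synonymous codon usage bias in chloroplast genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synonymous codon usage bias in chloroplast genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpSCUB)
```

## The problem

Synonymous codon usage bias (SCUB) is the unequal use of codons that encode
the same amino acid. In land-plant chloroplast genomes the bias runs strongly
toward codons ending in A or T, and its fine structure — how it varies with
intron number, exon position and dinucleotide context — carries information
about the mutational and selective forces acting on the plastome, including
the deamination of methylated cytosine in CpG contexts and the evolutionary
events surrounding allopolyploid formation in crop lineages such as cotton
(*Gossypium*) and bread wheat (*Triticum*/*Aegilops*).

cpSCUB implements that analysis as a pipeline from annotated GenBank records
to species-level SCUB profiles, context ratios, statistical tests and a
species ordination, together with a ground-truth synthetic plastome
generator so every stage is testable without network access.

## The eligible codon universe

All statistics run over the **59 synonymous codons (SCs)**: the 64 triplets
minus the three stops (TAA, TAG, TGA) and the two single-codon amino acids
Met (ATG) and Trp (TGG). These 59 codons encode 18 amino acids, each by at
least two codons. When codons are counted (`count_codons()`), the first
codon of each gene (typical or atypical start), the final codon (typical or
atypical stop), internal stop codons, internal ATG and TGG, and codons
containing an ambiguous base are excluded from the eligible counts; each
exclusion is tallied separately so nothing is silently dropped. Under this
default the four terminal-base frequencies (NNA, NNT, NNC, NNG) partition
the eligible universe and sum to exactly 1. A configuration switch
(`include_internal_atg`) reproduces the looser reading in which internal
Met codons enter the denominator; it is off by default because the 59-SC
universe is the internally consistent one.

## Statistics computed

* **Per-codon relative frequency**: each SC count over the eligible total.
* **RSCU** (relative synonymous codon usage): observed count × family size /
  family total, so values within a family average to 1. Families with zero
  total report `NA`, not 0. On exact ties for an extreme RSCU the
  lexicographically smallest codon is reported first.
* **CAI** (codon adaptation index): the geometric mean of relative
  adaptiveness weights *w* = RSCU / max(RSCU within family) over all
  eligible codon occurrences. The reference weights default to the table's
  own RSCU (an explicit `weights` argument accepts an external reference
  set); zero weights are floored at 0.01 before taking logs.
* **SCUB frequency**: the package's core statistic, the ratio of C/G-ending
  to A/T-ending SC counts, globally (`nncg_to_nnat`) and per amino-acid
  family (`per_aa_ratio`). Ratios are codon-pooled, not gene-averaged,
  because the chi-square tests operate on the raw pooled counts; a
  `per_gene = TRUE` flag provides the gene-averaged variant.

## Split codons and intron/exon resolution

Codons interrupted by an intron are assigned by phase: a codon split after
its first nucleotide belongs to the downstream exon, after its second
nucleotide to the upstream exon. A codon spanning three exons (possible only
with a 1-nt middle exon) is assigned to the middle exon; the case is logged.
`scub_by_intron_class()` pools eligible codons over genes grouped by intron
number; `scub_by_exon_position()` pools them by mRNA exon rank (1st, 2nd,
3rd — not genome order, which differs on the minus strand). Start and stop
codons sit in terminal exons and are tracked in the partition but never
enter the ratios, keeping eligibility identical everywhere.

## CpG-context proxies

Methylated cytosine deaminates to thymine; in a CpG context this depletes
CpG over evolutionary time. Two codon-level contexts are synonymous and
therefore visible in codon usage:

* **second/third position** (NCG): the ratio NCG/NCC per second-position
  base X (NXG/NXC), and NCG/NCA directly;
* **codon junction** (NC|X): the third base of an internal eligible codon
  followed by the first base of the next internal codon. The successor may
  be any internal codon (including ATG/TGG) because only its first base
  matters; the focal codon must be one of the 59 SCs. Junctions are counted
  on the spliced CDS (mRNA frame), so intron-spanning junctions count as
  contiguous — a caveat, since the genomic context differs, but no genomic
  variant of the ratio is defined here.

Raw numerator and denominator counts are always carried along so chi-square
tests run on counts, never on ratios. The per-amino-acid NNG/NNC ratios use
the same-prefix pairs (Ala GCG/GCC, Pro CCG/CCC, Ser TCG/TCC, Thr ACG/ACC,
Arg CGG/CGC, Gly GGG/GGC, Leu CTG/CTC, Val GTG/GTC): for six-codon families
only the pair sharing first and second positions is compared, since the
point of the measure is to isolate the third-position effect at fixed
dinucleotide context.

## Statistical conventions

Chi-square (contingency and goodness-of-fit), one- and two-sample t,
Pearson correlation, Cronbach's alpha and the coefficient of variation are
exposed as pure functions on counts/vectors. Conventions: two-sided
p-values; sample (n−1) variances; pooled-variance two-sample t by default
with Welch behind a flag; no continuity correction in 2×2 chi-square (the
analysis counts are 10³–10⁴, where the correction is negligible) with a
flag to enable it; tables with any expected cell count below 1 are rejected;
no multiple-testing correction, matching the convention of reporting raw
p-values. Identical values passed to the one-sample t are an error (the
statistic is 0/0), not a statistic of 0.

## Ordination

The species matrix has one row per species and 59 columns (per-codon
frequency of total SCs, or RSCU — both modes are supported and both must
support any qualitative claim). Clustering uses correlation distance
d = 1 − r with average linkage; ties are resolved by `stats::hclust`'s
deterministic ordering. PCA is column-centered covariance PCA by default
(`scale = TRUE` gives the correlation variant); each component's sign is
fixed so its largest-magnitude loading is positive, making score plots
reproducible, and all claims made of the scores (clade membership, axis
separation) are sign-invariant anyway.

## The synthetic plastome generator

`synthetic_truth()` fixes the ground truth: genes per intron class, a
third-position A/T preference θ (scalar, per exon rank, or per amino-acid
family), rates for atypical ACG starts and internal stops, CpG deamination
probabilities, and a seed. Genes are drawn codon by codon: amino acid
uniform over the 18 families, then a synonymous choice ending in A/T with
probability θ (uniform within the A/T and C/G pools). The expected
NNC/G-to-NNA/T ratio is therefore (1 − θ)/θ, the recovery target of the
acceptance tests. Introns are inserted at uniform positions at least 3 nt
from the CDS ends (split-codon phases are exercised, termini stay clean);
about 30% of genes land on the minus strand; records are circular, with an
optional origin-spanning gene for the wrap-around test. Generation is
deterministic given the seed, to the byte in the GenBank output.

CpG deamination has two synonymous channels, each with its own probability:
`ncg_depletion` converts codon-internal NCG → NCA (the antisense-strand
deamination, synonymous for all four NCG codons), and `cpg_depletion`
converts a third-position C followed by a G-starting codon to T (the
sense-strand deamination, synonymous for every NNC). The junction channel
thins the NC|G count by exactly the factor (1 − d), which is what the
depletion-recovery tests check.

### Presets

`emulate_paper_architecture()` provides the two study presets: a cotton-like
plastome (70 intronless, 11 one-intron, 4 two-intron genes; one atypical ACG
start) and a wheat-like plastome (71/7/1). Both use a fixed per-family θ
profile with mean 0.73 — so the genus-mean SCUB frequency is about 0.37, the
magnitude observed in these chloroplast genomes — spanning θ ≈ 0.64–0.79
(per-family ratios ≈ 0.27–0.56, the observed heterogeneity), and both
deamination rates at 0.3, reproducing the observed NCG/NCC deficit. The two
genus profiles differ modestly but systematically (Leu more biased in the
cotton profile, Ser in the wheat profile), which is what makes the genera
distinguishable in ordination. Because deamination moves codons from the
C/G to the A/T pool, the presets analytically compensate the draw-θ of each
family so that the realized per-family ratios still match the profile; the
closed form is in `.depletion_adjusted_theta()`.

Mean gene length is 250 codons (Poisson, floor 10), giving ≈ 20 000 eligible
codons per record — the scale of a real plastome's coding complement.

### Genera as ancestor plus divergence

Real congeneric chloroplast genomes are more than 99% identical, which is
why published within-genus consistency statistics (pairwise r ≈ 0.999,
Cronbach's alpha ≈ 1.000) are so extreme. Independent multinomial draws per
species cannot reproduce that at any realistic sequencing depth, so
`generate_genus()` generates one ancestor and derives each congener by
redrawing a small fraction of internal codons in place (default 1% per
codon; 2% is used for the more heterogeneous wheat-like complex). Gene
architecture, coordinates and intergenic sequence are untouched, so
divergence is purely synonymous-site turnover.

### What the generator does not emulate

* No inverted repeat, tRNA/rRNA genes or realistic intergenic sequence.
* Amino-acid composition is uniform over the 18 families (configurable in
  principle; the analysis depends only on third-position behaviour).
* Within the A/T and C/G pools the choice is uniform, so second-position
  context ratios other than the NCG deficit (e.g. NAG/NAC, NTG/NTC) take
  values set by family structure, not by the preferences seen in real
  plastomes — their real-data directionality (above 1) is not reproduced,
  only the NCG-specific deficit is.
* The baseline junction ratio NC|G/NG|G reflects the structural C/G-ending
  balance (≈ 1.4 under the presets) rather than the below-1 values of real
  plastomes; depletion lowers it multiplicatively, which is the tested
  property.
* The presets apply no intron-class or exon-rank θ gradient, so
  intron/exon-resolved contrasts on preset data are a negative control;
  rank-dependent bias is exercised through the explicit per-rank θ option.
* RNA editing is out of scope entirely.

Consequently, passing tests demonstrate the correctness of the measurement
machinery and the recoverability of known truth — not that real plastomes
satisfy any particular value.

## Numerical and design choices

* Coordinates are 1-based inclusive internally (the R/IRanges idiom) and at
  the GenBank boundary; split-codon arithmetic uses cumulative exon lengths,
  which needs no half-open convention.
* Inverted-repeat duplicate genes are *not* deduplicated: every annotated
  non-pseudo CDS counts. Pseudogenes are excluded everywhere. Trans-spliced
  genes are processed exactly as their location joins state.
* Genes whose length is not a multiple of 3 are retained but flagged and
  excluded from all statistics; every excluded CDS appears in the rejection
  log with its reason.
* Codons containing N are excluded from tallies; the gene is kept.
* Ratios with zero denominators are `NA` ("undefined"), never 0 or Inf.
* Reports round to 3 decimals for display; machine-readable TSV/JSON keep
  full precision.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
11 preset-scale records (≈ 85 genes × 250 codons each) for the study-scale
analyses, 30 records of ≈ 10⁴ codons for θ recovery (three θ values × 10
seeds, the recovered ratio required within 3 Monte-Carlo standard errors of
(1 − θ)/θ), 15 records for the CpG-depletion response, and 500 random exon
architectures for the split-codon property test. The full suite runs in
well under a minute on one CPU.

Analyses of the real accessions require downloading their GenBank records;
`run_scub_pipeline()` accepts the downloaded files directly and produces
the same report bundle.
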