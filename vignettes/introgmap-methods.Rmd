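---
title: "Methods: transcriptome-based genotyping of introgression lines"
author: "introgmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based genotyping of introgression lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `introgmap`, the choices made
where the underlying procedures are genuinely open, and what the bundled
simulator does and does not emulate. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The variant-excess model

A transcript transcribed from a donor (*indica*) segment differs from the
*japonica* reference at many sites, while a recurrent-parent transcript
shows only the cultivar's natural variation. We model the observed
per-transcript variant counts as

* donor origin: `v ~ NB(mu_donor, phi)` with `mu_donor = 18` and mild
  overdispersion `phi = 0.01` (variance `mu + phi mu^2`; callable-site
  sampling is close to Poisson, the NB term absorbs transcript-level
  heterogeneity),
* recurrent origin: `v ~ Poisson(mu_recurrent)` with `mu_recurrent = 2`,

both thinned binomially with detection probability `p_detect = 0.9`,
which models expression-dependent variant discovery (weakly expressed
transcripts reveal fewer of their variants). Binomial thinning of an NB
(or Poisson) with mean `mu` is again NB (Poisson) with mean `p * mu`, so
the donor-side observed mean is `18 × 0.9 = 16.2`.

The classifier is the published rule taken literally: donor when
`delta_v = v_test − v_control ≥ T` with `T = 10`, strict "10 or more";
`delta_v` is an absolute count difference, not a per-kilobase rate — the
rule compares raw variant numbers. Transcripts with no variant
information at all are classified recurrent and flagged (`no_info`),
since only expressed transcripts are observable.

Under these defaults the rule is *separable but imperfect*: integrating
the recurrent (Poisson 1.8) control against the donor (NB 16.2) test
distribution gives a per-transcript miss probability of about 0.13–0.15,
and a false-positive probability below 1e-5. A per-transcript error rate
of that size is exactly why the block step exists.

## 2. Block delimitation and what "recovery" means

Within a chromosome, transcripts are position-sorted and a block is a
maximal run of donor calls containing at least `K = 5` donor transcripts
in which at most `G = 2` consecutive recurrent calls are bridged. Runs
with fewer than `K` donors are reported as *dispersed* donor transcripts
rather than discarded — isolated donor genes are a real feature of
backcross genomes. The source procedure delimits blocks without stating a
segmentation rule; `K` and `G` are this package's choice and are
configurable (`mapperConfig()`). Block members are the donor-called
transcripts of the run, so the conservation identity

> donor calls = Σ block members + dispersed

holds exactly and totals can always be audited. Boundaries are the
coordinates of the first and last member. Annotation coordinates are
1-based inclusive (GFF3); exported BED intervals are 0-based half-open.

`benchmarkRecovery()` scores the *reconstructed mosaic*: a transcript
counts as mapped-donor when it lies inside a called block interval or is
a dispersed donor call. This is deliberate. With a ~0.14 miss rate the
raw per-transcript classification tops out near 0.86 sensitivity no
matter how large the blocks are; the gap-bridging block step is the
mechanism that rescues under-detected transcripts inside introgressions,
and the mosaic — not the individual call — is the analysis product. The
raw classification sensitivity is still reported (`classSensitivity`).
One consequence of the same error model: a run of three or more
consecutive misses splits a block, which happens somewhere in a
~400-donor genome in roughly half of simulated lines. Fragment counts are
therefore not a stable statistic; recovered boundaries (we report the
union extent of called blocks overlapping a truth block) and
sensitivity/FDR are.

## 3. The simulated study line

`genomeSpec()` defaults to a 12-chromosome rice-scale genome (43–23 Mb)
carrying 2,000 expressed, variant-informative transcripts allocated by
the rice per-chromosome gene share. `mosaicConfig()` defaults place two
large donor blocks on chromosome 1 (2–19 Mb and 21–40 Mb, the second
covering the *Saltol* flanking interval at 9.06–13.34 Mb) and one on
chromosome 3 (2–28 Mb), plus 28 dispersed donor genes outside blocks, all
homozygous — heterozygous introgressions are out of scope. Block spans
were fixed at design time from the closed-form error rates above so that
each block carries on the order of a hundred transcripts: large enough
that boundary placement and gap bridging are genuinely exercised, and
that the expected mosaic sensitivity (~0.98) sits well clear of the 0.95
level the recovery checks use. The same reasoning fixed `phi = 0.01`;
pushing donor overdispersion to 0.05 or beyond degrades the per-transcript
miss rate to ~0.19 and the design would no longer support a 0.95
reconstruction target — that regime is available through
`divergenceModel()` for sensitivity analyses, but it is not the default
study condition.

What the generator does *not* emulate: read-level sequencing and variant
calling (counts are drawn, not called from alignments), linkage
disequilibrium inside blocks beyond the block structure itself,
heterozygous segments, and any correlation between a transcript's
expression level and its detection thinning (thinning is i.i.d.).
Passing recovery tests therefore validate the classification and
segmentation logic under the stated error model, not a variant-calling
workflow.

## 4. MABC simulation

Meiosis follows the Haldane (no-interference) model: between adjacent
markers at map distance `d` Morgans, recombination occurs with
probability `r = (1 − e^(−2d))/2`, independently across intervals. The
default panel has 68 SNPs over the 12 chromosomes (a uniform 250 kb/cM
rate), including three *Saltol*-region foreground markers on chromosome 1
at 9.06, 11.20 and 13.34 Mb. The programme is an initial cross, three
backcrosses and three selfings; embryo rescue is modelled as guaranteed
progeny viability (no computational content). The source does not state
family sizes or a ranking rule, so selection is: among foreground-positive
progeny (carriers during backcrossing, foreground homozygotes once
selfing begins), advance the top line by background RPG; 24
progeny/generation by default. A family with no foreground-positive
progeny is reported extinct rather than erroring.

RPG is allele-counting, `100 (2 n_RR + n_RD) / (2 n_panel)` —
heterozygotes contribute half. Whether the original accounting counted
heterozygotes as half or excluded them is not stated; allele counting is
the standard MABC convention and is the one under which "100%" coincides
with full recurrent homozygosity. Two consequences used as checks: with
no selection the expected RPG at BC3F1 is `100 (1 − (1/2)^4) = 93.75%`,
and selfing without selection halves heterozygosity per generation in
expectation.

Marker filtering keeps parent-polymorphic loci with heterozygote rate
strictly below 40%. Founder grouping agglomerates lines whose
donor-marker fingerprints are identical or nested, with a Jaccard-distance
tolerance of 0.2 for noisy data; on clean data the recovered partition
equals or refines the founder partition (sister lines fix nested subsets
of their founder's segments).

## 5. Phenotype indices

Each line carries a latent tolerance in [0, 1]; salt damage is
`(1 − tolerance)` scaled by NaCl dose relative to 80 mM (the phenotyping
condition is 80 mM NaCl for 14 days; the transcriptome condition 24 h).
Trait means under salt decline linearly with damage (multiplicative
log-normal replicate noise, default SD 0.08); electrolyte leakage rises
from a 5% baseline to ~80% at full damage, with `0 ≤ Ec1 ≤ Ec2` enforced
by construction; SES scores are produced by cutting a Gaussian latent
damage score (SD 0.12) at fixed thresholds 0.2/0.4/0.6/0.8 into the
ordinal categories {1, 3, 5, 7, 9} — this reproduces a 5-category ordinal
scale whose distribution shifts with genotype. Tissue Na⁺/K⁺ ratios rise
with damage in shoot tissues and stay nearly flat in roots, mirroring the
tissue pattern observed in salt-stressed seedlings. Replicate values
represent plant-pool means ("three replicates from four plants each"), so
aggregation is replicate means first, then line means. Trait
normalization uses grand means per line and condition (per-tank pairing
is not modelled). SES is treated as ordinal: distributions only, no
parametric test. Student's pooled-variance *t* is the default comparison,
Welch's available by flag.

## 6. Differential expression

FPKM is `counts × 10⁹ / (length × library size)`. The DEG thresholds are
applied with the printed operators: strict `|log2FC| > 0.5`, inclusive
`p ≤ 0.05` and `FPKM ≥ 25` (the FPKM filter is the only low-expression
filter; no multiple-testing correction by default, BH available by flag;
an `inclusiveLfc` flag covers the alternative reading of the fold-change
bound). The FPKM criterion uses the mean over the contrast's samples.

The test is a negative-binomial exact conditional test: per gene, the
group totals are conditioned on their sum under a common-mean NB with a
shared dispersion estimated by conditional maximum likelihood over all
genes (within-group conditioning removes the gene means). It assumes
equal library sizes, so counts are first scaled to a common effective
depth. Effective depths are median-of-ratios size factors anchored at the
geometric mean of the raw depths rather than raw column sums: when the
salt response is strongly asymmetric, the up-regulated mass inflates raw
totals and pushes every unaffected gene toward apparent down-regulation;
the median ratio is robust to that composition effect. The same effective
sizes are used for FPKM so fold changes of unaffected genes stay centred
at zero. Genes with zero counts throughout get `p = 1` and a flag.

The expression generator draws NB counts (dispersion 0.1) for 2
genotypes × 2 conditions × 3 replicates, baseline means log-uniform on
[20, 5000] at a reference depth of 2×10⁷ (so roughly half the genes clear
the FPKM ≥ 25 bar, as an expression-level filter is meant to do), library
sizes uniform on [15, 25]×10⁶ and gene lengths on [500, 3000] bp.
Salt-responsive fractions default to 10% (IL) and 12% (parent) with a
common fraction of 1.75%, chosen so the design's true common-response
percentage `100·common/union` is ≈ 8.6 — the regime of interest, where
most of the salt response is genotype-specific. Effect sizes default to
|log2FC| = 2, half up, half down, common genes direction-matched.
Overlap estimates are compared against the set-arithmetic truth
restricted to the quantifiable (FPKM-passing) universe; the restriction
removes the sampling noise of which genes happen to be expressed highly
enough to be callable.

## 7. Numerical and interface conventions

* All simulators take an integer `seed` and restore the caller's RNG
  state; identical seeds give bit-identical outputs (the pipeline
  manifest records md5 digests to make this checkable).
* TSVs are tab-delimited UTF-8 with a header and `.` for missing; VCF is
  fixed at v4.2 with a GT-only FORMAT (`0/0`, `0/1`, `1/1`); GFF3 is
  1-based inclusive with an `ID` per transcript; BED is 0-based
  half-open.
* Degenerate inputs fail loudly: overlapping truth blocks, blocks outside
  chromosomes, empty marker panels, `Ec2 = 0`, SES values outside
  {1,3,5,7,9}, single-replicate comparisons, duplicate transcript ids.
  `Ec1 > Ec2` warns and flags rather than errors (it occurs in real
  conductivity data).
* Ties at thresholds follow the printed operators everywhere (`≥ T`,
  `> 0.5`, `≤ 0.05`, `≥ 25`, het rate `< 0.40`).

Problem sizes used by the checks — 2,000 transcripts for mosaic
recovery, 1,000 families for the RPG expectation, 2,000 genes for test
calibration, 5,000 genes for overlap recovery, 1,000 random instances
(≤ 200 transcripts) for the segmentation oracle — are the package's
standard verification conditions; they keep every Monte-Carlo standard
error far below the tolerance it is compared against.

## 8. Known limitations

* The variant-count model is per-transcript and abstract; what counts as
  one "variant" (SNV, indel, per-site vs per-allele) is left to the
  upstream caller that produced the profile table.
* Only homozygous introgressions are modelled and detected; heterozygous
  segments would halve the variant excess and need a different threshold.
* The NB exact test is a classic two-group test with a single common
  dispersion — no tagwise shrinkage, no GLM covariates.
* Founder grouping assumes fingerprints are informative; after very
  aggressive background selection all lines collapse to the foreground
  fingerprint and families are genuinely indistinguishable.
* The block rule has no likelihood interpretation; `K` and `G` trade
  sensitivity to short introgressions against fragmentation, and users
  mapping sparser transcriptomes should revisit them.
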