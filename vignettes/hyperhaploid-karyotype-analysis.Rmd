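---
title: "Inferring hyperhaploid karyotypes, their generating mechanism, and double-hit TP53 status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hyperhaploid karyotypes, their generating mechanism, and double-hit TP53 status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperhaploidy)
```

## The problem

Hyperhaploid multiple myeloma is a rare, high-risk numerical subgroup
defined by a karyotype of 24–34 chromosomes. It arises by extensive
whole-chromosome loss: most autosomes become monosomic while a
characteristic set — the odd-numbered chromosomes gained in
hyperdiploid myeloma, plus chromosome 18 — stays disomic. Because
tumor/normal exome data resolve *which parental homolog* is present,
three questions become answerable from SNP allele counts alone:

1. **Which chromosomes are monosomic?** Whole-chromosome copy number
   and loss of heterozygosity (LOH) from B-allele frequencies and depth
   ratios.
2. **How did the karyotype arise?** Three candidate routes leave
   distinct LOH signatures on the disomic chromosomes.
3. **Is TP53 doubly inactivated?** A TP53 mutation on top of monosomy
   17 constitutes bi-allelic ("double-hit") inactivation, and the
   mutation's cancer cell fraction orders the two hits in time.

The patient data this analysis was designed around are
controlled-access, so the package ships a first-class simulator that
reproduces the statistical structure the inference assumes; every
claim the test suite makes is checked against simulator ground truth.

## The allele-specific model

Each autosome is described by maternal/paternal copy counts
$(n_m, n_p)$: heterodisomy is $(1,1)$, monosomy $(1,0)$ or $(0,1)$,
LOH means $\min(n_m,n_p)=0$. At a germline-heterozygous SNP where the
alternate (B) allele sits on a homolog with $n_B$ tumor copies, a
sample of purity $\pi$ has expected B-allele frequency

$$\mathrm{BAF} = \frac{(1-\pi) + \pi n_B}{(1-\pi)\,2 + \pi\,\mathrm{CN_t}},$$

implemented in `expected_baf()`. Read counts are binomial at this
expectation, with Poisson depth scaled by
$((1-\pi)2 + \pi \mathrm{CN_t})/2$ — the simplest model consistent
with ~100× exome coverage. The simulator (`simulate_allele_counts()`)
draws exactly from this model; its defaults (50 SNPs/chromosome, depth
100×, purity 0.9) were chosen so that per-chromosome calls are
near-certain, which is the regime CD138-selected myeloma samples
occupy.

### LOH calling

`compute_baf_profile()` folds BAF to mirrored BAF
$\max(\mathrm{BAF}, 1-\mathrm{BAF}) \in [0.5, 1]$ and takes
per-chromosome medians (SNPs under `min_depth = 10` in either sample
are excluded; chromosomes with fewer than `min_snps = 20` usable SNPs
are no-call, never force-called). A chromosome is LOH when its median
mirrored BAF reaches the midpoint between the heterodisomic
expectation 0.5 and the purity-adjusted monosomy expectation
$1 - (1-\pi)/(2-\pi)$ — a symmetric error trade-off that reduces to
0.75 at $\pi = 1$ and ≈0.705 at $\pi = 0.9$. At the default settings
the binomial standard error of the median is far below the decision
gap, which is why the recovery tests demand ≥99% per-chromosome
accuracy.

### Ploidy renormalization

Depth ratios (tumor/normal per SNP, per-chromosome medians) only fix
copy number up to a scale. Where consistent LOH is seen, the scale is
chosen so the median depth ratio of LOH chromosomes maps to copy
number one (`renormalize_ploidy()`); every chromosome then gets the
nearest integer (half rounds *up*, so ties never depend on floating
parity). An LOH chromosome whose rescaled ratio strays from 1 by more
than `cn_tolerance = 0.25` is flagged *discordant* rather than
overwritten — this is not a defect guard but a signal: under the
haploidization-then-duplication mechanism, duplicated LOH chromosomes
(copy state $(2,0)$) surface exactly as discordant CN-2 LOH calls.
A sample with no LOH at all (e.g. a diploid control) has no internal
anchor, so the caller must supply `anchor_cn` (default 2 in
`call_chromosomes()`); we made this an explicit argument rather than a
silent assumption because the renormalization convention is the one
place the whole copy-number scale can go wrong.

## Karyotype groups

Group bands follow the cytogenetic definitions: 24–34 hyperhaploid,
47–57 hyperdiploid, inclusive at all four boundaries. The pipeline is
autosome-only, so `summarize_karyotype()` adds a configurable
`sex_chromosome_copies` (default 2) to the autosomal CN sum — an
explicit, logged assumption rather than a guess about whether
published counts include sex chromosomes. A sample with more than 4
no-call autosomes is `unclassifiable`: 4 is the width of the gap
between the hyperhaploid band and the diploid count, so a larger
no-call budget could silently move a sample across groups.

## Mechanism inference

Three routes can generate a hyperhaploid karyotype, and they disagree
only on the disomic chromosomes:

| route | disomic chromosomes | predicted LOH fraction |
|---|---|---|
| haploidization, then duplication | duplicated single homologs | 1 |
| hyperdiploid intermediate, then haploid loss | survivor of a random loss from $(2,1)$ | 1/3 |
| direct sequential loss | untouched heterodisomies | 0 |

The 1/3 arises because a gain is modeled as a duplicate of one
randomly chosen existing homolog — $(2,1)$ or $(1,2)$ — after which a
uniformly random copy is lost; the singleton parent's copy is hit with
probability 1/3. We state this modeling choice explicitly because the
qualitative argument only asserts the outcome; `monte_carlo_oracle()`
verifies it by simulation, independently of the closed form.

Observing $k$ LOH chromosomes among $n$ disomic ones,
`classify_mechanism()` scores each route with a binomial likelihood at
$p' = p(1-\varepsilon) + (1-p)\varepsilon$. The per-chromosome
call-error rate $\varepsilon$ (default 0.01) exists only to keep the
likelihoods finite at the deterministic predictions 0 and 1; the
winner is invariant to $\varepsilon$ across $(0, 0.1)$ for the extreme
observations, and exact ties return `"undetermined"` rather than an
arbitrary winner. The only appreciable confusion is a true
hyperdiploid-route sample whose nine disomic chromosomes all happen to
retain heterodisomy, probability $(2/3)^9 \approx 2.6\%$ — the tests
bound the observed confusion near this exact binomial tail.

```{r}
classify_mechanism(k_loh = 0, n_disomic = 9)
```

## Clonality and double-hit calling

A mutation's cancer cell fraction uses the standard purity/copy-number
correction

$$\mathrm{CCF} = \mathrm{VAF}\cdot
  \frac{\pi\,\mathrm{CN_t} + (1-\pi)\,\mathrm{CN_n}}{\pi\, m},$$

with multiplicity $m$ assigned by binomial maximum likelihood
(`assign_multiplicity()`; on a monosomic chromosome $m=1$ is forced).
Raw CCF above 1 is capped with the raw value retained, since sampling
noise and $m$ misassignment inflate it. The clonality threshold is 0.8
on capped CCF: any threshold in (0.63, 0.88] gives the same
clonal/subclonal split on the published eight-sample TP53 table (VAFs
0.42 and 0.59 subclonal, the rest clonal), and 0.8 is the
conventional midpoint; it is exposed in `pipeline_config()`.

`call_double_hit()` declares bi-allelic inactivation when two
independent hits cover both alleles — mutation + monosomy with LOH,
two mutations on a copy-neutral-LOH background, or homozygous deletion
— and orders the hits by clonality contrast: a subclonal mutation on a
clonal deletion means the deletion came first. Whole-chromosome
monosomies called from median BAF shifts are clonal-level events, so
the deletion's clonality defaults to clonal. Gene-to-chromosome
mapping is a small built-in table (TP53→17, CYLD→16, TRAF3→14),
extensible through the config; no annotation download is involved.

## What the simulator does and does not emulate

It emulates: heterozygous SNP panels on all 22 autosomes; the three
mechanisms' allele-specific copy states with replayable event logs;
binomial/Poisson read noise at configurable purity and depth; spiked
mutations with known multiplicity and CCF; serial pairs differing by
additional losses. It deliberately does not emulate sub-chromosomal
segments, whole-genome doubling, chromothripsis, sequencing-level
artifacts (mapping bias, GC waves), germline CNVs, or sex chromosomes.
Passing tests therefore demonstrate correctness of the inference
*under the whole-chromosome model*, not robustness to segmental
rearrangement — on real exomes a segmentation-based caller should
precede this pipeline whenever sub-chromosomal events are plausible.

Purity is a config input (default 0.9), not estimated: the intended
samples are CD138-selected and near-pure, and joint purity/ploidy
estimation is an explicit non-goal.

## Problem sizes and numerical choices

The test suite simulates 200 samples for copy-number recovery, 1,000
per mechanism for classifier recovery, 500 mutation replicates for CCF
recovery, and 10,000 karyotypes for the Monte-Carlo check of the 1/3
prediction — sizes at which Monte-Carlo error is well below every
asserted margin while the full suite runs in about a minute. All
randomness flows through explicit integer seeds; seeded operations
restore the caller's RNG stream, so results are reproducible
end-to-end and independent of call order.

## Known limitations

Whole-chromosome resolution only; no purity estimation; no support for
sex-linked genes in double-hit calling; the serial-sample comparison
is descriptive (lost/gained sets), not a statistical test of gradual
versus catastrophic loss — with two timepoints per patient there is no
power to separate those formally.
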