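---
title: "Discovering sex-linked markers and assigning the sex chromosome"
author: "SexLinkR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked markers and assigning the sex chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SexLinkR)
```

## The problem

Many poikilothermic vertebrates — frogs prominently among them — carry
homomorphic sex chromosomes that turn over repeatedly between chromosomes and
between populations of the same species. With no visible heteromorphy,
identifying which chromosome carries the sex-determining region is a
genotype-counting problem: genotype a family or population of known-sex
individuals at thousands of reduced-representation loci (DArTseq-style
co-dominant SNP calls plus dominant SilicoDArT presence/absence calls, each
locus backed by a short ~69 bp tag sequence), find the loci whose genotypes
track sex, and locate those loci by aligning their tags to the nearest
chromosome-scale reference genome.

`SexLinkR` implements that pipeline end to end, for both male-heterogametic
(XX/XY) and female-heterogametic (ZZ/ZW) systems, together with a synthetic
data generator that makes every stage testable at desk scale, including a
between-population Y-haplotype introgression scenario.

## The discovery model

Let a locus have calls in known-sex individuals (individuals of unknown sex
are carried in the matrices but never enter any statistic). Discovery runs in
four steps.

**Call-ratio filter.** The call ratio is the fraction of known-sex
individuals with a non-missing call. Loci *below* a threshold (default 0.8)
are removed; the boundary passes.

**Concordance under both systems.** Under a hypothesized system, the
heterogametic sex is expected heterozygous (SNP) or fragment-present (PA) and
the homogametic sex homozygous — either homozygote class — or
fragment-absent. For a SNP locus under XY,

$$
c_\mathrm{XY} \;=\;
\frac{\#\{\text{het males}\} + \#\{\text{homozygous females}\}}
     {\#\{\text{called males}\} + \#\{\text{called females}\}},
$$

and symmetrically for ZW and for presence/absence loci
(present-in-limited-sex plus absent-in-other-sex over called individuals).
Every locus is scored under both systems; it joins the candidate set when the
better of the two concordances reaches the threshold (default 0.8, boundary
inclusive) and both sexes have at least `min_called_per_sex` (default 3)
called individuals. An exact XY/ZW tie is ambiguous and drops the locus, with
a log line. The sub-100% threshold is what absorbs recombination between the
sex chromosomes, occasional phenotypic sex reversal, and genotyping error.

Counting over *all* called individuals (rather than per sex separately) is a
design choice: it makes the statistic a single fraction with a clean
denominator and treats a miscalled male and a miscalled female identically.

**Sex-limited allele and the false-positive test.** For a SNP candidate, the
sex-limited allele *b* is the heterozygote allele *not* matching the majority
homozygote class of the homogametic sex (a tie between the homozygote classes
leaves it undefined). Under true sex linkage *b* lives only on the Y (or W)
and is therefore never seen homozygously; the false-positive statistic is the
proportion of called known-sex individuals (both sexes) homozygous for *b*.
Candidates exceeding a threshold (default 0.05), or with an undefined *b*,
are flagged. Flagged loci stay in the set but are excluded from true-marker
counts. Dominant presence/absence candidates are exempt — homozygosity is
undefined for them — which matches the observation that published false
positives in this kind of bookkeeping are SNPs.

**Bookkeeping.** `summarizeDiscovery()` tabulates, per category
(male-heterozygous SNP, female-heterozygous SNP, male-present PA,
female-present PA): initial members, false positives, and true markers
(initial minus false positive), plus the four-category total.

```{r discovery-example}
sex <- c(rep("male", 10), rep("female", 10))
calls <- rbind(
  sexY  = c(rep(1L, 10), rep(0L, 10)),            # perfect XY locus
  noisy = c(rep(1L, 8), 0L, 0L, rep(0L, 8), 1L, 1L),
  auto  = rep(c(0L, 1L), 10)                      # autosomal
)
colnames(calls) <- sprintf("ind%02d", 1:20)
snp <- SnpGenotypes(calls, sex)
set <- falsePositiveTest(classifySexLinked(snp), snp)
markerTable(set)
summarizeDiscovery(set)
```

## Assigning the sex chromosome

Tags of the true markers are aligned to a reference genome. The built-in
mapper is deliberately simple and fully deterministic: exact `seed_k`-mer
seeding (default 21) against both strands, then ungapped scoring of the full
tag at each seeded placement; a hit requires the whole tag on the chromosome
and identity ≥ `min_identity` (default 0.90). Its documented sensitivity
guarantee is exact: any placement containing an exact 21 bp run is found.
There is no gapped extension, e-value model, or repeat masking — for real
data a BLASTn run can be substituted via `readAlignmentTab()` (standard
12-column tabular layout), and everything downstream is unchanged.

Markers whose hits name more than one chromosome are set aside; a marker with
several placements on a *single* chromosome still counts, because the
assignment names the chromosome, not the position. The modal chromosome among
uniquely assigned markers — with ties broken deterministically towards the
smaller chromosome id, and flagged — defines the sex chromosome, translated
to the study species by a correspondence map (default: reference chromosome
9 → species 7, 4 → 3, 13 → 13). Modal percentages are reported rounded
half-up to one decimal, the conventional printed style. A call is confident
when the modal fraction is at least `min_fraction` (default 0.5) and the
modal chromosome carries at least `min_markers` (default 3) markers — below
that, the call is still reported but marked low-confidence, mirroring how a
handful of markers on one chromosome is suggestive rather than conclusive.

## What the simulator emulates — and what it does not

`ScenarioConfig()` describes a scenario; `generateReference()` plus
`simulatePopulation()` realize it reproducibly under a seed. The generative
model:

* genotypic sex is assigned (XY males / XX females, or the ZW mirror);
  phenotypic sex flips with probability `sex_reversal` per individual —
  statistics see phenotypic sex, truth records both;
* autosomal SNPs: per-locus alternate-allele frequency ~ U(`maf_range`,
  default 0.05–0.5), genotypes at Hardy–Weinberg proportions;
* non-recombining sex-linked SNPs are fixed differences: homogametic sex
  a/a, heterogametic sex a/b. The sex-limited allele is labelled `b1`
  (alternate; homogametic sex homozygous reference) or `b2` (reference;
  homogametic sex homozygous alternate) with equal probability — a two-letter
  Y-haplotype alphabet that is recoverable from genotypes alone via the
  majority-homozygote rule, which is what makes haplotype sharing measurable
  downstream;
* a fraction `recomb_fraction` of sex-linked loci (SNP and PA alike)
  "recombine": they sit on the sex chromosome but segregate autosomally —
  recombination is a per-locus indicator, not a genetic-map crossover model;
* sex-linked PA markers are present exactly in the heterogametic genotypic
  sex; autosomal PA markers have a per-locus presence probability
  ~ U(0.3, 0.9);
* noise is layered last: each call is replaced by a uniformly chosen
  different non-missing state with probability `error_rate`, then set
  missing with probability `missing_rate`;
* every locus receives a tag copied verbatim from its true chromosome at a
  recorded position.

Default locus counts (2000 autosomal + 50 sex-linked SNPs; 200 + 10 PA) are
sib-ship-scale: presence/absence markers at roughly a tenth to a quarter of
SNP counts reflect the usual SilicoDArT-to-SNP ratio in this kind of survey.
Default noise (e = 0.02, m = 0.10, r = 0.10, s = 0) is the reference
condition used throughout the tests; observed rates of sex reversal and
sex-chromosome recombination in wild populations are not well measured, so
these are working values to be varied, not estimates.

Deliberately **not** modelled: sib-ship pedigree structure (individuals are
independent population draws, so Mendelian linkage within a family is
absent); polymorphic X haplotypes (sex-linked loci are fixed differences plus
noise); read-level artifacts (we simulate called markers, not reads);
mitochondrial sequences. A pipeline that passes on this generator is
validated for its counting and assignment logic — not for robustness to
pedigree-specific artifacts of real DArT reports.

`simulateIntrogression()` builds the Y-introgression scenario: a donor, a
recipient whose per-locus `b1`/`b2` labels are copied from the donor (the
introgressed haplotype), and an independent control; autosomal frequencies
are drawn independently everywhere. `sharedYAlleleFraction()` then measures
the fraction of index-matched sex-linked SNP loci with identical sex-limited
alleles — about 1 for donor vs recipient, about 0.5 (fair-coin matches) for
donor vs control. It is a desk-scale surrogate for the shared Y clusters a
population-structure analysis would show, and has both a truth route and an
inferred route (re-discovering alleles from the matrices).

```{r introgression}
mk <- function(seed) {
  ScenarioConfig(n_chrom = 4, sex_chrom = "chr2", chrom_length = 2000,
                 n_snp_autosomal = 60, n_snp_sexlinked = 50,
                 n_pa_autosomal = 10, n_pa_sexlinked = 0,
                 error_rate = 0, missing_rate = 0, recomb_fraction = 0,
                 seed = seed)
}
trio <- simulateIntrogression(mk(1), mk(2), mk(3), seed = 7)
c(donor_vs_recipient = sharedYAlleleFraction(trio$donor, trio$recipient),
  donor_vs_control   = sharedYAlleleFraction(trio$donor, trio$control))
```

## Numerical and edge-case choices

* **Boundaries are inclusive**: a call ratio or concordance exactly at its
  threshold passes ("below" is strict), and a false-positive statistic
  exactly at its threshold is not flagged (flagging is strict `>`). Small
  epsilons guard the comparisons against binary-representation noise.
* **Ties**: XY/ZW concordance tie → locus dropped as ambiguous;
  homogametic homozygote-class tie → sex-limited allele undefined → flagged;
  modal-chromosome tie → smaller chromosome id, flagged in the log.
* **Degenerate inputs**: loci with a sex at zero called individuals are
  skipped with a logged reason; an all-missing locus has call ratio 0; an
  empty candidate set summarizes to zeros; an assignment with nothing
  uniquely aligned has undefined modal fields and refuses to call a sex
  chromosome.
* **Sexes**: `unknown` individuals ride along in every matrix and export but
  are excluded from every sex-conditional count.
* **Rounding**: percentages use half-up rounding to one decimal, matching
  the printed style of the bar-chart summaries this package reproduces.
* **Determinism**: every stochastic operation takes a seed and restores the
  caller's RNG state; identical `(config, seed)` gives byte-identical
  written output.

## Definitions used by the validation suite

Two definitions are worth stating explicitly because they fix what the test
suite measures. A simulated non-recombining sex-linked locus counts as
*recovered* when it is classified into the candidate set with the correct
category — recovery measures the concordance filter, before false-positive
flagging. Conversely the *false-discovery proportion* in the no-sex-linked
null scenario counts only unflagged candidates among autosomal loci — the
false-positive test is part of the pipeline's specificity and is credited to
it. At the reference noise level a single erroneous homozygote in ~18 called
individuals (proportion 0.056 > 0.05) flags an otherwise perfect locus, so
roughly one in six true loci is flagged; that is the designed trade-off of a
strict false-positive threshold, and the reason recovery is defined upstream
of it.

Problem sizes in the suite: the reference-scenario check runs 50 seeded
replicates of the default configuration; oracle-equivalence checks use
matrices up to 8 individuals × 6 loci against per-individual enumeration and
references up to a few kb against an exhaustive position/strand scan; the
introgression check pools 500 sex-linked loci over five independent trios so
its exact-binomial bounds are not dominated by single-trio sampling noise.

## Limitations

The concordance and false-positive formulas are explicit, configurable
stand-ins for a family of similar published filters; exact thresholds differ
between studies. The mapper is a deterministic seeded substitute for a real
aligner and will under-report hits whose every 21-mer is broken by
mismatches (at default identity 0.90 over 69 bp this requires an unusual
mismatch spacing). No statistical test of sex association or multiple-testing
correction is performed — the pipeline is a filter cascade, as is standard
for this marker-count regime. And the generator's independence assumptions
mean that performance numbers quoted from it are upper bounds for real
sib-ship data.
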