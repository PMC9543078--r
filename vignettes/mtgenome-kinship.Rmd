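---
title: "Interpreting whole-mtGenome haplotype comparisons in maternal pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting whole-mtGenome haplotype comparisons in maternal pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokin)
```

## The interpretation problem

Mitochondrial DNA is inherited maternally and without recombination, so two
individuals connected by an unbroken chain of mothers are expected to carry
the same mtGenome haplotype up to the occasional germline mutation and to
heteroplasmy — the presence of two bases at one position within a single
individual. Forensic identification of historical remains leans on this:
a questioned sample is compared with a living maternal relative, often
separated by many meioses. The SWGDAM counting rule classifies a pairwise
comparison by the number of differing nucleotide positions:

* **0 differences** — *cannot exclude* a shared maternal lineage,
* **1 difference** — *inconclusive*,
* **2 or more differences** — *exclude*.

The rule was written for control-region Sanger data and close relatives.
`mitokin` implements the machinery needed to study how it behaves when the
comparison spans the entire ~16.6 kb mtGenome and distant relatives: a
haplotype representation with forensic nomenclature normalization,
frequency-threshold heteroplasmy calling, maternal-pedigree meiosis
counting, the pairwise comparison itself under two heteroplasmy-handling
conventions, and the binomial/contingency statistics used to summarize
outcome tables. Because cohort genotype data of this kind are restricted,
the package also ships a pedigree + transmission + sequencing simulator so
every stage can be exercised end to end from code alone.

## Haplotypes and nomenclature

A haplotype is stored as the set of differences from a circular reference
(1-based positions). The EMPOP-style token dialect is `A16247G` for a
substitution, `T146Y` for a point heteroplasmy (two-base IUPAC code),
`315.1C` for an insertion, `249DEL` for a deletion, and a lowercase
inserted base (`315.1c`) for length heteroplasmy. Normalization applies the
two conventions that matter for reproducible comparison:

1. **3′ shifting.** An indel inside a homopolymer run has many equivalent
   placements; `normalize_haplotype()` re-anchors it at the highest
   position on the light strand that yields the same edited sequence. The
   test suite checks this against a brute-force oracle that enumerates
   every placement by string comparison.
2. **C-stretch masking.** Homopolymeric cytosine tracts in the
   hypervariable regions (16183–16194, 302–310, 568–573 on a 16,569-base
   reference) vary in length within individuals and between tissues, so no
   attempt is made to interpret variation there: variants whose normalized
   position falls inside a masked range are dropped. The common 315.1C
   insertion anchors just outside the HVII range and therefore remains
   reportable.

The package does not bundle a real human reference sequence.
`synthetic_rcrs()` returns a deterministic synthetic 16,569-base stand-in
that carries the correct reference bases at the positions used in the
bundled examples and cytosine runs across the masked ranges; positions act
as labels, which is all the comparison logic needs. Users with the actual
reference supply it as FASTA via `read_reference_fasta()`.

## Heteroplasmy calling

`call_position()` implements a purely frequency-based rule: rank bases by
read count, compute the minor allele fraction (MAF) as the second count
over depth, and call heteroplasmy only when MAF is **strictly greater**
than the threshold (default 0.20 — the conservative choice used when
independent replicates for confirming low-level heteroplasmy are
unavailable; NGS itself can quantify heteroplasmy far lower). A count map
of `{A: 296, G: 74}` (MAF exactly 20%) is therefore homoplasmic A. Ties
for the top base are broken by the fixed order A < C < G < T so calls are
deterministic. `min_depth` defaults to 1 — no minimum coverage is
required — and positions below it become explicit no-calls that are
excluded from comparison on either side. Lowering the threshold can only
add heteroplasmic calls, never remove variants; this monotonicity is a
tested invariant.

## Meioses and pair enumeration

Pedigrees are plain tables (`id`, `mother_id`, `sex`, `family`,
`sampled`); only maternal links are used and they must form a forest. The
meiosis count between two individuals is the number of mother-to-child
transmissions on the path through their most recent common maternal
ancestor — 1 for mother and child, 2 for siblings. `enumerate_pairs()`
emits every unordered pair of sampled individuals within each maternal
clan; unsampled ancestors route paths but never pair. The implementation
is cross-checked against an independent graph-distance oracle on random
pedigrees.

`pedigree_from_histogram()` is a shape-matching helper: given a target
pairs-per-meiosis histogram it builds independent two-branch clans that
reproduce the histogram exactly, which is useful for studying the
published cohort's 2339-pair distribution (`ni_pair_histogram()`) without
its (unavailable) topology.

## Two comparison modes

`position_differs()` encodes the decision at the heart of the package.
Homoplasmic calls differ when the bases differ. When at least one call is
heteroplasmic:

* **isfg** — the shared-allele rule: no difference unless the allele sets
  are disjoint. R (= A/G) against homoplasmic G is concordant.
* **strict** — any allele-set inequality is a difference.

The isfg difference set is provably a subset of the strict one, so the
strict mode can only move pairs away from *cannot exclude*; this subset
property is tested on randomized haplotype pairs. Two heteroplasmies with
disjoint allele sets (e.g. R vs Y) count as a difference in *both* modes:
with no shared allele the rationale behind the shared-allele rule fails.
No such case has been observed in real cohort data, but the rule must
decide, and this choice is the conservative one. Discordant fixed-length
indels are a difference in both modes; a length-heteroplasmy call against
a concordant fixed-length insertion of the same base mirrors the
point-heteroplasmy logic (concordant in isfg, a difference in strict).

`compare_all()` evaluates every pair over the union of the two variant
position sets (all other positions agree by construction — an invariant
verified against a full position-by-position scan on small references)
and aggregates outcome counts plus a meioses-by-differences matrix.

## Statistics

`clopper_pearson()` and `wilson()` give two-sided 95% binomial intervals;
the exact interval uses Beta quantiles (lower bound exactly 0 at x = 0)
and the score interval uses z = `qnorm(0.975)` ≈ 1.959964 rather than
1.96, which is what reproduces published bounds at two decimals.
`pearson_chi2()` computes the Pearson statistic without continuity
correction, dropping degenerate all-zero margins with a warning and
reducing the degrees of freedom; it is cross-checked against
`chisq.test(correct = FALSE)`. `fisher_exact()` enumerates the
hypergeometric support for 2×2 tables and falls back to margin-preserving
Monte Carlo (via `r2dtable`, with reported standard error) for larger
tables; both routes are checked against independent enumeration.

## What the simulator emulates — and what it does not

`simulation_config()` defaults define the synthetic study conditions:

* **Shape** — 45 maternal families over 10 generations with the last 4
  generations sampled. Offspring counts are Poisson (means 0.7 daughters
  and 0.6 sons per mother, with the founding line always carrying one
  daughter so every clan reaches full depth). These means were chosen so
  that a default run lands near the published cohort's scale — roughly
  2,300–2,400 sampled pairs spanning up to ~16 meioses from a few hundred
  sampled individuals — while keeping runtimes in seconds. The real
  cohort's exact 2339-pair histogram is available separately through
  `pedigree_from_histogram(ni_pair_histogram())`.
* **Mutation** — de-novo substitutions at 0.002 and de-novo point
  heteroplasmies at 0.004 per transmission per genome, at uniformly
  random unmasked positions. The published cohort shows 9 variant
  positions arising across 345 transmissions, which constrains only the
  order of magnitude; these defaults reproduce "rare and private"
  variation without implying a calibrated per-site mutation rate.
* **Heteroplasmy drift** — a single binomial bottleneck: a heteroplasmy at
  MAF *m* is transmitted as Binomial(N~b~, m)/N~b~ with N~b~ = 30
  segregating units, converting to homoplasmy at draws of 0 or N~b~. The
  transmitted allele frequency is a martingale (tested by Monte Carlo) and
  the loss probability has the closed form (1−m)^N~b~. A single
  bottleneck was chosen over multi-round Wright–Fisher for transparency;
  N~b~ is configurable. De-novo heteroplasmies start above the calling
  threshold by default so they are observable; `maf_floor` can be lowered
  to seed sub-threshold heteroplasmies that the 20% rule reports as
  homoplasmic substitutions — the miscall scenario that motivates the
  shared-allele recommendation.
* **Sequencing** — per-position depth is log-normal around a median of
  370× (σ~log~ = 0.33, the value for which the bulk of draws falls inside
  the published 139–1316× range before clipping), and reads are
  multinomial draws from the true allele mix with a 0.001 per-base error
  spread uniformly over the other bases.

The simulator deliberately does **not** reproduce: real pedigree topology
(clan sizes are homogeneous rather than the real mix of tiny and huge
families), linked or recurrent mutation, haplogroup structure, tissue
differences in heteroplasmy, strand bias, or alignment artefacts. Passing
end-to-end tests therefore demonstrate that the interpretation logic is
correct under the stated model, not that the calling rule is robust to
every failure mode of real sequencing.

## Numerical and degenerate-input choices

* MAF comparisons use strict inequality (`> threshold`), making the
  boundary case deterministic.
* Top-base ties: fixed order A < C < G < T; at counts exactly equal the
  MAF is 0.5.
* Three- and four-base ambiguity codes are rejected rather than
  truncated: no two-allele interpretation exists for them.
* A pedigree with a maternal cycle, a dangling `mother_id`, or a male
  listed as a mother fails validation loudly.
* `pearson_chi2` keeps cells with expected count 0 out of the statistic
  by dropping degenerate margins, with the df reduced to match.
* Reports regenerate byte-identically from the same inputs and seed
  (tested), and all simulation randomness flows from the mandatory seed
  through a local RNG scope that leaves the caller's RNG state untouched.

## Worked example

The deterministic two-clan fixture reproduces the published case
structure: a 7-member family with one private HVI substitution carrier
and a 59-member family with one private coding-region substitution
carrier plus two point-heteroplasmy carriers.

```{r fixture}
ref <- synthetic_rcrs()
fx <- build_two_family_fixture(ref)
report <- run_study(fx$pedigree, fx$haplotypes, study_config(), ref)
report
report$variant_table
```

Under the shared-allele rule the 64 inconclusive pairs are exactly the
pairs involving one of the two substitution carriers (6 + 58), and there
are no exclusions; counting heteroplasmy as a difference turns the two
heteroplasmy carriers' pairs into additional inconclusives and creates
false exclusions in the pairs where a heteroplasmy carrier meets the same
family's substitution carrier (two differing positions).

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
scales used throughout this vignette: the 66-individual/1732-pair
fixture, simulated cohorts of up to ~45 families (~2,400 pairs), the
27,553-individual histogram-shaped pedigree, and Monte-Carlo checks of
20,000 replicates for interval coverage and 10,000 transmissions for the
drift martingale. All of these complete in well under a minute each.

## Limitations

Classification is purely count-based: no haplotype-frequency or
likelihood-ratio weighting of matches, no haplogroup assignment, no read
alignment or BAM ingestion, and no modelling of the human review steps
(electropherogram peak inspection, independent Sanger confirmation) that
accompany real casework. The statistics module intentionally stops at the
tools a guideline-evaluation study needs — binomial intervals and two
contingency tests — with no multiplicity correction.
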