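---
title: "Verifying maternal and paternal lines in a closed stud with uniparental markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying maternal and paternal lines in a closed stud with uniparental markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studlines)
```

## The problem

Historical studbooks record maternal families by name, and in a closed
conservation stud those names are the backbone of the mating scheme: matings
are arranged so that every classical female family and every classical sire
line stays represented. Handwritten records spanning two centuries, however,
accumulate transcription errors. Mitochondrial DNA offers an independent
check: it is transmitted strictly from dam to offspring, so every member of
a true matriline must carry the same mtDNA haplotype. When several
haplotypes turn up inside one recorded family, some of its members are in
the wrong family on paper. The male-specific region of the Y chromosome
(MSY) plays the mirrored role for sire lines.

`studlines` implements this verification pipeline end to end: variant
calling of D-loop control-region sequences against a fixed reference
coordinate frame, clustering of identical variant profiles into named
haplotypes, an iterative procedure that associates each haplotype with one
pedigree family, retention reporting, three-locus MSY haplotyping, and the
probability-of-gene-origin statistics used to monitor how culling decisions
move a closed population's genetic diversity.

## Coordinate frame and variant calling

All positions are 1-based nucleotide positions ("np") on the reference
frame; no 0-based coordinate is ever exposed. The default frame places the
D-loop at np 15445–16660, split into the upstream hypervariable region (UP,
np 15445–16153) and the downstream region (DOWN, np 16154–16660), with an
8-bp tandem-repeat array at np 16129–16153.

`anchor_align()` aligns a query semi-globally (the full query must land
inside the reference; ends of the reference are free) and reports variants
in reference coordinates. Choices that matter:

* **Alignment scoring.** Unit match, `-1` mismatch, affine gaps (open 4,
  extend 1). No published alignment parameters exist for this task; these
  are ordinary values for near-identical mitochondrial amplicons, and the
  results are insensitive to them because queries differ from the reference
  by a handful of substitutions. A configurable score floor (default half
  the query length) rejects unalignable input; a configurable minimum
  D-loop overlap (default 50 positions) rejects uninformative fragments.
* **Repeat array exclusion.** Length heteroplasmy makes the repeat-copy
  count irreproducible between sequencing runs, so positions inside the
  repeat interval are excluded from variant output, coverage, and haplotype
  identity.
* **IUPAC ambiguity codes** (including `N`) are non-calls: the position is
  dropped from the sample's coverage rather than guessed. This is the
  conservative choice for haplotype identity.
* **Indels** are left-aligned against the reference, the usual
  normalisation so that the same event is always reported at the same
  position.

## Haplotype identity under coverage gaps

A haplotype is a named variant set plus a coverage mask. Real
control-region data have "nd" windows (the packaged catalogue reproduces a
missing np 16320–16399 window on eight of ten haplotypes), so identity is
defined on the *intersection* of coverages: a sample matches a catalogued
haplotype iff their variant sets agree wherever both are covered. Three
consequences, all deliberate:

* a gapped sample consistent with exactly one catalogued haplotype is
  merged into it — coverage gaps never mint new haplotypes;
* a sample whose coverage cannot separate two catalogued haplotypes returns
  the ambiguity set rather than an arbitrary pick;
* a sample matching nothing mints a new name under a configurable
  prefix/suffix convention (default `HTnn_ASCAL_ITA`).

Polymorphic sites are counted in two modes: `among` (two or more distinct
states among covering haplotypes; positions covered by fewer than two
haplotypes are skipped) and `reference` (any covering haplotype differs
from the reference). `among` is the default because between-haplotype
variability is what the family analysis uses; the reference mode is kept
because motif tables are usually printed reference-relative.

Haplogroup classification is a pure rule engine: each rule is a diagnostic
variant motif with a unique priority, and the highest-priority rule whose
motif is fully present *and covered* wins. The package ships fixture rules
matched to its synthetic catalogue (G and L as three-haplotype groups, B,
C, M, Q as singletons); genuine nomenclature motifs must be supplied by the
user, since they are external reference data, not something this package
can derive.

## The assignment procedure

`assign_families()` resolves the family-by-haplotype contingency table into
a one-to-one association. A haplotype's *support* is the set of families in
which it was observed and that no other haplotype has already claimed. The
procedure iterates two rules to a fixed point:

* **Rule A — uniqueness / exclusion.** Any haplotype whose support is a
  singleton takes that family. This is applied repeatedly, because each
  assignment can shrink someone else's support to one.
* **Rule B — majority.** When rule A stalls, open haplotypes are ranked by
  their largest support count, then by the margin over their second-best
  family, then by name; the first with a *unique* most-frequent family
  takes it, and control returns to rule A.
* **Ties.** Only when no open haplotype has a unique most-frequent family
  does the top-ranked one take its tied family set jointly (both families'
  mares then count as matching). Tied families are withheld from other
  supports only when those supports retain an alternative.

Deferring tied haplotypes while any unique-majority candidate remains is a
deliberate design decision: assigning a tied set eagerly would freeze
families that a later majority step disambiguates, and on the packaged
worked example it would block the exclusion chain that resolves the last
open haplotypes. With the deferred rule the procedure reproduces the
worked-example map exactly and, as `matching_oracle()` verifies by
exhaustive enumeration, attains the maximum possible number of retained
mares (55 of 93) under the constraints that every family keeps a haplotype
and every haplotype keeps a family. The procedure is deterministic and
invariant to row and column permutations of the table.

Percentage frequencies are rounded half-to-even to one decimal. The
packaged frequency row is anchored only on the cells that are arithmetic
consequences of their counts.

## MSY typing

Three loci (YE3, YE17, YXX) are each typed at one diagnostic position after
the same semi-global alignment, giving `reference`/`variant`/`missing`
states. The rule table maps all-reference to HT01, a lone YE17 variant
(np 1277) to HT02, and a lone variant at the configured third locus to HT3.
Which of YE3/YXX defines HT3 is configuration with YXX as the documented
default, and the packaged tests always inject it explicitly. Samples with
every locus missing are uncallable and are excluded from frequency
denominators rather than silently biasing them.

## Probability-of-gene-origin statistics

All pedigree statistics describe a *reference population*, defaulting to
the individuals with no recorded progeny (the usual stand-in for "living
animals" in an active studbook; an explicit id list overrides it, and the
simulator provides its final generation via `stud_reference_ids()`).

* **Inbreeding** `F` is half the additive relationship between the parents,
  computed by the recursive tabular kinship method; an unknown parent
  contributes no identity by descent. The test suite checks it against an
  independent Wright path-counting oracle — exact agreement, not a
  tolerance band.
* **Equivalent founders** `f_e = 1 / sum(q_k^2)` over expected founder
  genome proportions. An unknown single parent becomes a phantom founder
  unique to that individual, the standard treatment that keeps
  `sum(q_k) = 1`.
* **Effective ancestors** `f_a = 1 / sum(p_j^2)` over marginal
  contributions selected greedily. Each round is two linear passes: an
  upward pass giving, for every candidate at once, the probability that a
  reference gene descends from it without passing through an already
  selected ancestor, and a downward pass discounting the part of the
  candidate's own genome that selected ancestors already explain.
  Candidates are the strict ancestors of the reference population. The
  stopping rule (residual contribution below `eps = 1e-6`) is configuration
  because no published stopping criterion exists for this statistic; at
  that threshold the selection has explained the gene pool to numerical
  completeness.
* **Founder genome equivalents** `N_g` by gene dropping: two uniquely
  labelled alleles per founder, Mendelian transmission per replicate,
  `N_g = 1/(2 * mean(sum(p_a^2)))` over the reference gene pool. The seed
  is mandatory, results are bit-for-bit reproducible, the default is
  10,000 replicates, and the Monte-Carlo standard error is always reported
  (delta method on the replicate mean). The suite checks the trio pedigree
  against exact enumeration of the four possible transmissions at 100,000
  replicates.

These satisfy `N_g <= f_a <= f_e <=` total founders on every valid
pedigree, which the suite asserts on simulated studs.

`matriline_expected_haplotype()` propagates foundress haplotypes strictly
through dam links; a dam line broken by a lost record is `untraceable`, and
a matriline ending in an unmapped founder is reported as such rather than
guessed.

## What the simulator emulates — and what it does not

`stud_scenario()` / `simulate_stud()` generate a closed multi-generation
pedigree under conservation management: per-family female quotas and a
capped stallion pool each generation (this is what actually keeps all
matrilines alive in a small closed stud), strict dam-to-offspring haplotype
transmission, family-label recording errors at rate `label_error_rate`
(the *label* is switched, never the transmitted haplotype — discordance in
this model is always a pedigree error, matching how the analysis interprets
it), and lost parent records at rate `missing_parent_rate`. Default scale —
11 families, 3 foundresses each, 6 founder stallions, 8 generations, ~44
breeding females per generation — mirrors a small national conservation
nucleus. Poisson(4) offspring per mare keeps matriline extinction rare;
extinct runs are retried boundedly with a warning, and everything is
deterministic under the mandatory seed.

The packaged motif catalogue is *synthetic* (deposited haplotype sequences
are not bundled): ten substitution motifs constructed to carry the study
system's regional structure — 55 among-haplotype polymorphic sites in UP
and 8 in DOWN, shared variants defining the G and L haplogroup trios,
identical DOWN states inside {Allegra, Wera} and {Capriola, Slavina,
Dubovina, X}, and the nd window on eight of ten haplotypes. Passing tests
on these fixtures demonstrates that the machinery is correct on data with
the right shape; it does not validate the biological content of any real
catalogue, and real analyses must build their catalogue from genuine
deposited sequences.

The simulator deliberately omits: mutation along matrilines (haplotypes are
fixed per family, as the verification logic itself assumes), overlapping
generations, unequal sex ratios, and selection on anything but family
quotas. Error flagging at sensitivity 1 therefore requires distinct family
motifs (`ascal_family_map(distinct_families = TRUE)` gives the eleventh
family its own synthetic haplotype); with the shared-haplotype default, two
families are indistinguishable by construction, exactly as in the system
being emulated.

## Problem sizes and numerical choices in the shipped checks

The test suite and acceptance script run at deliberately modest sizes so a
full check stays in the low minutes: 93-sequence re-clustering for the
worked example; 100 random generation-structured pedigrees (about 40
individuals each) for the path-counting comparison; simulated studs of a
few hundred to a few thousand animals for the invariant and error-recovery
checks; 100,000 gene-dropping replicates only on the three-individual trio
where enumeration is exact. The dense kinship table is quadratic in
pedigree size and is guarded at 6,000 individuals; larger studbooks should
be subset to the ancestry of the reference population first.

## Known limitations

* Haplogroup motifs and MSY diagnostic positions are configuration, not
  knowledge the package owns; the shipped defaults are stand-ins for
  testing.
* The haplotype-family association a run produces is valid only within the
  stud analysed; labels are not harmonised across studbooks.
* The retention logic treats every haplotype/family discordance as a
  pedigree error; biological events (e.g. a genuine new mutation) would be
  flagged the same way.
* The exhaustive matching oracle enumerates feasible assignments and is
  intended for tables up to roughly 12 x 12.
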