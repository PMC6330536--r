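---
title: "Methods: single-dose marker genetics for autopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-dose marker genetics for autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octomap)
```

## The problem

Highly autopolyploid genomes — the motivating case is an octoploid crop with
2n = 8x and essentially random pairing among its eight homologs — defeat
diploid genotyping: a biallelic locus can carry the alternative allele in
zero to eight copies, and read counts alone rarely resolve the dose.  The
classical workaround, which this package implements end to end, is to map
only *single-dose* (simplex) alleles.  In an F1 cross of two heterozygous
parents (a pseudo-testcross), an allele present on exactly one homolog of
one parent and absent from the other segregates 1:1 among progeny, exactly
like a backcross marker, so standard two-point linkage applies.

## Dosage and segregation model

With ploidy $2m$ and random chromosome segregation, a gamete samples $m$ of
the $2m$ homologs without replacement.  For a parental dose $d$ the
probability a gamete carries none of the $d$ copies is hypergeometric:

$$P(\text{absent}) = \binom{2m-d}{m}\Big/\binom{2m}{m},$$

giving absence fractions 1/2, 3/14, 1/14 and 1/70 for $d = 1..4$ in an
octoploid.  We implement these as exact binomial-coefficient ratios
(`gamete_absence_prob()`); `choose()` is exact for these small integers, so
tests can assert equality against a brute-force enumeration of all
$\binom{8}{4}$ gametes.  The model deliberately excludes double reduction
and preferential pairing: the package targets autopolyploids whose
homologs pair at random, and the simulator's meiosis (random bivalent
pairing, one recombinant product per bivalent) reproduces the
hypergeometric law exactly at a single locus.

Pooling reads across a transmission-balanced cross samples the 16 parental
haplotypes uniformly, so a single-dose site shows minor:major odds of 1:15
(`pooled_minor_fraction()`), and the chance of observing the minor allele
at least once among $n$ pooled reads is $1-(15/16)^n$; 72 reads reach 99%
(`min_depth(1/16, 0.99)`).

## SNP screening from pileups

The caller consumes a minimal 6-column mpileup dialect (sequence, 1-based
position, reference base, depth, read bases, Phred+33 qualities; no
indels).  Design choices, with defaults:

* base quality: only calls with Phred > 28 are counted;
* per-sample coverage prefilter: filtered depth > 7, otherwise the sample
  is missing at the locus;
* merged-progeny screen: minor/major count ratio inside the inclusive
  window [1/30, 1/6] around the expected 1/15, at merged depth ≥ 72
  (from the detection formula above); the deliberately generous window
  absorbs depth variation and homolog expression bias, at the cost of
  admitting some duplex sites (pooled ratio 2:14 ≈ 0.143), which the
  segregation filter removes downstream;
* multi-allelic guard: third-allele reads above 1% of depth reject the
  site (the source screen does not specify this; it is our robustness
  choice);
* parent of origin: the informative parent's own ratio must fall in the
  same window while the other parent's minor fraction stays ≤ 1%;
  anything else is ambiguous and excluded from maps;
* per-progeny calls: presence needs ≥ 2 minor reads (one read is too
  error-prone at ~0.2% sequencing error); an *absence* call additionally
  needs enough depth to have detected a within-individual single-dose
  allele ($p = 1/8$): `min_depth(1/8, 0.95)` = 22 reads.  Shallower
  samples are missing, not absent.  Without this rule, low-coverage
  carriers are systematically under-called, which drags duplex markers'
  presence fractions into the 1:1 acceptance band and inflates the
  false-single-dose rate.

## Marker QC and binning

Markers pass QC when the presence fraction among non-missing progeny lies
in [0.3, 0.7] and at least 39 individuals are genotyped.  (The source
description couples "39 individuals" with "less than 10% missing", which
is arithmetically tense for 59 progeny; we expose them as independent
knobs: ≥ 39 genotyped for QC, ≤ 10% missing to be binnable.)  Bins join
markers whose calls conflict at ≤ `max_conflicts` (default 0) jointly
genotyped progeny *in either phase orientation* — a presence vector and
its complement describe the same locus in coupling vs repulsion — via
greedy leader clustering over id-sorted markers.  Greedy leaders, rather
than transitive closure, prevent conflict chaining when `max_conflicts`
is raised; sorting first makes the order-dependence reproducible.  The
bin representative is the member with least missing data, ties to the
smallest id.

## Linkage grouping and ordering

Two-point statistics resolve phase by mismatch minimisation
($R = \min(M, n-M)$) and use the standard 1:1 LOD
$(n-R)\log_{10} 2(1-\hat r) + R\log_{10} 2\hat r$.  Groups are connected
components at LOD ≥ 6; bins left single are rescued into the group of
their strongest link if that LOD ≥ 4, an interpretation of the
strongest-cross-link rescue used with JoinMap-style grouping.  Multipoint
regression mapping is *not* reimplemented; ordering is a documented
heuristic — greedy chain extension from the strongest pair, appending at
whichever end minimises the recombination fraction, then 2-opt reversal
refinement on the sum of adjacent fractions — validated against
simulation truth (exact order recovery at n = 200 for 10 cM spacing).
Positions are cumulative Kosambi distances,
$d = 25\ln\frac{1+2r}{1-2r}$; adjacent fractions are capped at 0.4999 so
an unlinked neighbour cannot produce an infinite map.  Pairs sharing
fewer than 10 genotyped progeny are not scored.

## Synteny and rearrangements

Each mapped marker anchors to a chromosome of the diploid reference via
its gene model.  A linkage group's homologous group is its anchored-marker
majority chromosome (ties: longest run of map-adjacent markers, then
lowest chromosome id, flagged); markers anchored there are congruous, and
the overall congruous fraction is the marker-weighted mean across groups.
A group carrying ≥ 3 markers anchored to a single foreign chromosome
witnesses an interchromosomal rearrangement; unplaced-scaffold anchors
("other") count in totals but never in majorities or events.  Events are
matched across two species by unordered chromosome pair, listed at
linkage-group level but de-duplicated per species for matching, and the
shared percentage is shared events over all events of both maps.  Foreign
markers need not be map-adjacent (an optional run constraint is easy to
add but the detection rule itself does not require it).  Note the method's
intrinsic blind spot: if a translocated block maps as a fragment with
little or no native context, its group's majority *is* the source
chromosome and no event can be called — our acceptance checks therefore
require ≥ 3 moved markers *and* ≥ 3 native target-chromosome markers in
one group before demanding detection.

## Ks dating

Ortholog pairs are reciprocal best hits under global protein alignment
(BLOSUM62, gap opening 10, extension 0.5; ties drop the query), aligned
codon-wise by back-translating the protein alignment and removing gap
columns, and kept when the aligned length *exceeds* half the reference
ortholog.  Redundancy is handled by exact-duplicate removal — a
deterministic stand-in for identity clustering.  Synonymous divergence
follows the counting method: synonymous sites are the per-position
fraction of synonymous one-step changes (denominator 3 per position;
changes into stops are non-synonymous), averaged over the two sequences;
differences average equally over all minimal mutational pathways that
avoid stop codons (with an unrestricted fallback if all are blocked —
only reachable for some two/three-step pairs); and
$K_s = -\tfrac34\ln(1-\tfrac43 p_s)$ corrects multiple hits, undefined at
$p_s \ge 3/4$.  Divergence time is $T = \tilde K_s / (2\mu)$ with the
grass synonymous rate $\mu = 6.5\times10^{-9}$ per site per year; the
median uses the lower value for even counts (a documented convention —
dating sources are typically silent on it).

## The simulator: what it emulates, and what it does not

`simulate_cross()` generates a 10-chromosome gene space, spikes variant
sites into one of two octoploid parents with dose mixture 70/20/7/3% for
simplex..quadruplex, runs random-bivalent meiosis with Poisson crossovers
(Haldane-style, no interference: crossover count per bivalent has mean
L/100), optionally injects translocations (blocks of ≥ 3 genes; shared
events hit both species), and writes mpileup text per individual.

Sequencing depth is modelled in two layers: a lognormal per-gene
expression level shared by every library (sdlog 0.25 by default), and
individual-level negative-binomial noise around it (size 60, a depth CV
of ~25% at the mean of 40 reads/gene).  The shared layer is what makes
whole markers drop out together — the dominant failure mode of RNA-seq
maps — while the individual layer drives per-sample missingness.  Real
transcriptomes vary far more than sdlog 0.25 across genes; the simulated
spread should be read as "genes expressed well enough to be mappable",
which is the population the screen operates on anyway.  Passing tests on
this simulator therefore demonstrates correctness of the machinery under
its stated model, not robustness to the full dynamic range, allele-specific
expression, splice isoforms, alignment artefacts or reference bias, none
of which are modelled.  Optional per-haplotype expression weights exist
for the parents (homolog expression dominance) but default to uniform and
are not propagated to progeny.

Every stage draws from an RNG stream derived deterministically from the
config seed, so a `(seed, config)` pair reproduces the dataset
byte-for-byte.

## Problem sizes used by the test suite

The end-to-end acceptance run simulates 59 progeny, 600 genes over
10 chromosomes (~3200 variant sites, ~2250 of them single dose), and five
24-gene translocations (three shared between the species); segregation
checks use ≥ 5000 sites, recombination checks 2000 meioses, ordering
checks 200–500 individuals, and Ks recovery 200 pairs of 300 codons at
true Ks 0.01 and 0.1.  These sizes give the property checks comfortable
statistical resolution (3-SE bands, chi-square at α = 0.001) while a full
`devtools::test()` stays well under a minute.

## Known limitations

* Dosage is screened, never estimated by likelihood; markers outside the
  ratio window are simply unused.
* Grouping purity is high but not perfect: a duplex marker that slips
  both the parent window and the segregation filter can join a simplex
  group through its shared carrier homolog (observed at ~1% of groups at
  n = 59).
* The ordering heuristic has no goodness-of-fit locus removal; with
  sparse or noisy bins local order inversions survive 2-opt.
* Ks saturation ($p_s \ge 3/4$) is an error by design, so deep
  divergences must be filtered before dating.
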