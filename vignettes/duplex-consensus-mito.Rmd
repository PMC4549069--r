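---
title: "Duplex consensus calling and mitochondrial mutation spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling and mitochondrial mutation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoduplex)
library(dplyr)
```

## The problem

Conventional short-read sequencing has a background error frequency of
roughly $10^{-2}$ to $10^{-3}$ per base, so it can only detect mitochondrial
variants that are already clonal within a sample. Most somatic mtDNA
mutations are not: they sit on a small fraction of the hundreds to thousands
of genome copies per cell. Duplex sequencing solves this by tagging each
double-stranded DNA fragment with a random double-stranded barcode before
amplification, sequencing many reads per strand, and only scoring a mutation
when it appears as complementary substitutions on *both* strands of one
source molecule. `mitoduplex` implements that consensus logic and the
downstream mitochondrial mutation analyses as composable, tibble-in /
tibble-out functions.

## The consensus model

Reads that share a duplex tag and strand order form a **single-strand
family**. Two layers of consensus remove the two error layers:

1. **SSCS** (single-strand consensus sequence). At each position of a
   co-aligned family of $n \ge$ `min_family_size` reads, the most frequent
   base is called if its fraction of non-`N` calls is at least
   `consensus_threshold`, otherwise `N`. This removes *independent*
   sequencing errors: an error private to one read of three can never reach
   a 0.7 threshold.
2. **DCS** (duplex consensus sequence). The two complementary families of a
   molecule are matched through the canonical tag (the lexicographically
   smaller of the barcode's two half-orders). Over the reference overlap,
   the DCS carries the agreed base and `N` wherever the strands disagree or
   either is `N`. This removes *strand-lineage* artifacts — PCR errors from
   the first amplification rounds that are shared by every read of one
   strand family but, being single-stranded events, almost never replicate
   independently on the partner strand.

Indel events obey the same two rules: family support at the threshold
fraction, then presence on both strands.

The first five 5' bases and last six 3' bases of every consensus are clipped
before any counting, because end repair and ligation chemistry concentrate
artifacts at fragment termini; a 100-bp consensus therefore contributes 89
evaluable positions.

## Clonality tiers and the frequency definition

DCS calls are piled up on the circular L-strand reference (1-based
coordinates; position $L+1$ wraps to 1). Each (position, alternate allele)
with at least one mutant call at a position of depth $\ge$ `min_depth`
becomes a variant with

$$\text{clonality} = 100 \cdot \frac{\text{mutant DCS calls}}{\text{DCS depth}}\ (\%)$$

classified as **rare** (0–0.5%], **low-heteroplasmic** (0.5–20%],
**high-heteroplasmic** (20–95%) or **homoplasmic** [95–100%]. The tier
mutation frequency is the number of *unique* mutants divided by the total
sequenced nucleotides: a mutant is scored once per (position, alt) no matter
how many molecules carry it, and two different alternate alleles at one
position are two mutations (the type-resolved spectra require alt-resolved
counting). Wilson score intervals accompany every frequency because they
remain well-behaved at the zero and near-zero counts that dominate this
regime.

## Spectra

The 12 substitution types are kept in L-strand orientation so that strand
bias — unequal prevalence of a type and its complement, e.g. `G>A` versus
`C>T` — stays visible; each type's denominator is the number of sequenced
nucleotides whose reference base is the type's source base. The 6-type
collapse sums complementary pairs and reports percentages of all point
mutations. Trinucleotide context spectra use the canonical pyrimidine-centred
(COSMIC-style) 96-class frame: purine-centred mutations are
reverse-complemented into it, so each mutation maps to exactly one class and
complements are never double counted. Comparisons between samples — tier
frequencies, type frequencies, context fractions — all use the two-sample
proportion test with continuity correction (Yates-corrected $\chi^2$, df 1,
two-sided); rank comparisons use the Mann–Whitney U test and associations
use Spearman or Pearson correlation, matching the routines a practitioner
would call in base R.

## Coding consequences

Translation uses the vertebrate mitochondrial code (NCBI table 2: `TGA`
Trp, `ATA` Met, `AGA`/`AGG` stop). `expected_ns_fraction()` enumerates all
three alternative bases at every protein-coding position with equal weight
and returns the nonsynonymous fraction — the no-selection null for the
observed nonsynonymous share of mutated codons. Design choices:

* **Incomplete stop codons** (completed by polyadenylation in mt mRNAs) have
  no unambiguous genomic codon and are excluded from codon arithmetic.
* **Overlapping protein genes** (ATP8/ATP6, ND4L/ND4): a substitution is
  evaluated independently in each gene and each (position, alt, gene) triple
  counts once, which matches per-gene burden reporting.
* Stop gains and losses count as nonsynonymous; stop-to-stop is synonymous.

For the real human mtDNA coding sequence this enumeration gives about
75.7%. The packaged reference, however, is a **synthetic stand-in** (see
below), whose iid-composition ORFs give about 77.2% — real codon usage,
which the stand-in does not reproduce, is what pulls the genome-wide value
down. Analyses that need the real expectation should point
`load_reference()` at a genuine NC_012920 FASTA; everything downstream is
reference-agnostic.

## The synthetic reference

No raw data accompany this package, and the bundled genome is generated, not
downloaded: `make_synthetic_rcrs()` builds a 16,569-bp circular sequence
carrying the standard 37-gene human annotation (22 tRNAs, 2 rRNAs, 13
protein genes, control region 16024–16569 plus 1–576) with bases drawn iid
from the documented rCRS composition (A 0.309, C 0.313, G 0.131, T 0.247)
and protein ORFs built codon-wise with in-frame stops rejected, an ATG
start, and a TAA stop where the gene length permits. Codons already written
by an earlier overlapping gene are left untouched. The stand-in reproduces
the genome's size, layout, gene sizes and composition — so coordinate
arithmetic, strand handling, the noncoding share and per-gene burden scale
correctly — but not the real sequence or codon usage. Files are labelled
`synthetic_rcrs` throughout.

The annotated noncoding share is the control region (1122 bp, 6.77%); the
~89 intergenic nucleotides between genes are tallied separately as
`intergenic_bp` rather than folded into that figure.

## The read simulator

`simulate_population()` + `simulate_duplex_reads()` emulate the data the
consensus caller actually sees:

* each planted variant rides on each molecule independently with probability
  clonality/100, so realised carrier counts are binomial and recorded as
  truth;
* every molecule gets a fresh duplex tag and two strand families whose sizes
  come from a configurable distribution (default log-normal around 4,
  because real family sizes are heavy-tailed; `constant` is available for
  controlled experiments);
* PCR-lineage errors (default $10^{-4}$/base) are applied to the strand
  template *before* reads are sampled, so they are shared within a strand
  family and survive SSCS but not DCS — exactly the artifact class duplex
  pairing exists to remove;
* sequencing errors (default $10^{-2}$/base, the upper end of the standard
  short-read background) are independent per read;
* everything derives from one seed and is bit-identical across reruns.

What the simulator does **not** model: base-quality strings, alignment and
mapping artifacts, nuclear mitochondrial insertions (NUMTs), context- or
cycle-dependent error profiles, chimeras, and any indel error beyond a
single configurable event class. Passing tests therefore demonstrate the
correctness of the consensus and counting logic under the stated error
model, not robustness to every artifact of real libraries.

Problem sizes used by the test suite and the acceptance script are chosen to
make the statistics decisive at desk scale: the background-floor experiment
uses 25,000 molecules × 2 strands × 3 reads of 100 bp (≈2.1 million DCS
nucleotides after clipping and masking), at which scale the expected number
of duplex-surviving artifacts is ≈0.002, so observing zero DCS mutations is
the overwhelmingly likely correct outcome while the SSCS layer still shows
its ≈$10^{-4}$ PCR-driven floor. Tier recovery uses 5,000 full-length
molecules so that a 0.2% clonality realises 5–20 carriers with probability
>0.9999.

## Numerical conventions

* Consensus ties resolve alphabetically, which is unreachable at thresholds
  above 0.5 and therefore never decides a call.
* Positions whose DCS calls are all `N` vanish from pileups and from
  denominators; positions below `min_depth` stay in denominators but yield
  no tiered calls (a 50-deep position cannot distinguish 0.5% from 2%).
* Degenerate 2×2 tables (both counts zero, or both saturated) are reported
  as "no evidence" (p = 1) in sample comparisons rather than erroring.
* A tier with zero mutants reports frequency 0 with Wilson lower bound
  exactly 0; `k = n` gives upper bound exactly 1.
* Correlation of gene size with nonsynonymous burden needs ≥3 genes and
  nonzero variance; otherwise it is reported as not estimable.

## Known limitations

The package consumes *aligned* reads — alignment, local realignment and
quality trimming happen upstream. Heteroplasmy phasing across positions,
copy-number inference, NUMT filtering, haplogroup calling and mutational
signature decomposition are out of scope. The known-variant lookup is a
user-supplied static snapshot; nothing is fetched at run time.
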