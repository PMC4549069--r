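# mitoduplex

Duplex-consensus mutation calling and mutation-spectrum analysis for the
human mitochondrial genome, for researchers measuring somatic mtDNA
mutations far below the detection limit of conventional short-read
sequencing.

Standard NGS carries a background error frequency of 10⁻²–10⁻³ per base, so
it only sees variants that are already clonal. Duplex sequencing tags every
double-stranded fragment with a random double-stranded barcode, builds a
**single-strand consensus sequence (SSCS)** from each strand family
(majority base at fraction ≥ *t*, default *t* = 0.7, families of ≥ 3
reads), then pairs the two complementary SSCS of one molecule into a
**duplex consensus sequence (DCS)** that keeps only bases on which both
strands agree. Independent sequencing errors die at the SSCS stage;
PCR-lineage artifacts shared within one strand family die at the DCS stage,
leaving a background below 5×10⁻⁸. Consensus ends are clipped (5 bases 5',
6 bases 3') before counting.

Per position, variants are tiered by clonality
*c* = 100·(mutant DCS calls)/(DCS depth):

| tier | clonality |
|---|---|
| rare | 0 < c ≤ 0.5% |
| low-heteroplasmic | 0.5 < c ≤ 20% |
| high-heteroplasmic | 20 < c < 95% |
| homoplasmic | 95 ≤ c ≤ 100% |

Tier mutation frequencies count each unique (position, alt) once over the
total sequenced nucleotides, with Wilson 95% intervals. Downstream analyses:
12-type L-strand substitution spectra with strand-bias tests
(continuity-corrected two-proportion test), 6-type complementary collapse,
96-class pyrimidine-centred trinucleotide context spectra, cross-sample
common/unique variant sets with known-variant flagging,
nonsynonymous/synonymous burden under the vertebrate mitochondrial code
(NCBI table 2) with the by-chance nonsynonymous expectation from exhaustive
substitution enumeration, and MutPred-style g-score aggregation. A seeded
duplex-read simulator with planted truth (binomial clonality, strand-shared
PCR errors, per-read sequencing errors) makes every stage verifiable.

The bundled 16,569-bp reference is a **synthetic stand-in**: true NC_012920
gene coordinates (37 genes + control region) over a generated
rCRS-composition sequence, labelled `synthetic_rcrs` throughout.

## Worked example

Simulate a duplex library of a 1,000-bp toy genome with three planted
variants (clonalities 0.3%, 8%, 100%), strand families of 3 reads, PCR
error 10⁻⁴ and sequencing error 10⁻³, then run the whole pipeline:

```r
library(mitoduplex)
library(dplyr)

toy <- make_toy_reference(1000, c(protein = 0.6, tRNA = 0.07, rRNA = 0.15),
                          seed = 2026)
planted <- tibble::tibble(position = c(120L, 450L, 800L),
                          clonality_pct = c(0.3, 8, 100))
planted$alt <- vapply(planted$position, function(p)
  setdiff(c("A","C","G","T"), ref_base(toy$reference, p))[1], "")

report <- run_pipeline(mito_pipeline_config(
  reference = toy$reference, annotation = toy$annotation,
  simulate = list(
    planted = planted, n_molecules = 3000,
    sim = duplex_sim_config(read_length = 1000,
                            family_size = list(kind = "constant", size = 3),
                            pcr_error_rate = 1e-4, seq_error_rate = 1e-3,
                            seed = 42)
  ),
  seed = 42
))
report
#> <mito_dx_report> toy_mt (1000 bp)
#>   reads 18000 -> families 6000 -> SSCS 6000 -> DCS 3000
#>   DCS nt 2,948,714, variants 3

select(report$variants, name, mutant_count, depth, clonality_pct, tier)
#> # A tibble: 3 × 5
#>   name     mutant_count depth clonality_pct tier
#>   <chr>           <int> <int>         <dbl> <chr>
#> 1 m.120A>C           12  2955         0.406 rare
#> 2 m.450G>A          225  2955         7.61  low_het
#> 3 m.800A>C         2948  2948       100     homoplasmic
```

Despite ~18 million simulated base calls at 10⁻³ error, the DCS layer calls
exactly the three planted variants, in their planted tiers, with zero false
positives; realised clonalities (0.406%, 7.61%, 100%) are the binomial
draws recorded in `report$truth$planted`. Codon consequences come from the
annotation:

```r
select(filter(report$variant_effects, position %in% planted$position),
       name, tier, gene, effect, ref_aa, alt_aa)
#> # A tibble: 3 × 6
#>   name     tier        gene  effect        ref_aa alt_aa
#> 1 m.120A>C rare        P1    nonsynonymous K      N
#> 2 m.450G>A low_het     P1    synonymous    S      S
#> 3 m.800A>C homoplasmic R1    <NA>          <NA>   <NA>
```

`tidy(report)` gives per-tier frequencies with Wilson bounds,
`glance(report)` a one-row summary (including the SSCS/DCS frequency
ratio), `plot_spectrum()`, `plot_context_spectrum()` and
`plot_tier_distribution()` the standard displays, and
`compare_samples(a, b)` the two-sample frequency, type and context
comparisons plus shared/exclusive variant sets.

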