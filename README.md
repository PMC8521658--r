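# melmap

Desk-scale R implementation of the forward-genetics inference chain for a
**dominant, incompletely penetrant Mendelian locus** — the kind of analysis
that takes a segregating plumage pattern in a chicken back-cross down to a
single candidate causal variant, plus the expression follow-up that shows
the variant acts in *cis*.

It is written for geneticists who want the individual stages as reusable,
tested functions rather than one-off scripts:

1. **Pool scans** — reference-allele frequency per pool, the absolute
   pool-frequency difference `absRAFdif = |p_A − p_B|` (ceiling 0.5 in a
   het-vs-hom back-cross contrast), per-site Nei-style
   `F_ST = (H_T − H_S)/H_T`, and its windowed, genome-wide Z-standardised
   form `ZF_ST`, with run-based peak calling.
2. **Linkage refinement** — minimal-switch recombinant classification
   against the phenotype-inferred causal genotype (nonrecombinant / single /
   double), interval refinement by intersecting single-recombinant
   constraints (closed at the innermost constraining markers), and
   penetrance estimation with a Wilson 95% CI.
3. **IBD mapping** — the maximal run of variants compatible with a
   haplotype shared by all carriers (hom carriers homozygous, het carriers
   carrying; missing never vetoes).
4. **Two-stage concordance filtering** — stage 1: no homozygous-mutant
   noncarrier in the sequenced panel; stage 2: mutant allele absent from
   every noncarrier across sequenced and diagnostic panels.
5. **Expression follow-up** — ΔΔCt relative expression
   (`efficiency^(−ΔΔCt)`), Ct-based fold changes, and allelic imbalance as
   the cDNA mutant/wild-type peak ratio normalised by the same sample's
   gDNA ratio, tested with Welch's t on log2 ratios.

A seeded synthetic-data generator (`sim_config()`, `simulate_cross()`,
`simulate_pools()`, `simulate_panel()`, `simulate_expression()`) produces a
back-cross of 126 females (penetrance 0.855), 30x binomial pool reads, a
12 + 82 carrier/noncarrier panel with a planted 21.4-kb descent segment
containing the causal variant plus five decoys, and two-transcript
expression data — so the whole chain is testable without any external data.

## Worked example

```r
library(melmap)
run <- run_pipeline(sim_config(seed = 11))
run
#> <melmap_run>
#>   simulate     126 back-cross (42 double_lacing, 28 intermediate, 56 pencilling), panel 94+101 samples
#>   scan         top peak chr1:90000001-102000000 (absRAFdif 0.400), seed interval chr1:84000001-108000000
#>   linkage      38 singles, 12 doubles; refined interval chr1:92850374-94324190 (1473817 bp); penetrance 0.883
#>   ibd          IBD region chr1:93842294-93857709 (6 compatible sites)
#>   concordance  6 stage-1 / 1 stage-2 passer(s): causal_chr1_93852277
#>   expression   allelic imbalance up, p = 0.00036
```

Reading the output: the pooled scan puts the locus on chromosome 1 near
94 Mb; affected single recombinants narrow it to a 1.47-Mb interval;
within that, the 12 panel carriers share a 15-kb identical-by-descent
region holding six fully associated variants; the diagnostic panel
eliminates five of them (their mutant allele appears in noncarriers),
leaving exactly the planted causal variant at 93,852,277. The expression
stage detects the planted five-fold cis up-regulation
(`t = 19.4, p = 3.6e-04`, direction "up"). Penetrance is estimated from
the genotyped heterozygotes:

```r
run$penetrance
#> Penetrance: 0.8833 (53 of 60 carriers affected), 95% CI [0.7782, 0.9423]
```

The package also ships a real six-variant diagnostic panel across 25 breed
groups; the two-stage filter isolates the 41-bp/38-bp indel at 93,852,277:

```r
panel <- load_candidate_panel()
out <- diagnostic_concordance(panel$wgs, panel$diagnostic)
out$id[out$stage2_pass]
#> [1] "InDel1"
```

Small worked numbers the functions reproduce: 53 affected of 62
heterozygotes → 85% penetrance; endpoints chr1:93,846,273–93,867,646 →
21,374 bp (21.4 kb); Ct 28.9 vs 22.9 at efficiency 2 →
`fold_change_from_ct(28.9, 22.9) = 64`.

A thin command-line wrapper with subcommands
`simulate | scan | linkage | ibd | concordance | expression | run` is
installed at `system.file("cli", "melmap.R", package = "melmap")`; configs
are YAML files mapping 1:1 onto `sim_config()` fields.

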