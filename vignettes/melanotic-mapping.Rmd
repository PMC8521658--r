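---
title: "Mapping a dominant, incompletely penetrant plumage-pattern locus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant, incompletely penetrant plumage-pattern locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melmap)
```

# The mapping problem

`melmap` implements the classical inference chain used to move from a
segregating Mendelian trait to a single candidate causal variant, for the
specific situation of a **dominant allele with incomplete penetrance** in a
back-cross design. The motivating system is a chicken plumage-pattern locus:
a carrier line fixed for a dominant pattern allele (phenotype *double
lacing*) is crossed to a wild-type line (*pencilling*), F1 females are
back-crossed to wild-type males, and female offspring are phenotyped as
pencilling, double lacing, or intermediate. Because every offspring carries
one intact wild-type chromosome, each individual's informative genotype at
any marker is simply heterozygous (carrier allele present) or homozygous
wild-type — the cleanest possible setting for breakpoint logic.

The chain has five analysis stages, each consuming the previous stage's
output:

1. **Pool scan.** DNA pools of the two clear phenotype classes are
   sequenced; the absolute difference in reference-allele frequency between
   pools (absRAFdif) peaks around the causal locus. In a het-vs-hom
   back-cross contrast the theoretical ceiling is 0.5: the carrier-class
   pool is heterozygous (frequency 1/2) and the wild-type-class pool
   homozygous (frequency 1) at a fully informative site. A per-site
   F~ST~ scan, windowed and Z-standardised genome-wide (ZF~ST~), gives an
   equivalent view.
2. **Linkage refinement.** Individual genotyping of markers inside the peak
   region classifies each bird as nonrecombinant, single or double
   recombinant relative to its phenotype-inferred causal genotype; single
   recombinants bound the locus, and the interval is the intersection of
   their constraints.
3. **IBD detection.** Carriers sampled from many breeds share the causal
   mutation by descent, hence a short haplotype around it. The maximal run
   of variants compatible with a shared carrier haplotype pins the locus to
   a few tens of kb.
4. **Concordance filtering.** Within the IBD region, a variant is causal
   only if its mutant allele is perfectly concordant with carrier status —
   first in the sequenced panel (stage 1), then additionally absent from
   every noncarrier in a larger diagnostic panel (stage 2).
5. **Expression follow-up.** If the surviving variant is regulatory, its
   effect should be visible as differential expression (ΔΔCt qPCR) and as
   allelic imbalance in heterozygotes (cDNA peak-height ratios normalised
   by genomic DNA).

# Phenotype model and penetrance

Phenotype is drawn conditionally on the true causal genotype. A
heterozygote is *affected* with probability `penetrance` (default 0.855,
matching the canonical 53-of-62 worked example); an affected bird is scored
`intermediate` with probability `p_intermediate_given_affected` (default
10/53) and `double_lacing` otherwise; an unaffected heterozygote is scored
`pencilling`. Homozygous wild-type birds are scored `intermediate` with
probability `p_intermediate_given_hom` (default 13/64) and `pencilling`
otherwise.

Two modelling points deserve emphasis:

* **Intermediates are excluded from mapping** — they enter neither the pools
  nor the clear-class genotype inference — but they **count as affected** in
  penetrance estimation, since an intermediate pattern is a phenotypic
  effect of the allele.
* The default class frequencies reproduce a 60/43/23
  pencilling/double-lacing/intermediate split among 126 birds in
  expectation. The two intermediate probabilities are separate dials
  because the two sources of intermediates (partially expressing carriers,
  ambiguous wild-types) are biologically distinct; setting both to zero
  gives a strictly deterministic two-class model, used in several tests.

`estimate_penetrance()` is the affected fraction among diagnostically
genotyped heterozygotes with a Wilson score interval — chosen over
Clopper–Pearson for its better behaviour at moderate n, and because no
interval method was prescribed for this estimator.

# The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its planted truth.

* **Genetic map.** Uniform `cm_per_mb` (default 3.0) per chromosome and the
  Haldane map function r = (1 − e^(−2d/100))/2 with no interference. No
  genetic map is available for the motivating cross; this is the simplest
  defensible model, and the map calibration is itself property-tested
  (observed recombinant fraction at 10 cM over 50,000 meioses within 3
  binomial SD of the Haldane value).
* **Markers.** `n_markers_per_chrom` (default 400) evenly spaced markers on
  each of three chromosomes (197/149/111 Mb), all fixed for alternative
  alleles in the founder lines, so every marker is informative by
  construction. The causal site (default chr1:93,852,277) is carried as a
  marker by default (`include_causal_marker`); disabling it emulates a
  genotyping panel that lacks the causal variant.
* **Pool-seq.** Read counts are Binomial(depth, p′) with
  p′ = p(1−ε) + (1−p)ε for symmetric base error ε (defaults: depth 30,
  ε = 0.001). No overdispersion term is modelled; that is a documented
  extension point. Array-style intensity data are not emulated — a
  high-depth count pool is the stand-in, since exact frequencies are the
  limit both converge to.
* **Carrier panel.** A descent segment of `ibd_segment_length` (default
  21,400 bp) centred on the causal position is planted in 12 carriers (2 of
  them heterozygous) against 82 noncarriers, with a follow-up diagnostic
  panel of 47 carriers / 54 noncarriers. Inside the segment segregate the
  causal variant and 5 decoys. Every decoy's mutant allele leaks into at
  least one noncarrier — heterozygous leaks in the sequenced panel, plus
  one homozygous-mutant noncarrier in the diagnostic panel for the first
  decoy — so that by construction exactly one variant (the causal one)
  survives stage 2, while all six survive stage 1 in the sequenced panel.
  Outside the segment, variants are independent Hardy–Weinberg draws and
  are almost never compatible with a shared haplotype across 12 carriers.
* **Expression.** Ct values are Gaussian around planted transcript means
  (reference gene at 20 cycles; two target transcripts separated by
  `delta_ct`, default 6 cycles); peak heights carry a shared allele-specific
  bias (default 1.25), multiplicative log-normal noise, and a cDNA
  mutant/wild-type ratio centred on `true_fold_allele_ratio`.
* **Seeding.** One integer seed determines everything; the generators
  derive sub-seeds by fixed offsets (cross +0, pools +1, panel +2,
  expression +3) so stages can be re-run independently yet reproducibly.

What the generator does **not** emulate: linkage disequilibrium beyond the
planted segment, coalescent demography, genotyping error inside the
planted segment, sequence-level reads, or array intensity noise. Passing
tests therefore demonstrate the *logic* of the chain under its stated
assumptions, not robustness to every artefact of real data.

# Numerical and procedural choices

* **Coordinates** are 1-based inclusive everywhere internally (interval
  length = end − start + 1, so chr1:93,846,273–93,867,646 is 21,374 bp ≈
  21.4 kb); conversion to 0-based half-open happens only at the BED file
  boundary.
* **F~ST~ estimator.** Nei-style two-population G~ST~ on pool frequencies:
  F~ST~ = (H~T~ − H~S~)/H~T~, defined 0 when H~T~ = 0, negatives clamped to
  0 before windowing. No sample-size correction is applied: pool depths are
  large and no correction was prescribed.
* **Windows.** Default 40-kb windows with 20-kb step and `min_sites = 10`
  for ZF~ST~ at sequencing density. Window membership is
  \[start, start + window); the Z-standardisation set is all windows
  genome-wide meeting `min_sites`; zero-variance window means yield Z = 0
  with a warning rather than NaN.
* **Peak calling** operates on maximal runs of at-or-above-threshold
  records, merging runs separated by gaps shorter than `min_run`, and
  returns intervals sorted by peak value. The pipeline calls peaks on a
  *window-averaged* absRAFdif track (4-Mb windows, 2-Mb step) rather than
  per-site values: at 30x pool depth the per-site difference has a null
  mean near 0.11 with SD near 0.13, so single sites cross any useful
  threshold erratically, while window means (SE ≈ 0.05 at the simulated
  marker spacing) separate cleanly. The default threshold 0.3 sits midway
  between the null window mean (~0.11) and the linked-region signal
  (~0.4). The classification interval is the top peak padded by
  `interval_pad` (default 6 Mb) — wide enough that a one-window offset of
  the called run never excludes the causal position; the padding costs
  nothing downstream because refinement uses innermost constraints.
* **Recombinant classification** is minimal-switch logic: the
  phenotype-inferred causal state must be inserted strictly between the
  flanking markers, and the class is the minimal number of haplotype-state
  switches the merged sequence requires (0/1/2/complex). A pencilling bird
  heterozygous at both flanking markers is thus a "double recombinant" —
  over a short interval the far likelier reading is a non-penetrant
  heterozygote, which is why doubles are excluded from refinement and
  counted on the affected side of penetrance checks instead. Missing marker
  genotypes contribute no information and are never imputed; samples with
  fewer than two called markers are skipped.
* **Interval refinement** bounds are *closed at the far bracket marker*:
  a single recombinant with crossover bracket (L, R) and the causal allele
  on the left constrains the locus to ≤ R (and symmetrically ≥ L). This
  matches how marker-defined interval endpoints are conventionally
  reported (both boundary markers included) and resolves the tie when a
  bracket contains an old boundary marker: the innermost constraining
  marker wins.
* **Affected-only constraints.** `run_pipeline()` refines, by default, on
  double-lacing (affected) single recombinants only. With incomplete
  penetrance an affected phenotype *proves* carrier status, while a
  pencilling phenotype does not: roughly 15% of heterozygotes present as
  pencilling, and such a bird with a genuine crossover in the scanned
  interval masquerades as a valid single recombinant whose constraint can
  silently exclude the causal position. Affected-only refinement is the
  standard defensive practice for incompletely penetrant dominants; the
  exported `refine_interval()` still accepts both classes (and errors on
  inconsistent constraints, naming the samples) for data where penetrance
  is complete.
* **IBD compatibility.** A site is compatible with a shared carrier
  haplotype iff some allele is carried by every carrier: homozygous
  carriers must be homozygous for it, heterozygous carriers must carry at
  least one copy, and missing calls never veto. This allele-sharing rule
  deliberately avoids phasing — it is the weakest assumption under which a
  shared-descent claim is testable from genotypes alone. The region
  returned is the maximal compatible run containing the most-associated
  site (ties: leftmost), reported from its first to its last compatible
  variant; `max_conflicts` (default 0) tolerates isolated incompatible
  sites for real panels with genotyping errors.
* **Concordance.** Stage 1 forbids a homozygous-mutant noncarrier; stage 2
  additionally forbids any mutant allele in any noncarrier across both
  panels. Missing genotypes never veto at either stage (no-call cells occur
  inside accepted haplotype blocks in practice). Multi-allelic sites are
  skipped with a message — the filter logic is biallelic.
* **Expression.** Amplification efficiency defaults to 2.0 (perfect
  doubling) and is configurable; replicate Ct values are averaged before
  ΔCt with no outlier rejection. The allelic-imbalance test is a Welch
  two-sample t on log2 raw ratios (cDNA vs gDNA): the log scale makes
  k-fold up and k-fold down symmetric, and the gDNA group doubles as the
  bias control, so no explicit normalisation enters the test. No test was
  prescribed for the original figure's significance stars; Welch-on-logs is
  the conservative default. Its type-I rate is verified to sit at the
  nominal 0.05 over 1,000 null simulations.

# Bundled diagnostic panel

`load_candidate_panel()` ships a plain-text encoding of a six-variant
candidate panel (rs316201461, InDel1, rs312865584, InDel2, rs317670985,
rs794497277 at 93.85–93.87 Mb on chromosome 1) genotyped across carrier and
noncarrier breed groups, split into the sequenced panel (12 carriers / 82
noncarriers) and the diagnostic panel (47 / 54). Group rows expand to one
sample per animal. The per-panel assignment of noncarrier groups is
reconstructed so that the sequenced panel contains no homozygous-mutant
noncarrier (all six variants pass stage 1 there), with the
homozygous-mutant red junglefowl in the diagnostic panel. The indel allele
sequences in the fixture are synthetic placeholders of the documented
lengths (41 bp replaced by 38 bp); only genotype codes matter to the
filter. Running the two-stage filter on this panel leaves exactly InDel1 at
93,852,277.

```{r table1}
panel <- load_candidate_panel()
diagnostic_concordance(panel$wgs, panel$diagnostic)
```

# Problem sizes used in the tests

The test suite exercises the chain at the design's own scale: 126
back-cross females with 400 markers per chromosome for single runs; 100
seeds for end-to-end recovery (the refined interval contains the causal
position and the concordance filter returns exactly the planted variant in
100/100 at defaults); 50,000 meioses for map calibration; 10,000 birds for
penetrance calibration; 100 seeds of 10,000 birds for CI coverage; 1,000
null seeds for the imbalance test's type-I rate; exhaustive enumeration
(all 3^5 five-marker genotype vectors, all sub-intervals of ≤50-site
panels, brute-force window rescans to 1e-12) for the combinatorial
oracles.

# Known limitations

* The pool model has no overdispersion; real pool-seq data are noisier than
  Binomial at a given depth.
* The two-round marker-selection economics of a real project (genotype few
  SNPs first, then densify around the signal) is represented by a single
  dense classification pass; the constraint arithmetic is identical.
* IBD detection assumes the carriers share *one* ancestral mutation event;
  allelic heterogeneity would break the shared-haplotype assumption and is
  out of scope.
* Incomplete penetrance makes wild-type-classified recombinants
  irreducibly ambiguous; no deterministic breakpoint method can use them
  safely, which is precisely why the pipeline's default ignores them.
* Expression simulation plants a single cis effect with log-normal noise;
  tissue effects, efficiency drift between genes, and chromatogram
  artefacts are not modelled (peak heights are taken as inputs).
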