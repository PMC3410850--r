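---
title: "Population genomics of paired bacterial species: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics of paired bacterial species: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizopopgen)
```

## The analysis this package implements

`rhizopopgen` analyses panels of haploid bacterial strains sampled from two
closely related species whose genomes are divided over several replicons — a
chromosome and one or more megaplasmids, the layout of rhizobia such as
*Sinorhizobium meliloti* and *S. medicae*.  Three questions drive the
design:

1. **How much gene flow crosses the species boundary?**  At every ortholog
   pair the package counts *fixed differences* (each species monomorphic,
   for different bases) and *shared polymorphisms* (both species segregating
   the same two bases).  Vertical descent after a deep split produces many
   fixed differences and almost no shared polymorphism; a recent
   interspecific transfer inverts that balance.  Genes whose
   shared:fixed ratio exceeds 0.2 (strictly) are flagged and then clustered
   into contiguous transferred regions.
2. **How is diversity structured within a species?**  Per gene and per
   10-kb window the package computes the number of segregating sites S,
   nucleotide diversity θ~π~, Watterson's θ~W~, Tajima's D, and — polarised
   against the sister species — θ~H~ and Fay and Wu's H, plus the
   synonymous/nonsynonymous partition of θ~π~.
3. **Which genes were recently swept?**  Within an analysis group (a
   replicon, or a chromosome half delimited by the replication terminus),
   genes lying in the lower 5% empirical tail of *both* D and H are reported
   as candidate targets of recent positive selection.

A coalescent simulator generates two-species cohorts with known per-gene
truth (θ, transfer status, sweep status) so that every stage of the pipeline
is testable against ground truth at desk scale.

## Consensus calling and coverage eligibility

Haploid consensus bases are called from per-site read counts: a base is
accepted only when total depth lies in [10, 500) and the base is supported
by at least 70% of the reads; everything else is ambiguous (`N`).  The
bounds are inclusive below and exclusive above, exactly as stated; 70%
support passes.  Because 70% > 50%, two bases can never qualify at once.
Positions absent from the count table are `N` rather than an error: missing
evidence means unaligned sequence, not a broken input.

Coverage eligibility is enforced at two scales:

* **genes** — eligible when at least 80% of strains each have calls for
  *more than* 90% of the gene length;
* **10-kb windows** — eligible when *more than* 8,000 bp are called in
  *more than* 80% of strains (both inequalities strict, following the
  stated rule).

## Missing data and site classes

All statistics use **complete deletion**: only columns without any `N`
across the analysed strains enter the computation, and per-site values are
scaled by that analysed length.  The eligibility thresholds guarantee that
at least roughly 72% of sites survive in the worst admissible case, so
complete deletion cannot silently hollow out a gene that passed the filter.
Columns with three or more alleles (possible under the finite-sites
simulator, rare at realistic θ) count toward S but are excluded from all
SFS-based quantities (θ~π~, spectra, θ~H~); they are reported per gene as a
diagnostic.  Whether the original analyses used complete or pairwise
deletion is not documented; complete deletion is this package's recorded
choice, made once.

## Polarisation and the two forms of H

Derived states are assigned against an outgroup sequence, by default the
majority consensus of the sister species' ortholog alignment (ties give
`N`).  Columns whose outgroup base is `N` or matches neither allele are
unpolarizable: excluded from the unfolded spectrum and from H, but still
counted in S and the folded spectrum.  The consensus outgroup is the
least-assumption choice where the source procedure is not documented.

`gene_stats()` reports H in two forms:

* `fay_wu_h` — the classic unnormalised statistic π − θ~H~ (per site),
  matching the textbook worked examples;
* `fay_wu_h_norm` — H divided by the standard deviation of its neutral
  sampling distribution given S (the form used by joint D–H tests, with
  the variance formula driven by `S/a₁` and `S(S−1)/(a₁²+a₂)`).

The selection scan ranks the H tail on the *normalised* statistic by
default.  The reason is practical and verifiable: the neutral spread of
unnormalised H grows with θ, so in a tail computed across genes the most
diverse neutral genes crowd out genuinely swept genes, which have little
diversity left.  Normalisation puts genes of different θ on one scale; in
neutral simulations at n = 24 the normalised H has standard deviation ≈
0.94, confirming the calibration.  `dth_scan(..., h_col = "fay_wu_h")`
restores the plain statistic.

## The selection scan

Within each group the lower-tail threshold is the value at rank ⌈q·m⌉ of
the ascending sort, and membership is `value ≤ threshold` (ties admitted,
with a warning when ties inflate the tail by more than half).  Candidates
must sit in both the D and the H tail.  Admissible genes are coverage
eligible, show no evidence of transfer, have S ≥ 2 (D is wildly skewed at
S = 1), and have a defined H.  An alternative tail convention — rescaling q
by the admissible-to-total gene ratio — is exposed as
`tail_scale = "total"`; the wording of the source procedure is ambiguous
between the two readings, so both ship and neither is asserted as the
original intent.

## HGT classification and region clustering

The ratio conventions at zero counts preserve monotonicity: `shared > 0`
with `fixed = 0` is +∞ (flagged); `0/0` is undefined (not flagged).  A
ratio of exactly 0.2 is *not* flagged.  Flagged genes are clustered into
maximal regions: two flagged genes join when every intervening gene either
lacks an ortholog (any number) or has ratio < 0.2, with at most two such
low-ratio genes in any single gap between consecutive flagged members —
the gap-wise reading of the clustering rule, which is the natural
maximal-region interpretation.  Genes with an ortholog but no computable
ratio are treated as low-ratio.  Published aggregate counts reproduce the
printed ratios through `table1_report()` (e.g. 1,964 shared / 563 fixed →
3.49); one published row prints a ratio (0.0010:1) inconsistent with its
own counts (246/25,480 ≈ 0.0097), and the package reports the arithmetic
ratio rather than matching the misprint.

## Genealogies

Pairwise distances are maximum-likelihood F84 distances with empirical base
frequencies of the pooled pair and a fixed transition/transversion ratio
(default 2.0, the classic `dnadist` default; the original parameter value
is not documented).  The within-group rate is solved from the requested
ts/tv flux ratio and the per-pair likelihood is maximised numerically over
the expected-substitutions scale; columns with `N` in either sequence are
dropped pairwise.  With equal base frequencies and ts/tv = 0.5 the distance
reduces to Jukes–Cantor, which the tests exploit as an oracle, alongside an
independent matrix-exponential implementation of the model.

Trees are built by neighbor-joining (via `ape`), with negative branch
lengths clamped to zero.  Bootstrap support resamples alignment columns
(200 replicates by default) and internal edges with support below 80% are
contracted into polytomies; majority-rule consensus keeps bipartitions in
more than half of the input trees.  Site patterns are compressed before
distance computation, so bootstrap replicates cost little on concatenated
gene sets.

## Replichores

GC skew, (G − C)/(G + C), is profiled in 10-kb windows with a 5-kb step;
windows without G or C are omitted.  The terminus is placed at the most
*persistent* sign change — the change maximising the summed |skew| of the
two flanking constant-sign runs, after a light 3-window running mean —
because a deterministic rule is needed where the original analysis read the
switch point off a plot.  When the origin position is supplied, the
origin-side sign change of the circular chromosome is excluded.  Chromosome
halves are split closed-left: a gene starting exactly at the split belongs
to the first half.  `theta_contrast_table()` renders between-group
diversity relationships as ratios and rounded percentages, the form in
which half-versus-plasmid comparisons are usually quoted (0.004 vs 0.0008
→ 5×; 0.0008 vs 0.0134 → 6%).

## The synthetic cohort generator

Each gene is an independent, non-recombining locus (free recombination
between genes, none within — matching the per-gene analysis granularity).
Within-species genealogies follow the standard neutral coalescent; the two
species merge into one ancestral population at depth `t_split` in
coalescent units.  Mutations fall on branches at rate θ/2 per site under
finite sites with repeat hits allowed, so the downstream biallelic
filtering has real work to do.  Defaults describe the emulated study
conditions and were fixed once:

* 24 + 12 strains; three replicons (chromosome 120 genes at θ = 0.004,
  two plasmids of 60 genes at θ = 0.012 and 0.008, 1-kb genes, 200-bp
  spacers) — plasmid diversity exceeds chromosomal diversity, as in the
  emulated system;
* `t_split = 10`, deep enough that fixed differences exceed shared
  polymorphisms by two to three orders of magnitude at neutral genes (the
  documented qualitative regime; the true interspecific divergence in
  coalescent units is not documented anywhere and is not estimated here);
* `t_hgt = 0.2` (2% of `t_split`) for transferred genes — a whole-gene
  replacement with a recent interspecific coalescent, which makes
  essentially every transferred gene detectable at the 0.2 ratio rule while
  neutral genes are practically never flagged;
* sweeps: the genealogy runs neutrally up to `t_s = f/2`, at which point
  every surviving lineage coalesces instantly unless it escapes
  (probability 0.12 per lineage).  A uniform rescaling of all coalescent
  times by f — the simplest reading of "scaling within-species times" —
  is exactly a reparameterisation θ → fθ: it thins diversity but leaves
  the genealogy's *shape*, hence E[D] and E[H], untouched, so it cannot
  produce the sweep signatures the scan is supposed to detect.  The
  truncation-with-escape model is the standard coalescent approximation of
  a hard sweep: diversity drops (median θ̂~π~ of swept genes ≈ 0.13–0.25 of
  neutral at f = 0.1), D drops by 1.5–1.9, and the swept-cluster stem
  generates high-frequency derived variants (negative H) whenever at least
  one lineage escapes.

Simulated read counts are Poisson in depth with uniform base errors, so the
caller's thresholds are exercised end to end.

What the generator does **not** emulate: intragenic recombination and gene
conversion, indels and alignment gaps (cohort alignments are gapless, which
is also why ortholog alignments are consumed pre-aligned), variation in
gene content between strains, mapping artefacts with position-correlated
coverage, and base-composition structure (apart from the dedicated
skew-genome builder).  Passing tests therefore demonstrate the statistics
and the decision rules, not robustness to real-data alignment pathology.

## Numerical choices and degenerate inputs

* Tajima's D uses the standard constants and is undefined below two
  segregating sites; such genes are excluded from D-based analyses.
* θ and H are reported per analysed site; H worked examples at L = 1
  coincide with per-gene totals.
* The codon partition counts fractional synonymous sites Nei–Gojobori
  style under translation table 11 (changes to stops count as
  replacement); the reference codon is the majority base per column with
  alphabetical tie-breaking, codons containing `N` in the reference are
  skipped, an internal reference stop flags the gene and skips the
  partition, and an incomplete terminal codon is trimmed.
* NJ Q-criterion ties are resolved by `ape`'s deterministic
  implementation; bootstrap supports are reproducible given a seed.
* `call_site` with all-zero counts, empty count tables, empty scan groups,
  and profiles without a sign change all return the documented neutral
  values or fail loudly — never silently.

## Problem sizes used by the tests and the acceptance script

The shipped suites run at the study conditions scaled to desk size, chosen
once as the package's own verification budget: estimator recovery on 200
neutral genes of 10 kb at n = 24 and θ = 0.005; the sweep scan on 300 genes
with 10% swept at f = 0.1; HGT detection on 120 genes with six 4-gene
transferred tracts; θ~π~ oracle equivalence on 1,000 random small
alignments at 10⁻¹² tolerance; terminus recovery on a 400-kb two-arm
genome.  A full synthetic end-to-end run (pileup → caller → statistics →
HGT → scan → trees → reports) at the default cohort finishes in minutes on
one CPU.

## Known limitations

The selection scan is an empirical outlier method: it ranks genes, it does
not test a null model, and with fewer than ~20 admissible genes a 5% tail
is a single gene (a warning is emitted).  The HGT ratio rule cannot see
very old transfers (shared polymorphism decays into fixed differences), and
region clustering inherits the annotation's gene order.  The F84 distance
errors on saturated pairs instead of guessing.  VCF export of segregating
sites is not provided; consensus matrices, gene statistics and region
tables are the exchange formats.
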